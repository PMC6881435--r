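#' Assemble a feature table
#'
#' The central container of the pipeline: a samples-by-features intensity
#' matrix with aligned per-sample and per-feature metadata tibbles. All
#' downstream stages (QC filtering, multivariate modelling, signature
#' selection, evaluation) consume and return this object.
#'
#' @param intensities Numeric matrix, samples in rows and features in
#'   columns. Row and column names, if present, must agree with the
#'   metadata identifiers.
#' @param samples Data frame of per-sample metadata with columns
#'   `sample_id`, `role` (one of `"study"`, `"sqc"`, `"ltr"`,
#'   `"dilution"`), `class` (`"bacterial"`, `"viral"` or `NA` for
#'   non-study samples), `injection_order`, `dilution_factor`,
#'   `age_months`, `sex`.
#' @param features Data frame of per-feature metadata with columns
#'   `feature_id`, `mz` (Daltons), `rt_min` (minutes), `annotation` and
#'   `annotation_level` (Metabolomics Standards Initiative tier, 1-4).
#' @param log_transformed Logical flag recording whether the intensities
#'   are on the natural-log scale (set by [log_transform()]).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features,
                          log_transformed = FALSE) {
  samples <- tibble::as_tibble(samples)
  features <- tibble::as_tibble(features)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))

  required_s <- c("sample_id", "role", "class", "injection_order",
                  "dilution_factor", "age_months", "sex")
  missing_s <- setdiff(required_s, names(samples))
  if (length(missing_s) > 0) {
    note("samples metadata lacks column(s): %s",
         paste(missing_s, collapse = ", "))
  }
  required_f <- c("feature_id", "mz", "rt_min", "annotation",
                  "annotation_level")
  missing_f <- setdiff(required_f, names(features))
  if (length(missing_f) > 0) {
    note("features metadata lacks column(s): %s",
         paste(missing_f, collapse = ", "))
  }
  if (length(problems) > 0) {
    rlang::abort(paste(problems, collapse = "\n"), class = "lipidsig_error")
  }

  if (nrow(intensities) != nrow(samples)) {
    note("dimension mismatch: %d intensity rows vs %d sample records",
         nrow(intensities), nrow(samples))
  }
  if (ncol(intensities) != nrow(features)) {
    note("dimension mismatch: %d intensity columns vs %d feature records",
         ncol(intensities), nrow(features))
  }
  if (anyDuplicated(samples$sample_id)) note("duplicate sample_id values")
  if (anyDuplicated(features$feature_id)) note("duplicate feature_id values")
  if (!all(samples$role %in% c("study", "sqc", "ltr", "dilution"))) {
    note("sample role must be one of study/sqc/ltr/dilution")
  }
  study <- samples$role == "study"
  if (any(study & (is.na(samples$class) |
                   !samples$class %in% c("bacterial", "viral")))) {
    note("every study sample needs class 'bacterial' or 'viral'")
  }
  if (any(samples$role == "dilution" & !is.finite(samples$dilution_factor))) {
    note("every dilution sample needs a finite dilution_factor")
  }
  ord <- samples$injection_order[!is.na(samples$injection_order)]
  if (anyDuplicated(ord)) note("injection_order values must be unique")
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    note("intensities must be finite (no NA/Inf); set a missing-value policy upstream")
  } else if (!log_transformed && any(intensities < 0)) {
    note("raw intensities must be non-negative")
  }
  if (length(problems) > 0) {
    rlang::abort(paste(problems, collapse = "\n"), class = "lipidsig_error")
  }

  rownames(intensities) <- samples$sample_id
  colnames(intensities) <- features$feature_id

  structure(
    list(intensities = intensities, samples = samples, features = features,
         log_transformed = isTRUE(log_transformed)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$log_transformed) "log" else "raw"))
  print(dplyr::count(x$samples, .data$role, .data$class))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param table A [feature_table()].
#' @param samples,features Identifiers or logical/integer indices; `NULL`
#'   keeps everything. Order of the table is preserved metadata-aligned.
#' @return A `feature_table`.
#' @export
ft_subset <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- resolve_index(samples, table$samples$sample_id, "sample")
  fi <- resolve_index(features, table$features$feature_id, "feature")
  feature_table(table$intensities[si, fi, drop = FALSE],
                table$samples[si, , drop = FALSE],
                table$features[fi, , drop = FALSE],
                log_transformed = table$log_transformed)
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(idx) || anyNA(pos)) {
      rlang::abort(sprintf("unknown %s id(s): %s", what,
                           paste(idx[is.na(pos)], collapse = ", ")),
                   class = "lipidsig_error")
    }
    return(pos)
  }
  idx
}

#' Keep only study samples
#'
#' @param table A [feature_table()].
#' @return A `feature_table` restricted to `role == "study"`.
#' @export
ft_study <- function(table) {
  ft_subset(table, samples = which(table$samples$role == "study"))
}

#' Class labels of the study samples
#'
#' Encodes the two-class descriptor used by all supervised stages:
#' bacterial = 1, viral = 0.
#'
#' @param table A [feature_table()] (only study samples are used).
#' @return Named numeric vector of 0/1 labels, names are sample ids.
#' @export
class_vector <- function(table) {
  s <- table$samples[table$samples$role == "study", ]
  y <- as.numeric(s$class == "bacterial")
  names(y) <- s$sample_id
  if (length(unique(y)) < 2) {
    rlang::abort("both classes (bacterial and viral) must be present",
                 class = "lipidsig_error")
  }
  y
}

encode_class <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) {
      rlang::abort("numeric class labels must be 0/1 (bacterial = 1)",
                   class = "lipidsig_error")
    }
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("bacterial", "viral"))) {
    rlang::abort("class labels must be 'bacterial'/'viral' or 0/1",
                 class = "lipidsig_error")
  }
  as.numeric(y == "bacterial")
}

#' Natural-log transform the intensity matrix
#'
#' All model fitting downstream operates on log intensities by default:
#' LC-MS intensity noise is multiplicative, so the log scale is the
#' conventional space for the linear models. The pipeline config can skip
#' the transform to mimic raw-abundance analysis.
#'
#' @param table A raw-scale [feature_table()].
#' @param pseudocount Non-negative offset added before the log; the
#'   default 1 is robust to zero intensities and negligible at LC-MS
#'   intensity scale.
#' @return A `feature_table` with `log_transformed = TRUE`.
#' @export
log_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_transformed) {
    rlang::abort("table is already log-transformed", class = "lipidsig_error")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    rlang::abort("pseudocount must be a single non-negative number",
                 class = "lipidsig_error")
  }
  if (pseudocount == 0 && any(table$intensities == 0)) {
    rlang::abort("zero intensities present; use a positive pseudocount",
                 class = "lipidsig_error")
  }
  feature_table(log(table$intensities + pseudocount),
                table$samples, table$features, log_transformed = TRUE)
}

#' Read a study from the three-file CSV layout
#'
#' Expects the dialect written by [write_fixture()]: an intensity file
#' whose first column is `sample_id`, a sample-metadata file and a
#' feature-metadata file. Delimiter is auto-detected from the extension
#' (`.tsv` means tab, anything else comma). Samples are reordered by
#' injection order when present. All validation failures are reported
#' together.
#'
#' @param intensities_path,samples_path,features_path File paths.
#' @return A validated [feature_table()].
#' @export
read_study <- function(intensities_path, samples_path, features_path) {
  rd <- function(path, coltypes) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    readr::read_delim(path, delim = delim, col_types = coltypes,
                      progress = FALSE, show_col_types = FALSE)
  }
  ints <- rd(intensities_path, readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()))
  if (names(ints)[1] != "sample_id") {
    rlang::abort("first column of the intensity file must be 'sample_id'",
                 class = "lipidsig_error")
  }
  bad <- !vapply(ints[-1], is.numeric, logical(1))
  if (any(bad)) {
    rlang::abort(sprintf("non-numeric intensity column(s): %s",
                         paste(names(ints)[-1][bad], collapse = ", ")),
                 class = "lipidsig_error")
  }
  samples <- rd(samples_path, readr::cols(
    sample_id = readr::col_character(), role = readr::col_character(),
    class = readr::col_character(), injection_order = readr::col_double(),
    dilution_factor = readr::col_double(), age_months = readr::col_double(),
    sex = readr::col_character()))
  features <- rd(features_path, readr::cols(
    feature_id = readr::col_character(), mz = readr::col_double(),
    rt_min = readr::col_double(), annotation = readr::col_character(),
    annotation_level = readr::col_double()))

  if (!setequal(ints$sample_id, samples$sample_id)) {
    rlang::abort("dimension mismatch: sample ids in the intensity and sample-metadata files differ",
                 class = "lipidsig_error")
  }
  samples <- samples[match(ints$sample_id, samples$sample_id), ]
  mat <- as.matrix(ints[-1])
  rownames(mat) <- ints$sample_id
  if (!setequal(colnames(mat), features$feature_id)) {
    rlang::abort("dimension mismatch: feature ids in the intensity and feature-metadata files differ",
                 class = "lipidsig_error")
  }
  features <- features[match(colnames(mat), features$feature_id), ]
  if (anyNA(mat)) {
    rlang::abort("non-numeric or missing intensity cells found",
                 class = "lipidsig_error")
  }
  if (!anyNA(samples$injection_order)) {
    ord <- order(samples$injection_order)
    mat <- mat[ord, , drop = FALSE]
    samples <- samples[ord, ]
  }
  feature_table(mat, samples, features)
}
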