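#' End-to-end pipeline configuration
#'
#' Bundles every stage's tunables plus the seeds that make a run
#' reproducible. Serializes to YAML and round-trips via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param qc A [qc_config()].
#' @param log_transform Model on natural-log intensities (recommended;
#'   disable to mimic raw-abundance analysis).
#' @param pseudocount Offset for the log transform.
#' @param n_ortho Orthogonal OPLS-DA components (1 = the minimal
#'   O-PLS-DA).
#' @param n_perm Label permutations for model validation.
#' @param n_folds Cross-validation folds for Q2.
#' @param splot_cutoff Shortlist threshold on the S-plot covariance axis.
#' @param fspls An [fspls_config()].
#' @param screen Covariate groupings screened before FS-PLS (subset of
#'   `"age_median_split"`, `"sex"`).
#' @param screen_alpha FDR level of the covariate screen.
#' @param screen_moderated Use limma moderated t for the screen.
#' @param n_boot Bootstrap iterations for ROC confidence intervals.
#' @param outlier_removal Sample ids confirmed for removal after
#'   inspecting the QC outlier flags (two-pass workflow: flag, inspect,
#'   confirm).
#' @param seed Master seed for folds, permutations and bootstrap.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_config(),
                            log_transform = TRUE,
                            pseudocount = 1,
                            n_ortho = 1,
                            n_perm = 999,
                            n_folds = 7,
                            splot_cutoff = 0.05,
                            fspls = fspls_config(),
                            screen = c("age_median_split", "sex"),
                            screen_alpha = 0.05,
                            screen_moderated = FALSE,
                            n_boot = 500,
                            outlier_removal = character(0),
                            seed = 1) {
  stopifnot(inherits(qc, "qc_config"), inherits(fspls, "fspls_config"))
  if (!all(screen %in% c("age_median_split", "sex"))) {
    rlang::abort("screen must be a subset of c('age_median_split','sex')",
                 class = "lipidsig_error")
  }
  structure(list(qc = qc, log_transform = log_transform,
                 pseudocount = pseudocount, n_ortho = n_ortho,
                 n_perm = n_perm, n_folds = n_folds,
                 splot_cutoff = splot_cutoff, fspls = fspls,
                 screen = screen, screen_alpha = screen_alpha,
                 screen_moderated = screen_moderated, n_boot = n_boot,
                 outlier_removal = as.character(outlier_removal),
                 seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the reconstructed
#'   [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    qc = do.call(qc_config, x$qc),
    log_transform = x$log_transform, pseudocount = x$pseudocount,
    n_ortho = x$n_ortho, n_perm = x$n_perm, n_folds = x$n_folds,
    splot_cutoff = x$splot_cutoff,
    fspls = do.call(fspls_config, x$fspls),
    screen = unlist(x$screen), screen_alpha = x$screen_alpha,
    screen_moderated = x$screen_moderated, n_boot = x$n_boot,
    outlier_removal = as.character(unlist(x$outlier_removal)),
    seed = x$seed)
}

#' Run the full biomarker-discovery pipeline
#'
#' QC filtering -> confirmed outlier removal -> log transform -> pareto
#' scaling -> PCA summary -> OPLS-DA with cross-validated Q2 and label
#' permutation validation -> S-plot shortlist -> age/sex covariate screen
#' -> FS-PLS signature selection with robustness check -> disease risk
#' score and ROC evaluation. If the OPLS-DA model is not valid (Q2 <= 0
#' or permutation p >= 0.05) the signature stages are skipped with a
#' warning, the behaviour expected of degenerate (e.g. label-independent)
#' data. The run is fully reproducible from the config and its seeds.
#'
#' @param table A raw-scale [feature_table()].
#' @param config A [pipeline_config()].
#' @return A `run_report` (see [report_markdown()]): feature counts per
#'   stage, the fitted models, the validity verdict, the signature and
#'   the evaluation summaries.
#' @export
run_discovery <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "lipidsig_error")
    })
  }
  n_acquired <- ncol(table$intensities)

  qc <- stage("qc", apply_qc(table, config$qc))
  tab <- qc$table
  if (length(config$outlier_removal) > 0) {
    unknown <- setdiff(config$outlier_removal, tab$samples$sample_id)
    if (length(unknown) > 0) {
      rlang::abort(sprintf("outlier_removal names unknown sample(s): %s",
                           paste(unknown, collapse = ", ")),
                   class = "lipidsig_error")
    }
    tab <- ft_subset(tab, samples = setdiff(tab$samples$sample_id,
                                            config$outlier_removal))
  }
  if (config$log_transform) {
    tab <- stage("log_transform", log_transform(tab, config$pseudocount))
  }
  y <- class_vector(tab)
  scaled <- stage("pareto_scale", pareto_scale(tab$intensities))
  pca <- stage("pca", fit_pca(scaled, k = min(2, nrow(tab$intensities) - 1)))
  opls <- stage("oplsda", fit_oplsda(scaled, y, config$n_ortho))
  cv <- stage("q2", cross_validated_q2(scaled, y, config$n_ortho,
                                       config$n_folds, seed = config$seed,
                                       return_scores = TRUE))
  opls$q2_cum <- cv$q2
  perm <- stage("permutation", permutation_test(
    scaled, y, config$n_ortho, config$n_perm, seed = config$seed,
    n_folds = config$n_folds))

  report <- list(
    counts = c(acquired = n_acquired,
               qc_retained = sum(qc$report$features$retained)),
    qc_report = qc$report,
    removed_samples = config$outlier_removal,
    pca = pca, opls = opls, cv_scores = cv$cv_scores,
    permutation = perm, valid = perm$valid,
    splot = NULL, screen = NULL, fspls = NULL, robustness = NULL,
    signature = NULL, drs = NULL, roc_signature = NULL,
    single_features = NULL,
    config = config,
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      timestamp = format(Sys.time(), tz = "UTC"),
                      n_study_samples = nrow(tab$intensities))
  )

  if (!perm$valid) {
    warning("OPLS-DA model not valid (Q2 <= 0 or permutation p >= 0.05); ",
            "signature selection skipped", call. = FALSE)
    report$counts <- c(report$counts, shortlisted = 0L, screened = 0L,
                       signature = 0L)
    return(structure(report, class = "run_report"))
  }

  sp <- stage("s_plot", s_plot(opls, scaled, config$splot_cutoff))
  shortlist <- sp$feature_id[sp$shortlisted]
  report$splot <- sp
  report$counts <- c(report$counts, shortlisted = length(shortlist))
  if (length(shortlist) < 2) {
    warning("fewer than 2 shortlisted features; signature selection skipped",
            call. = FALSE)
    report$counts <- c(report$counts, screened = 0L, signature = 0L)
    return(structure(report, class = "run_report"))
  }

  screen <- purrr::map(config$screen, function(g) {
    stage(paste0("screen_", g),
          diff_abundance(tab, grouping = g, features = shortlist,
                         moderated = config$screen_moderated))
  })
  names(screen) <- config$screen
  screen_tbl <- dplyr::bind_rows(screen, .id = "grouping")
  report$screen <- screen_tbl

  X <- tab$intensities[, shortlist, drop = FALSE]
  rob <- stage("fspls", robustness_check(X, y, screen_tbl, config$fspls,
                                         alpha = config$screen_alpha))
  report$fspls <- rob$full
  report$robustness <- rob
  n_screened <- length(setdiff(shortlist, rob$removed_features))
  report$counts <- c(report$counts, screened = n_screened)

  if (nrow(rob$full$selected) == 0) {
    warning("FS-PLS selected no features at the configured p_thresh",
            call. = FALSE)
    report$counts <- c(report$counts, signature = 0L)
    return(structure(report, class = "run_report"))
  }
  sig <- signature_of(rob$full)
  report$signature <- sig
  report$counts <- c(report$counts, signature = nrow(sig))

  drs <- stage("drs", disease_risk_score(tab, sig))
  report$drs <- drs
  report$roc_signature <- stage("roc", bootstrap_ci(
    drs$drs, class_vector(tab), n_boot = config$n_boot, seed = config$seed))
  report$single_features <- stage("single_roc", rank_single_features(
    tab, shortlist, n_boot = config$n_boot, seed = config$seed))

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(report_markdown(x))
  invisible(x)
}

#' Render a run report as markdown text
#'
#' @param report A `run_report` from [run_discovery()].
#' @return A single markdown string with stage counts, model metrics,
#'   validity verdict, signature and evaluation summaries.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "run_report"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("# Biomarker discovery run")
  add("")
  add("Feature counts: %s",
      paste(sprintf("%s = %d", names(report$counts), report$counts),
            collapse = " -> "))
  if (length(report$removed_samples) > 0) {
    add("Confirmed outlier sample(s) removed: %s",
        paste(report$removed_samples, collapse = ", "))
  }
  add("")
  add("## Model")
  add("R2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f",
      report$opls$r2x_cum, report$opls$r2y_cum, report$opls$q2_cum)
  add("Permutation p = %.4g (%d permutations); model %s.",
      report$permutation$p_value, report$permutation$n_perm,
      if (report$valid) "VALID" else
        "NOT VALID - signature selection was skipped")
  if (!is.null(report$signature)) {
    add("")
    add("## Signature (%d features)", nrow(report$signature))
    for (i in seq_len(nrow(report$signature))) {
      add("- %s (%s, weight %.3f)", report$signature$feature_id[i],
          report$signature$direction[i], report$signature$weight[i])
    }
    add("Robustness to covariate screen: signatures %s.",
        if (report$robustness$agreement) "agree" else "DIFFER")
    add("")
    add("## Evaluation")
    add("Signature DRS AUC = %.3f (95%% CI %.3f-%.3f, %d bootstrap iterations)",
        report$roc_signature$auc, report$roc_signature$ci_lower,
        report$roc_signature$ci_upper, report$roc_signature$n_boot)
    top <- report$single_features[1, ]
    add("Best single feature: %s, AUC = %.3f", top$feature_id, top$auc)
  }
  paste0(paste(ln, collapse = "\n"), "\n")
}
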