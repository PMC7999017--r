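#' Load a run configuration from YAML or JSON
#'
#' The document mirrors the argument names of [cohort_config()] (section
#' `cohort`), [preprocess_config()] (section `preprocess`) and the
#' chemometrics flags (section `chemometrics`: `n_pcs`, `linkage`,
#' `pca_outside_cv`), plus optional top-level `seed`, `manifest` and
#' `out_dir`. Missing fields fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A nested list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(cohort = raw$cohort, preprocess = raw$preprocess,
             chemometrics = raw$chemometrics, seed = raw$seed,
             manifest = raw$manifest, out_dir = raw$out_dir)
}

#' @rdname load_run_config
#' @param cohort,preprocess,chemometrics Named lists of overrides for the
#'   respective config constructors.
#' @param seed Integer seed for the run.
#' @param manifest Optional manifest path; when given, spectra are read from
#'   disk instead of simulated.
#' @param out_dir Output directory.
#' @export
run_config <- function(cohort = NULL, preprocess = NULL, chemometrics = NULL,
                       seed = 1L, manifest = NULL, out_dir = NULL) {
  seed <- as.integer(seed %||% 1L)
  cohort <- cohort %||% list()
  if (is.null(cohort$seed)) cohort$seed <- seed
  cfg <- list(
    cohort = do.call(cohort_config, cohort),
    preprocess = do.call(preprocess_config, preprocess %||% list()),
    chemometrics = utils::modifyList(
      list(n_pcs = 15L, linkage = "ward.D2", pca_outside_cv = FALSE),
      chemometrics %||% list()),
    seed = seed, manifest = manifest, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis end to end
#'
#' Generates (or loads) a cohort, preprocesses it, computes group mean and
#' difference spectra with differential-band assignment, and fits the
#' PCA-LDA classification model with spectrum-level leave-one-out
#' cross-validation, ROC/AUC, hierarchical clustering of the canonical
#' variable and a one-way ANOVA on CV1. All tables are written as CSV plus a
#' short markdown report; outputs are identical for identical config + seed.
#'
#' @param config A [run_config()] (or path to a YAML/JSON file).
#' @param out_dir Output directory (overrides the config's).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with every intermediate result (`cohort`,
#'   `preprocessed`, `means`, `difference`, `differential_table`, `pca`,
#'   `loocv`, `metrics`, `roc`, `clustering`, `anova`, `counts`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$manifest)) {
    say("reading cohort from %s", config$manifest)
    set <- read_manifest(config$manifest)
    substrate <- NULL
    cohort <- list(set = set, truth = NULL)
  } else {
    say("simulating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$cohort)
    set <- cohort$set
    substrate <- generate_substrate_spectrum(config$cohort)
  }
  say("preprocessing %d spectra", n_spectra(set))
  pp <- preprocess_pipeline(set, substrate = substrate,
                            config = config$preprocess)
  say("kept %d / %d spectra (%d fluorescence, %d de-focus rejected)",
      pp$counts[["processed"]], pp$counts[["input"]],
      pp$counts[["rejected_fluorescence"]], pp$counts[["rejected_defocus"]])
  proc <- pp$processed

  mean_copd <- group_mean_sd(proc, "COPD")
  mean_ctrl <- group_mean_sd(proc, "CTRL")
  diff <- difference_spectrum(mean_copd, mean_ctrl)
  tab <- read_attribution_table()
  diff_tab <- assign_differential_peaks(diff, tab)

  m <- spectra_matrix(proc)
  labels <- proc$meta$group
  pca <- fit_pca(m)
  n_pcs <- min(config$chemometrics$n_pcs, ncol(pca$scores))
  lda <- fit_lda(pca$scores[, seq_len(n_pcs), drop = FALSE], labels)
  cv <- loocv(m, labels, n_pcs = n_pcs,
              pca_outside_cv = config$chemometrics$pca_outside_cv)
  metrics <- compute_metrics(cv)
  roc <- roc_auc(cv$predictions$score, labels)
  clu <- hcluster_cv(lda$cv1, labels, linkage = config$chemometrics$linkage)
  anova <- compare_cv_distributions(lda$cv1, labels)

  res <- list(cohort = cohort, preprocessed = pp,
              means = list(COPD = mean_copd, CTRL = mean_ctrl),
              difference = diff, differential_table = diff_tab,
              pca = pca, lda = lda, loocv = cv, metrics = metrics, roc = roc,
              clustering = clu, anova = anova, counts = pp$counts)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir, n_pcs = n_pcs)
  invisible(res)
}

write_run_outputs <- function(res, out_dir, n_pcs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  m <- spectra_matrix(res$preprocessed$processed)
  w(as.data.frame(m), "processed_matrix.csv")
  w(res$preprocessed$processed$meta, "manifest_processed.csv")
  for (g in c("COPD", "CTRL")) {
    ms <- res$means[[g]]
    w(data.frame(wavenumber = ms$grid, mean = ms$mean, sd = ms$sd),
      sprintf("mean_%s.csv", tolower(g)))
  }
  w(data.frame(wavenumber = res$difference$grid, delta = res$difference$delta,
               error = res$difference$error), "difference_spectrum.csv")
  w(res$differential_table, "differential_peaks.csv")
  k <- min(n_pcs, ncol(res$pca$scores))
  sc <- as.data.frame(res$pca$scores[, seq_len(k), drop = FALSE])
  names(sc) <- paste0("PC", seq_len(k))
  sc$CV1 <- res$lda$cv1
  sc$group <- res$preprocessed$processed$meta$group
  sc$loocv_predicted <- res$loocv$predictions$predicted
  sc$loocv_score <- res$loocv$predictions$score
  w(sc, "scores.csv")
  mt <- res$metrics
  w(data.frame(Accuracy = mt$accuracy, Sensitivity = mt$sensitivity,
               Specificity = mt$specificity, Precision = mt$precision,
               ER = mt$error_rate, MCC = mt$mcc, `ROC-AUC` = res$roc$auc,
               check.names = FALSE), "metrics.csv")
  w(res$roc$points, "roc_points.csv")
  w(data.frame(res$clustering$hclust$merge,
               height = res$clustering$hclust$height), "dendrogram_merges.csv")
  report <- c(
    "# Salivary Raman fingerprint run report", "",
    sprintf("- Spectra in: %d; kept after artifact screening: %d (%d fluorescence, %d de-focus rejected)",
            res$counts[["input"]], res$counts[["processed"]],
            res$counts[["rejected_fluorescence"]],
            res$counts[["rejected_defocus"]]),
    sprintf("- Differential bands (|dI| >= 0.005): %d", nrow(res$differential_table)),
    sprintf("- First %d PCs explain %.1f%% of variance", k,
            100 * sum(res$pca$var_fraction[seq_len(k)])),
    sprintf("- LOOCV: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, precision %.1f%%, ER %.2f%%, MCC %.3f, ROC-AUC %.3f",
            100 * mt$accuracy, 100 * mt$sensitivity, 100 * mt$specificity,
            100 * mt$precision, 100 * mt$error_rate, mt$mcc, res$roc$auc),
    sprintf("- Hierarchical 2-cluster Rand index vs labels: %.3f",
            res$clustering$rand),
    sprintf("- One-way ANOVA on CV1: F = %.2f, p = %.3g",
            res$anova$statistic, res$anova$p_value))
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
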