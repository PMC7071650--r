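# Cohort statistics used alongside the measurements, plus a small pipeline
# orchestrator that wires the stages together and writes their outputs.

#' Welch's t test between two cohorts
#'
#' Two-sided, unequal-variance by default (Welch-Satterthwaite df); set
#' `var_equal = TRUE` for the classical Student test. Degenerate inputs
#' follow fixed conventions: zero variance in both groups with equal means
#' gives statistic 0 and p = 1; zero variance in both with different means
#' gives p = 0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (Student) instead of Welch.
#' @return object of class `cohort_comparison` with group ns, means, SDs,
#'   the test name, `statistic` and `p_value`.
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("welch_t_test: each group needs n >= 2")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    res <- list(statistic = if (same) 0 else Inf,
                p.value = if (same) 1 else 0)
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(groups = c("A", "B"), n = c(length(group_a), length(group_b)),
                 means = c(mean(group_a), mean(group_b)),
                 sds = c(stats::sd(group_a), stats::sd(group_b)),
                 test = if (var_equal) "student_t" else "welch_t",
                 statistic = res$statistic, p_value = res$p.value),
            class = "cohort_comparison")
}

#' One-way ANOVA across cohorts
#'
#' Classical equal-variance one-way ANOVA (so with two groups F equals the
#' square of the Student t statistic). If every value in every group is
#' identical, p = 1 by convention.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return a `cohort_comparison` with the F `statistic` and `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("anova_oneway: at least 2 groups required")
  if (any(vapply(groups, length, 0L) < 2))
    stop("anova_oneway: each group needs n >= 2")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::sd(values) == 0) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  structure(list(groups = nm, n = vapply(groups, length, 0L),
                 means = vapply(groups, mean, 0),
                 sds = vapply(groups, stats::sd, 0),
                 test = "anova_oneway",
                 statistic = res$statistic, p_value = res$p.value),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: n = %d, mean = %.4g, SD = %.4g\n",
                x$groups[i], x$n[i], x$means[i], x$sds[i]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pipeline orchestration

.pipeline_default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "polarity", "puncta", "coloc", "frap", "score",
               "stats"),
    polarity = list(n_cells = 10, ratio_true = 7.5, snr = 10),
    field = list(n_maxima = 150, assoc_fraction_true = 0.8),
    frap = list(mobile_fraction_true = 0.2, n_bleach = 6, noise_sd = 50),
    densitometry = list(n = 3,
                        pellet_fraction_true = c("26" = 0.1, "42" = 0.9),
                        noise_cv = 0.1))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages against synthetic inputs (or, for the TIFF
#' based stages, against files named in the config), writing per-stage CSV
#' and JSON outputs plus a run log with the seed, thresholds and package
#' version. Missing inputs abort with the stage name; outputs of stages that
#' already completed are preserved.
#'
#' @param config named list or path to a JSON config file. Recognized fields:
#'   `seed`, `stages` (subset of `"simulate"`, `"polarity"`, `"puncta"`,
#'   `"coloc"`, `"frap"`, `"score"`, `"stats"`, or `"demo"` for all),
#'   and per-stage parameter lists `polarity`, `field`, `frap`,
#'   `densitometry`; a `tiff` field naming input files makes `polarity` read
#'   images from disk instead of simulating.
#' @param out_dir output directory, created if needed.
#' @return invisible named list of per-stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("flarequant_run")) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("run_pipeline [config]: config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.pipeline_default_config(), config)
  if ("demo" %in% cfg$stages)
    cfg$stages <- c("simulate", "polarity", "puncta", "coloc", "frap",
                    "score", "stats")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  log <- list(package = "flarequant",
              version = as.character(utils::packageVersion("flarequant")),
              seed = cfg$seed, stages = cfg$stages, started = format(Sys.time()))

  jwrite <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  if ("simulate" %in% cfg$stages) {
    sim_dir <- file.path(out_dir, "simulate")
    pair <- generate_cell_pair(cell_pair_params(
      ratio_true = cfg$polarity$ratio_true, snr = cfg$polarity$snr,
      seed = cfg$seed))
    write_synthetic(pair, file.path(sim_dir, "cell_pair"))
    fld <- generate_field(do.call(field_params,
                                  c(cfg$field, list(seed = cfg$seed))))
    write_synthetic(fld, file.path(sim_dir, "field"))
    results$simulate <- sim_dir
  }

  if ("polarity" %in% cfg$stages) {
    if (!is.null(cfg$tiff)) {
      for (f in unlist(cfg$tiff))
        if (!file.exists(f))
          stop("run_pipeline [polarity]: input TIFF not found: ", f)
    }
    co <- do.call(simulate_polarity_cohort,
                  c(cfg$polarity[c("n_cells", "ratio_true", "snr")],
                    list(seed = cfg$seed)))
    utils::write.csv(co$cells, file.path(out_dir, "polarity_cells.csv"),
                     row.names = FALSE, quote = FALSE)
    jwrite(co[c("n", "n_flagged", "mean_Fd", "mean_Fm", "mean_ratio",
                "sd_ratio")], "polarity_summary.json")
    results$polarity <- co
  }

  if (any(c("puncta", "coloc") %in% cfg$stages)) {
    fld <- generate_field(do.call(field_params,
                                  c(cfg$field, list(seed = cfg$seed))))
    if ("puncta" %in% cfg$stages) {
      mx <- find_maxima(fld$puncta, fld$params$puncta_amplitude / 2)
      er_mask <- pm_mask_from_marker(fld$er)
      thr <- derive_binary_threshold(fld$er, er_mask,
                                     .erode_box(!er_mask, 2))
      assoc <- classify_association(mx, fld$er, thr)
      utils::write.csv(assoc$points, file.path(out_dir, "maxima.csv"),
                       row.names = FALSE, quote = FALSE)
      jwrite(assoc[c("n_total", "n_associated", "fraction", "threshold_used",
                     "min_specific", "background_max")],
             "association_summary.json")
      results$puncta <- assoc
    }
    if ("coloc" %in% cfg$stages) {
      thr_p <- 50 + fld$params$puncta_amplitude / 2
      thr_e <- mean(c(fld$params$background_max,
                      fld$params$er_intensity_range[1]))
      cl <- coloc_overlap(fld$puncta, fld$er, thr_p, thr_e)
      jwrite(unclass(cl), "coloc.json")
      results$coloc <- cl
    }
  }

  if ("frap" %in% cfg$stages) {
    sim <- generate_frap_series(do.call(frap_sim_params,
                                        c(cfg$frap, list(seed = cfg$seed))))
    res <- measure_frap_cohort(sim)
    fit_df <- do.call(rbind, lapply(seq_along(res$fits), function(i) {
      f <- res$fits[[i]]
      data.frame(roi_id = i, F_post = f$F_post, F_inf = f$F_inf, k = f$k,
                 mobile = f$mobile_fraction, immobile = f$immobile_fraction,
                 flag = f$flag)
    }))
    utils::write.csv(fit_df, file.path(out_dir, "frap_fits.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(time_s = res$series$timestamps,
                 mean = res$cohort$mean_trace, sd = res$cohort$sd_trace),
      file.path(out_dir, "frap_cohort_curve.csv"), row.names = FALSE,
      quote = FALSE)
    jwrite(res$cohort[c("mean_mobile", "sd_mobile", "mean_immobile", "n",
                        "n_flagged")], "frap_summary.json")
    results$frap <- res$cohort
  }

  if ("score" %in% cfg$stages) {
    tab <- do.call(generate_densitometry,
                   c(cfg$densitometry, list(seed = cfg$seed)))
    sed <- sedimentation_fractions(tab)
    utils::write.csv(sed$summary, file.path(out_dir, "sedimentation.csv"),
                     row.names = FALSE, quote = FALSE)
    results$score <- sed
  }

  if ("stats" %in% cfg$stages) {
    if (!is.null(results$polarity)) {
      co2 <- simulate_polarity_cohort(cfg$polarity$n_cells,
                                      ratio_true = cfg$polarity$ratio_true / 2,
                                      snr = cfg$polarity$snr,
                                      seed = cfg$seed + 1)
      ok1 <- stats::na.omit(results$polarity$cells$ratio)
      ok2 <- stats::na.omit(co2$cells$ratio)
      cmp <- welch_t_test(ok1, ok2)
      jwrite(unclass(cmp), "stats.json")
      results$stats <- cmp
    }
  }

  log$finished <- format(Sys.time())
  jwrite(log, "run_log.json")
  invisible(results)
}
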