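## End-to-end experiment driver: simulate (or load) a two-group cohort,
## measure every acquisition, compare groups metric by metric with one-way
## ANOVA + post-hoc, and emit a reproducible report.

morphometry_metrics <- c("n_somata", "n_branches", "n_junctions",
                         "total_branch_length_um", "avg_branch_length_um")

#' Experiment configuration
#'
#' Either a simulated design (two generator parameter sets) or a
#' pre-computed metrics table.
#'
#' @param params_wt,params_ko [generator_params()] for the two groups
#'   (simulation mode).
#' @param n_images_per_group Acquisitions per replicate per group.
#' @param n_replicates Biological replicates per group.
#' @param master_seed Master seed controlling the whole cohort.
#' @param metrics Optional pre-computed metrics data.frame (or CSV path);
#'   when given, simulation is skipped.
#' @param masking [masking_params()] used by the measurement stage.
#' @param posthoc Post-hoc method, `"tukey"` or `"bonferroni"`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(params_wt = generator_params(),
                              params_ko = NULL,
                              n_images_per_group = 10L,
                              n_replicates = 3L,
                              master_seed = 1L,
                              metrics = NULL,
                              masking = masking_params(),
                              posthoc = "tukey") {
  if (is.null(metrics) && is.null(params_ko))
    stop("either `metrics` or both parameter sets must be given")
  structure(list(params_wt = params_wt, params_ko = params_ko,
                 n_images_per_group = as.integer(n_images_per_group),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 metrics = metrics, masking = masking, posthoc = posthoc),
            class = "experiment_config")
}

#' Run a full two-group experiment
#'
#' Simulation mode streams the cohort: each acquisition is generated from
#' its per-image seed, measured, and discarded, so memory stays flat.
#' Ground-truth metrics are collected alongside the measured ones. Each
#' morphometry metric is then compared across groups with
#' [anova_multicompare()]. Fully reproducible under the master seed.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_report`: `metrics` (measured,
#'   per-acquisition), `truth_metrics` (simulation mode only),
#'   `comparisons` (per metric), `config` echo and package version.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop("`config` must be an experiment_config")
  truth_metrics <- NULL
  if (is.null(config$metrics)) {
    if (config$n_images_per_group * config$n_replicates < 2L)
      stop("fewer than 2 images per group: group comparison is undefined")
    plan <- cohort_plan(config$n_images_per_group, config$n_replicates,
                        config$master_seed)
    rows <- vector("list", nrow(plan))
    trows <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      p <- if (plan$group[i] == "WT") config$params_wt else config$params_ko
      p$seed <- plan$seed[i]
      g <- generate_acquisition(p)
      rows[[i]] <- measure_acquisition(g$acquisition, config$masking,
                                       image_id = plan$image_id[i],
                                       group = plan$group[i],
                                       replicate = plan$replicate[i])
      trows[[i]] <- cbind(data.frame(image_id = plan$image_id[i],
                                     group = plan$group[i],
                                     replicate = plan$replicate[i],
                                     stringsAsFactors = FALSE),
                          g$truth$true_metrics)
    }
    metrics <- do.call(rbind, rows)
    truth_metrics <- do.call(rbind, trows)
  } else {
    metrics <- config$metrics
    if (is.character(metrics)) {
      if (!file.exists(metrics))
        stop("metrics file not found: ", metrics)
      metrics <- utils::read.csv(metrics, stringsAsFactors = FALSE)
    }
  }
  n_per <- table(metrics$group)
  if (any(n_per < 2))
    stop("group(s) with fewer than 2 acquisitions: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  # n_somata is constant by design when groups share n_cells; a metric with
  # no within-group variance anywhere yields a degenerate record, not an
  # error, so the remaining comparisons still run
  comparisons <- lapply(morphometry_metrics, function(m)
    tryCatch(anova_multicompare(metrics, m, posthoc = config$posthoc),
             error = function(e)
               structure(list(metric = m, degenerate = TRUE,
                              reason = conditionMessage(e)),
                         class = "group_comparison")))
  names(comparisons) <- morphometry_metrics
  structure(list(metrics = metrics,
                 truth_metrics = truth_metrics,
                 comparisons = comparisons,
                 config = config,
                 version = as.character(utils::packageVersion("neuromorph"))),
            class = "experiment_report")
}

#' Write an experiment report to JSON (plus metrics CSV)
#'
#' The JSON embeds the comparisons, per-group summaries, the master seed
#' and the package version; regeneration from the same metrics table is
#' bit-identical.
#'
#' @param report An `experiment_report`.
#' @param path Output JSON path.
#' @param metrics_csv Optional path for the per-acquisition metrics CSV.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, metrics_csv = NULL) {
  comp <- lapply(report$comparisons, function(x) {
    if (isTRUE(x$degenerate))
      return(list(metric = x$metric, degenerate = TRUE, reason = x$reason))
    list(metric = x$metric, groups = x$groups, n = x$n,
         F = x$F, p_value = x$p_value, posthoc = x$posthoc,
         pairwise = x$pairwise, summary = x$summary)
  })
  jsonlite::write_json(
    list(version = report$version,
         master_seed = report$config$master_seed,
         posthoc = report$config$posthoc,
         comparisons = comp),
    path, digits = 10, auto_unbox = TRUE)
  if (!is.null(metrics_csv)) write_metrics_csv(report$metrics, metrics_csv)
  invisible(path)
}

#' Boxplots of the morphometry metrics by group
#'
#' Base-graphics boxplots following the reporting convention of the
#' morphometry figures (median line, 25th-75th percentile box, outlier
#' dots).
#'
#' @param metrics Per-acquisition metrics data.frame.
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @return Invisibly, `NULL`.
#' @export
plot_metric_boxplots <- function(metrics, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 1500, height = 320)
  op <- graphics::par(mfrow = c(1, length(morphometry_metrics)),
                      mar = c(3, 4, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (m in morphometry_metrics)
    graphics::boxplot(metrics[[m]] ~ metrics$group, range = 1.5,
                      pch = 16, col = "grey85", main = m,
                      xlab = "", ylab = m)
  invisible(NULL)
}
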