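## Group statistics matching the reporting conventions of the morphometry
## figures: one-way ANOVA with a post-hoc multiple-comparison test,
## boxplot summaries (median, quartiles, Tukey-fence outliers) and the
## classical two-group Student t test.

#' Significance stars
#'
#' `*`, `**`, `***`, `****` at p <= 0.05, 0.01, 0.001, 0.0001; `"ns"`
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Boxplot summary with Tukey fences
#'
#' Quartiles use the linear-interpolation rule (R quantile type 7) so the
#' numbers are reproducible bit-exactly; outliers are the values outside
#' `[q25 - 1.5 IQR, q75 + 1.5 IQR]`.
#'
#' @param values Numeric vector (length >= 1, no NAs).
#' @return A list: `median`, `q25`, `q75`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values) || anyNA(values)) stop("values must be non-empty and NA-free")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(median = q[2], q25 = q[1], q75 = q[3],
       outliers = values[values < q[1] - 1.5 * iqr |
                         values > q[3] + 1.5 * iqr])
}

#' Two-group Student t test
#'
#' Two-tailed; the unpaired form uses the classical equal-variance
#' (pooled) statistic, the paired form the differences.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param paired If `TRUE`, a paired test (equal lengths required).
#' @return A list: `statistic` (t), `df`, `p_value`, `stars`.
#' @export
two_group_ttest <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (paired && length(values_a) != length(values_b))
    stop("paired test requires equal-length groups")
  ht <- stats::t.test(values_a, values_b, paired = paired,
                      var.equal = TRUE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, stars = significance_stars(ht$p.value))
}

#' One-way ANOVA with post-hoc multiple comparisons
#'
#' Omnibus one-way ANOVA across groups followed by all pairwise post-hoc
#' comparisons with a family-wise correction: Tukey's HSD (default) or
#' Bonferroni-adjusted pairwise t tests on the pooled residual variance.
#' Stars follow the convention of [significance_stars()]. Per-group
#' boxplot summaries are attached.
#'
#' @param metrics A data.frame of per-acquisition metrics.
#' @param metric Name of the numeric column to compare.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @return A list of class `group_comparison`: `metric`, `groups`, `n`,
#'   `F`, `p_value`, `posthoc` method, `pairwise` (data.frame `pair`,
#'   `diff`, `p_adj`, `stars`), `summary` (per-group boxplot summaries).
#' @export
anova_multicompare <- function(metrics, metric, group_col = "group",
                               posthoc = c("tukey", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  if (!metric %in% names(metrics)) stop("unknown metric: ", metric)
  values <- metrics[[metric]]
  groups <- factor(metrics[[group_col]])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n_per <- table(groups)
  small <- names(n_per)[n_per < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  if (all(tapply(values, groups, stats::var) == 0))
    stop("zero within-group variance everywhere: F is undefined")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  pairwise <- if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$groups
    data.frame(pair = rownames(tk), diff = tk[, "diff"],
               p_adj = tk[, "p adj"], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    raw <- apply(cmb, 2, function(pr) {
      a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
      # pooled-variance pairwise t on the ANOVA residual MS
      mse <- an["Residuals", "Mean Sq"]
      dfr <- an["Residuals", "Df"]
      t <- (mean(b) - mean(a)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
      c(diff = mean(b) - mean(a), p = 2 * stats::pt(-abs(t), dfr))
    })
    data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
               diff = raw["diff", ],
               p_adj = pmin(raw["p", ] * ncol(cmb), 1),
               stringsAsFactors = FALSE)
  }
  pairwise$stars <- significance_stars(pairwise$p_adj)
  structure(list(metric = metric,
                 groups = levels(groups),
                 n = as.integer(n_per),
                 F = an["groups", "F value"],
                 p_value = an["groups", "Pr(>F)"],
                 posthoc = posthoc,
                 pairwise = pairwise,
                 summary = lapply(split(values, groups), boxplot_summary)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("%s: no comparison (%s)\n", x$metric, x$reason))
    return(invisible(x))
  }
  cat(sprintf("%s: one-way ANOVA F = %.4g, p = %.3g (%s post-hoc)\n",
              x$metric, x$F, x$p_value, x$posthoc))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
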