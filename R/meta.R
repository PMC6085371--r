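#' Study-level effect sizes for the weighted synthesis
#'
#' Builds the effect-size table from per-study flux summaries. The weighting
#' factor is the inverse squared standard error assembled from the study's
#' posterior SD and replicate count: `W* = n / s^2` (a convention honouring
#' "weighed with the variation and sample size in individual studies"; the
#' exact historical MetaWin formula is not recoverable).
#'
#' @param summaries data frame with columns `study_id`, `metric`, `mean`,
#'   `sd`, `n` and optionally `nc_category` (rows from
#'   [standardized_summary()] or [experiment_synthesis()]).
#' @param metric optional filter on the `metric` column.
#' @param min_sd floor on `sd` to keep weights finite for degenerate
#'   (zero-spread) posteriors.
#' @return data frame of class `soc_effects` with columns `study_id`,
#'   `metric`, `mean`, `weight`, `n`, `nc_category`.
#' @export
effect_sizes <- function(summaries, metric = NULL, min_sd = 1e-6) {
  if (!is.null(metric)) summaries <- summaries[summaries$metric == metric, ]
  if (nrow(summaries) == 0) stop("no effects to synthesize")
  if (is.null(summaries$nc_category)) summaries$nc_category <- "none"
  s <- pmax(summaries$sd, min_sd)
  out <- data.frame(study_id = summaries$study_id, metric = summaries$metric,
                    mean = summaries$mean,
                    weight = summaries$n / s^2,
                    n = summaries$n, nc_category = summaries$nc_category)
  class(out) <- c("soc_effects", "data.frame")
  out
}

#' Weighted mean effect and 95% confidence interval
#'
#' `M = sum(W* M_j) / sum(W*)`, `V = 1 / sum(W*)`,
#' `CI = M +/- 1.96 sqrt(V)`. The effect is flagged significant when the CI
#' excludes zero.
#'
#' @param effects a `soc_effects` data frame (or any data frame with `mean`
#'   and `weight` columns), `k >= 1` rows.
#' @return list `(mean, variance, ci_lo, ci_hi, k, significant)`.
#' @export
weighted_mean_ci <- function(effects) {
  k <- nrow(effects)
  if (is.null(k) || k == 0) stop("no studies supplied")
  stopifnot(all(effects$weight > 0))
  m <- sum(effects$weight * effects$mean) / sum(effects$weight)
  v <- 1 / sum(effects$weight)
  half <- 1.96 * sqrt(v)
  list(mean = m, variance = v, ci_lo = m - half, ci_hi = m + half, k = k,
       significant = (m - half) > 0 || (m + half) < 0)
}

#' Per-group synthesis with pairwise CI-overlap significance
#'
#' Weighted mean and 95% CI per substrate N:C category (or any grouping
#' column); a pairwise difference is flagged significant when the two 95%
#' CIs do not overlap.
#'
#' @param effects a `soc_effects` data frame.
#' @param grouping column name to group by (default `"nc_category"`).
#' @return list with `groups` (data frame: group, mean, ci_lo, ci_hi, k,
#'   significant-vs-zero) and `pairwise` (data frame: group1, group2,
#'   significant).
#' @export
group_synthesis <- function(effects, grouping = "nc_category") {
  if (!grouping %in% names(effects)) stop("unknown grouping column")
  gs <- split(effects, effects[[grouping]])
  res <- lapply(gs, weighted_mean_ci)
  groups <- data.frame(
    group = names(res),
    mean = vapply(res, `[[`, numeric(1), "mean"),
    ci_lo = vapply(res, `[[`, numeric(1), "ci_lo"),
    ci_hi = vapply(res, `[[`, numeric(1), "ci_hi"),
    k = vapply(res, `[[`, numeric(1), "k"),
    significant = vapply(res, `[[`, logical(1), "significant"),
    row.names = NULL)
  pw <- NULL
  if (nrow(groups) > 1) {
    cmb <- utils::combn(nrow(groups), 2)
    pw <- data.frame(
      group1 = groups$group[cmb[1, ]], group2 = groups$group[cmb[2, ]],
      significant = groups$ci_lo[cmb[1, ]] > groups$ci_hi[cmb[2, ]] |
        groups$ci_lo[cmb[2, ]] > groups$ci_hi[cmb[1, ]])
  }
  list(groups = groups, pairwise = pw)
}
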