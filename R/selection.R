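#' Deviance information criterion from a posterior chain
#'
#' `Dbar` is the mean over retained samples of `-2 log P(Z | theta)`; the
#' effective parameter count is `p_D = Dbar - D(theta_bar)` with `theta_bar`
#' the sample mean; `DIC = Dbar + p_D`. The likelihood is the calibration
#' likelihood up to its additive constant, which cancels in model comparison.
#'
#' @param chain a `soc_chain` (or the list returned by [read_chain()]).
#' @param log_lik log-likelihood function for `D(theta_bar)`; defaults to the
#'   [study_objective()] of the chain's attached model and study.
#' @param spec,obs used to rebuild the objective when `log_lik` is missing.
#' @return named vector `c(Dbar, p_D, DIC)`.
#' @export
dic <- function(chain, log_lik = NULL, spec = attr(chain, "spec"),
                obs = attr(chain, "obs")) {
  if (is.null(chain$samples) || nrow(chain$samples) == 0)
    stop("empty chain")
  if (is.null(log_lik)) {
    if (is.null(spec) || is.null(obs))
      stop("provide log_lik or a chain with attached spec/obs")
    log_lik <- study_objective(spec, obs)
  }
  dbar <- mean(-2 * chain$log_lik)
  theta_bar <- colMeans(chain$samples)
  ll_bar <- log_lik(theta_bar)
  if (!is.finite(ll_bar)) {
    warning("posterior-mean parameters have zero likelihood; ",
            "using the best sample's deviance for p_D")
    ll_bar <- max(chain$log_lik)
  }
  p_d <- dbar + 2 * ll_bar
  c(Dbar = dbar, p_D = p_d, DIC = dbar + p_d)
}

#' Weighted average DIC over studies
#'
#' `DIC_w = sum(DIC_i * n_i) / sum(n_i)` with `n_i` the number of data points
#' in study `i`.
#'
#' @param per_study_dic numeric vector of study DICs.
#' @param per_study_n data-point counts, same length, `>= 1`.
#' @return scalar `DIC_w`.
#' @export
weighted_dic <- function(per_study_dic, per_study_n) {
  if (length(per_study_dic) == 0) stop("no studies supplied")
  stopifnot(length(per_study_dic) == length(per_study_n),
            all(per_study_n >= 1))
  sum(per_study_dic * per_study_n) / sum(per_study_n)
}

#' Model likelihood given the data
#'
#' `L = exp(-0.5 * (DIC_w - DIC_min))` relative to the best model; models
#' with `L > 0.5` form the selected set. Ties at the minimum all get `L = 1`.
#'
#' @param dic_w named numeric vector of weighted DICs, one per model
#'   (at least 2).
#' @param threshold selection threshold on `L` (default 0.5).
#' @return list with `L` (named vector) and `selected` (names with
#'   `L > threshold`).
#' @export
model_likelihood <- function(dic_w, threshold = 0.5) {
  if (length(dic_w) < 2) stop("need at least two models")
  L <- exp(-0.5 * (dic_w - min(dic_w)))
  list(L = L, selected = names(L)[L > threshold])
}

#' Within-sample evaluation: observed vs modeled regression
#'
#' Ordinary least squares of observed (y) on modeled (x) cumulative CO2,
#' pooled over studies and series; agreement with the 1:1 line is read from
#' the slope and R-squared. P is the two-sided t-test of slope = 0.
#'
#' @param modeled,observed numeric vectors (`>= 3` pairs).
#' @return list `(slope, intercept, r_squared, p_value, n)`.
#' @export
within_sample_eval <- function(modeled, observed) {
  stopifnot(length(modeled) == length(observed))
  if (length(modeled) < 3) stop("need at least 3 pairs")
  if (stats::var(modeled) == 0) stop("modeled values have zero variance")
  fit <- stats::lm(observed ~ modeled)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["modeled", "Pr(>|t|)"],
       n = length(modeled))
}

# modeled (at the chain MLE) and observed values for a set of studies
pooled_modeled_observed <- function(chains, studies = NULL) {
  mo <- lapply(chains, function(ch) {
    spec <- attr(ch, "spec"); obs <- attr(ch, "obs")
    o <- obs$observations
    th <- ch$mle
    tt <- sort(unique(o$time_d))
    trt <- simulate_model(spec, th, soc = obs$soc, added = obs$added,
                          times = tt, arm = "treatment")
    ctl <- simulate_model(spec, th, soc = obs$soc, added = 0,
                          times = tt, arm = "control")
    data.frame(modeled = modeled_values(trt, ctl, o), observed = o$cum_co2)
  })
  do.call(rbind, mo)
}

#' Fixed-parameter out-of-sample validation
#'
#' Fit the model to a training study, then simulate the validation study's
#' design with the optimized (fixed) parameters - same soil, different
#' added-C amount - and regress observed on modeled.
#'
#' @param spec a `soc_model`.
#' @param train_obs,validation_obs `soc_obs` from the same soil (equal SOC)
#'   with different added-C amounts.
#' @param config MCMC settings for the training fit.
#' @param chain optional pre-computed training chain (skips fitting).
#' @param bounds prior bounds passed to [fit_study()].
#' @return [within_sample_eval()] stats on the validation study.
#' @export
validate_fixed <- function(spec, train_obs, validation_obs,
                           config = mcmc_config(), chain = NULL,
                           bounds = NULL) {
  if (abs(train_obs$soc - validation_obs$soc) > 1e-9 * train_obs$soc)
    stop("fixed-mode validation requires the same soil (equal SOC)")
  if (abs(train_obs$added - validation_obs$added) < 1e-12)
    warning("training and validation added-C amounts are identical")
  if (is.null(chain))
    chain <- fit_study(spec, train_obs, config = config, bounds = bounds)
  th <- chain$mle
  o <- validation_obs$observations
  tt <- sort(unique(o$time_d))
  trt <- simulate_model(spec, th, soc = validation_obs$soc,
                        added = validation_obs$added, times = tt,
                        arm = "treatment")
  ctl <- simulate_model(spec, th, soc = validation_obs$soc, added = 0,
                        times = tt, arm = "control")
  within_sample_eval(modeled_values(trt, ctl, o), o$cum_co2)
}

#' Random-split out-of-sample validation
#'
#' Studies are split in half, stratified by quartile of the added-C fraction
#' (added C as % of SOC) so the two groups have similar addition-size
#' distributions. Prior bounds are tuned on the training group (the range of
#' its per-study MLEs, padded by 50% and clipped to the original box) - the
#' models stay study-specific, so what transfers between groups is the
#' hyper-setting, not the parameter values. The tuned priors are then used to
#' fit each validation study and observed is regressed on modeled.
#'
#' @param spec a `soc_model`.
#' @param studies list of `soc_obs` (`>= 4`).
#' @param split_seed integer seed controlling the split and the fits.
#' @param config MCMC settings used for every per-study fit.
#' @param bounds initial prior bounds.
#' @param ... passed on to [fit_study()] (e.g. `dt`, `optim_starts`).
#' @return list with `eval` ([within_sample_eval()] on the validation group),
#'   `train_ids`, `validation_ids`, `tuned_bounds` and `ks_p` (two-sample
#'   KS test p-value comparing the groups' added-C fractions).
#' @export
validate_random <- function(spec, studies, split_seed,
                            config = mcmc_config(), bounds = NULL, ...) {
  k <- length(studies)
  if (k < 4) stop("need at least 4 studies")
  frac <- vapply(studies, function(s) s$added / s$soc, numeric(1))
  set.seed(split_seed)
  if (k >= 8) {
    grp1 <- stratified_half_split(frac)
  } else {
    warning("too few studies to stratify; simple random split")
    grp1 <- sample(seq_len(k), floor(k / 2))
  }
  grp2 <- setdiff(seq_len(k), grp1)
  if (is.null(bounds))
    bounds <- if (spec$name == "interactive") interactive_fit_bounds()
              else default_bounds(spec$name)
  fit_one <- function(i, b) {
    cfg <- config
    cfg$seed <- (split_seed * 1009L + i) %% .Machine$integer.max
    fit_study(spec, studies[[i]], config = cfg, bounds = b, ...)
  }
  train_chains <- lapply(grp1, fit_one, b = bounds)
  mles <- do.call(rbind, lapply(train_chains, `[[`, "mle"))
  rng <- apply(mles, 2, range)
  pad <- 0.5 * (rng[2, ] - rng[1, ])
  tuned <- cbind(min = pmax(bounds[, "min"], rng[1, ] - pad),
                 max = pmin(bounds[, "max"], rng[2, ] + pad))
  keep <- tuned[, "max"] > tuned[, "min"]
  tuned[!keep, ] <- bounds[!keep, , drop = FALSE]
  val_chains <- lapply(grp2, fit_one, b = tuned)
  mo <- pooled_modeled_observed(val_chains)
  ks <- suppressWarnings(stats::ks.test(frac[grp1], frac[grp2]))
  list(eval = within_sample_eval(mo$modeled, mo$observed),
       train_ids = vapply(studies[grp1], `[[`, "", "study_id"),
       validation_ids = vapply(studies[grp2], `[[`, "", "study_id"),
       tuned_bounds = tuned, ks_p = ks$p.value)
}
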