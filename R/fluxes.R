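interp_col <- function(traj, col, t) {
  if (t < min(traj$time) - 1e-9 || t > max(traj$time) + 1e-9)
    stop("time ", t, " outside the simulated span")
  stats::approx(traj$time, traj[[col]], xout = t)$y
}

#' Replenishment: added C remaining in soil pools
#'
#' The isotope-labelled C left in all soil compartments (including microbial
#' biomass where the model has one) at time `t`; computed as
#' `added - cumulative labelled CO2`, which equals the summed labelled pools
#' by mass balance.
#'
#' @param traj_treatment treatment-arm `soc_trajectory`.
#' @param added amount added at `t = 0`, mg C per g soil.
#' @param t time (days) within the trajectory span.
#' @return replenished C, mg C per g soil.
#' @export
replenishment_at <- function(traj_treatment, added, t) {
  added - interp_col(traj_treatment, "co2_labeled", t)
}

#' Priming: extra old-C CO2 caused by the addition
#'
#' Difference in cumulative unlabelled (old-C) CO2 between the
#' substrate-addition treatment and the control at time `t`. Both arms must
#' start from the same unlabelled state.
#'
#' @param traj_treatment,traj_control `soc_trajectory` objects sharing the
#'   unlabelled initial state and parameters.
#' @param t time (days).
#' @return primed C loss, mg C per g soil.
#' @export
priming_at <- function(traj_treatment, traj_control, t) {
  u <- function(traj) {
    pool_cols <- attr(traj, "pool_cols")
    un <- pool_cols[endsWith(pool_cols, "_u")]
    sum(traj[1, un])
  }
  if (abs(u(traj_treatment) - u(traj_control)) > 1e-9)
    stop("treatment and control initial unlabelled states differ")
  interp_col(traj_treatment, "co2_unlabeled", t) -
    interp_col(traj_control, "co2_unlabeled", t)
}

#' Net SOC change
#'
#' @param replenishment,priming same units and horizon.
#' @return `replenishment - priming`.
#' @export
net_change <- function(replenishment, priming) replenishment - priming

#' Traditional priming expression: % increase over control
#'
#' Cumulative old-C CO2 in the treatment relative to the control, as a
#' percent increase; a convenience diagnostic only (the synthesis uses
#' %-of-added-C throughout).
#'
#' @inheritParams priming_at
#' @export
priming_percent_increase <- function(traj_treatment, traj_control, t) {
  100 * (interp_col(traj_treatment, "co2_unlabeled", t) /
           interp_col(traj_control, "co2_unlabeled", t) - 1)
}

# point fluxes for one parameter vector, as % of added C
flux_point <- function(spec, theta, soc, added, horizon, dt = 0.05) {
  tt <- c(0, horizon)
  trt <- simulate_model(spec, theta, soc = soc, added = added, times = tt,
                        arm = "treatment", dt = dt)
  ctl <- simulate_model(spec, theta, soc = soc, added = 0, times = tt,
                        arm = "control", dt = dt)
  rep_mg <- replenishment_at(trt, added, horizon)
  pri_mg <- priming_at(trt, ctl, horizon)
  c(replenishment = 100 * rep_mg / added,
    priming = 100 * pri_mg / added,
    net = 100 * (rep_mg - pri_mg) / added,
    loss = 100 * (added - rep_mg) / added)
}

#' Posterior flux summary at a standardized horizon
#'
#' Replenishment, priming, net SOC change and loss of added C are computed
#' per posterior sample at the horizon (1 year by default, extrapolating
#' beyond the incubation span with the fitted model) and summarized as the
#' posterior mean with 2.5/97.5 percentiles, expressed as % of added C.
#'
#' @param chain a `soc_chain` with attached `spec`/`obs` (see [fit_study()]).
#' @param spec,obs overrides for the attached model and study.
#' @param horizon_days standardized time point, `> 0` (default 365).
#' @param n_draws maximum number of posterior draws evaluated.
#' @param dt integrator step (days).
#' @return data frame with one row per metric: `study_id, horizon_d, metric,
#'   mean, lo95, hi95, sd, units` (units: % of added C).
#' @export
standardized_summary <- function(chain, spec = attr(chain, "spec"),
                                 obs = attr(chain, "obs"),
                                 horizon_days = 365, n_draws = 300,
                                 dt = 0.05) {
  if (horizon_days <= 0) stop("horizon must be positive")
  idx <- unique(round(seq(1, nrow(chain$samples),
                          length.out = min(n_draws, nrow(chain$samples)))))
  vals <- t(vapply(idx, function(i)
    flux_point(spec, chain$samples[i, ], obs$soc, obs$added, horizon_days,
               dt = dt), numeric(4)))
  data.frame(
    study_id = obs$study_id, horizon_d = horizon_days,
    metric = colnames(vals),
    mean = colMeans(vals),
    lo95 = apply(vals, 2, stats::quantile, probs = 0.025, names = FALSE),
    hi95 = apply(vals, 2, stats::quantile, probs = 0.975, names = FALSE),
    sd = apply(vals, 2, stats::sd),
    units = "% of added C", row.names = NULL)
}
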