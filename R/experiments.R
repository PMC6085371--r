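#' Recovery experiment: does the pipeline recover the generator truth?
#'
#' Generates a noise-free synthetic collection from the interactive model,
#' calibrates the interactive model to every study, summarizes the 1-year
#' net SOC change per study, and compares the weighted-mean net change
#' (weights from the posterior spread and replicate count) against the same
#' weighted mean computed from the generator's true per-study fluxes.
#'
#' @param seed master seed.
#' @param n_studies collection size.
#' @param S chain length per study.
#' @param noise_cv generator noise (0 = noise-free).
#' @param dt integrator step for the calibration.
#' @param n_draws posterior draws per flux summary.
#' @return list with `per_study` (estimates vs truth), `weighted_est`,
#'   `weighted_truth`, `abs_error`, the synthesis, the full per-study flux
#'   table (`fluxes`) and the fitted `chains`.
#' @export
recovery_experiment <- function(seed = 1, n_studies = 20, S = 10000,
                                noise_cv = 0, dt = 0.1, n_draws = 200) {
  coll <- generate_collection(synth_config(n_studies = n_studies,
                                           noise_cv = noise_cv, seed = seed))
  spec <- model_spec("interactive")
  chains <- list()
  fluxes <- list()
  rows <- lapply(seq_along(coll$studies), function(i) {
    obs <- coll$studies[[i]]
    cfg <- mcmc_config(S = S, seed = (seed * 131L + i) %% .Machine$integer.max)
    ch <- fit_study(spec, obs, config = cfg, dt = dt)
    fs <- standardized_summary(ch, n_draws = n_draws, dt = dt)
    chains[[obs$study_id]] <<- ch
    fluxes[[obs$study_id]] <<- cbind(fs, n = obs$n_rep,
                                     nc_category = obs$nc_category)
    net <- fs[fs$metric == "net", ]
    data.frame(study_id = obs$study_id, est = net$mean, sd = net$sd,
               truth = coll$truth[[i]]$flux_365[["net"]],
               n = obs$n_rep, nc_category = obs$nc_category)
  })
  per_study <- do.call(rbind, rows)
  flux_table <- do.call(rbind, fluxes)
  rownames(flux_table) <- NULL
  eff <- effect_sizes(data.frame(study_id = per_study$study_id,
                                 metric = "net", mean = per_study$est,
                                 sd = per_study$sd, n = per_study$n,
                                 nc_category = per_study$nc_category))
  eff_truth <- eff
  eff_truth$mean <- per_study$truth
  west <- weighted_mean_ci(eff)
  wtr <- weighted_mean_ci(eff_truth)
  list(per_study = per_study, weighted_est = west$mean,
       weighted_truth = wtr$mean,
       abs_error = abs(west$mean - wtr$mean), synthesis = west,
       fluxes = flux_table, chains = chains)
}

#' Model-comparison experiment: which model attains the lowest weighted DIC?
#'
#' Repeatedly generates a synthetic collection from the interactive model
#' (with observation noise), fits all four models to every study, and
#' records which model attains the minimal weighted DIC in each run.
#'
#' @param seed master seed.
#' @param n_runs number of independent seeded runs.
#' @param n_studies studies per run.
#' @param S chain length per fit.
#' @param noise_cv generator noise.
#' @param dt integrator step.
#' @param n_init starting candidates scored per fit.
#' @param optim_starts,optim_maxit mode-search effort per fit.
#' @return list with `winners` (character vector per run), `dic_w` (matrix
#'   runs x models) and `interactive_win_rate`.
#' @export
model_comparison_experiment <- function(seed = 1, n_runs = 10,
                                        n_studies = 10, S = 2000,
                                        noise_cv = 0.05, dt = 0.25,
                                        n_init = 300, optim_starts = 4,
                                        optim_maxit = 150) {
  models <- c("conventional", "interactive", "michaelis_menten",
              "reverse_michaelis_menten")
  dic_w <- matrix(NA_real_, n_runs, length(models),
                  dimnames = list(NULL, models))
  for (r in seq_len(n_runs)) {
    coll <- generate_collection(synth_config(n_studies = n_studies,
                                             noise_cv = noise_cv,
                                             seed = seed * 37L + r))
    for (m in models) {
      spec <- model_spec(m)
      dics <- ns <- numeric(0)
      for (i in seq_along(coll$studies)) {
        cfg <- mcmc_config(S = S, adapt_every = 250,
                           seed = (seed * 7L + r * 101L + spec$id * 13L + i) %%
                             .Machine$integer.max)
        ch <- fit_study(spec, coll$studies[[i]], config = cfg, dt = dt,
                        n_init = n_init, optim_starts = optim_starts,
                        optim_maxit = optim_maxit)
        dics <- c(dics, dic(ch)[["DIC"]])
        ns <- c(ns, nrow(coll$studies[[i]]$observations))
      }
      dic_w[r, m] <- weighted_dic(dics, ns)
    }
  }
  winners <- models[apply(dic_w, 1, which.min)]
  list(winners = winners, dic_w = dic_w,
       interactive_win_rate = mean(winners == "interactive"))
}

#' Coverage experiment: do 95% posterior intervals cover the truth?
#'
#' Generates independent single-study replicates from the interactive model
#' with observation noise, calibrates each, and reports the fraction of
#' replicates whose central 95% posterior interval covers the true value,
#' per parameter.
#'
#' @param seed master seed.
#' @param n_rep replicates.
#' @param S chain length per fit.
#' @param noise_cv generator noise.
#' @param dt integrator step.
#' @param n_init starting candidates scored per fit.
#' @return list with `coverage` (named per-parameter fractions) and the
#'   replicate-level logical matrix.
#' @export
coverage_experiment <- function(seed = 1, n_rep = 20, S = 50000,
                                noise_cv = 0.05, dt = 0.2, n_init = 300) {
  cover <- NULL
  for (r in seq_len(n_rep)) {
    st <- generate_study(synth_config(noise_cv = noise_cv, seed = seed),
                         study_id = sprintf("rep%02d", r),
                         seed = (seed * 53L + r) %% .Machine$integer.max)
    ch <- fit_study(model_spec("interactive"), st$obs,
                    config = mcmc_config(S = S,
                                         seed = (seed * 71L + r) %%
                                           .Machine$integer.max),
                    dt = dt, n_init = n_init)
    qs <- apply(ch$samples, 2, stats::quantile, probs = c(0.025, 0.975))
    cover <- rbind(cover, st$truth$params >= qs[1, ] &
                     st$truth$params <= qs[2, ])
  }
  list(coverage = colMeans(cover), detail = cover)
}

#' Stratified half-split of studies by added-C fraction
#'
#' Ranks the added-C fractions, cuts them into quartile strata, and splits
#' each stratum in half at random, so the two groups share the
#' addition-size distribution.
#'
#' @param frac numeric vector of added-C fractions (added / SOC).
#' @return integer indices of group 1 (the complement is group 2).
#' @export
stratified_half_split <- function(frac) {
  k <- length(frac)
  strata <- cut(rank(frac, ties.method = "first"), breaks = 4,
                labels = FALSE)
  unlist(lapply(split(seq_len(k), strata), function(idx) {
    n1 <- floor(length(idx) / 2) +
      stats::rbinom(1, 1, (length(idx) %% 2) / 2)
    sample(idx, n1)
  }))
}
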