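#' MCMC configuration
#'
#' Settings for the adaptive Metropolis sampler. Proposals are
#' `theta_new = theta_old + d * (theta_max - theta_min) / D` with
#' `d ~ Uniform(-0.5, 0.5)` independently per parameter; coordinates leaving
#' the prior box are reflected back. "Adaptive" means the scalar step divisor
#' `D` is doubled (smaller steps) or halved every `adapt_every` iterations
#' during burn-in to keep the block acceptance rate inside `accept_range`,
#' and frozen afterwards so the retained chain is a valid Metropolis sample.
#'
#' @param S chain length (iterations), `>= 1000`.
#' @param D initial step divisor, `> 0`.
#' @param burn_frac burn-in fraction discarded from the front (default 0.5).
#' @param adapt_every adaptation block length during burn-in.
#' @param accept_range target acceptance band for adaptation.
#' @param covariance adapt a full proposal covariance during burn-in: after
#'   an initial box-proposal phase the sampler switches to Gaussian steps
#'   shaped by the empirical covariance of the early chain (the classic
#'   adaptive-Metropolis scheme), which mixes across the strong parameter
#'   correlations these models produce; the proposal is frozen at the end
#'   of burn-in so the retained chain is a valid Metropolis sample.
#' @param seed optional integer seed applied at the start of the run.
#' @return a `soc_mcmc_config` list.
#' @export
mcmc_config <- function(S = 50000, D = 100, burn_frac = 0.5,
                        adapt_every = 1000, accept_range = c(0.2, 0.5),
                        covariance = TRUE, seed = NULL) {
  stopifnot(S >= 1000, D > 0, burn_frac > 0, burn_frac < 1,
            length(accept_range) == 2)
  structure(list(S = as.integer(S), D = D, burn_frac = burn_frac,
                 adapt_every = as.integer(adapt_every),
                 accept_range = accept_range,
                 covariance = isTRUE(covariance), seed = seed),
            class = "soc_mcmc_config")
}

#' Uniform-box proposal with boundary reflection
#'
#' @param theta_old current parameter vector (inside the bounds).
#' @param bounds matrix with `min`/`max` columns.
#' @param D step divisor (scalar or per-parameter).
#' @param d optional vector of uniform draws in `[-0.5, 0.5]` (drawn if
#'   `NULL`); exposed for testing.
#' @return proposed vector, guaranteed inside the bounds.
#' @export
propose <- function(theta_old, bounds, D, d = NULL) {
  lo <- bounds[, "min"]; hi <- bounds[, "max"]
  if (is.null(d)) d <- stats::runif(length(theta_old), -0.5, 0.5)
  reflect(theta_old + d * (hi - lo) / D, lo, hi)
}

#' Reflect values into an interval
#'
#' Folds each coordinate back into `[lo, hi]` by mirror reflection at the
#' boundaries (period `2 * (hi - lo)`), preserving detailed balance of the
#' symmetric uniform proposal.
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds (vectors).
#' @return reflected vector.
#' @export
reflect <- function(x, lo, hi) {
  w <- hi - lo
  fixed <- w <= 0
  r <- (x - lo) %% (2 * w)
  out <- ifelse(r > w, 2 * w - r, r) + lo
  out[fixed] <- lo[fixed]
  out
}

#' Run the adaptive Metropolis sampler
#'
#' Uniform priors over the bounds box (they cancel in the acceptance ratio,
#' except that structurally invalid proposals with `log_lik = -Inf` are
#' always rejected). The first `burn_frac` of the chain is discarded.
#'
#' @param log_lik function(named parameter vector) -> scalar log-likelihood
#'   (`-Inf` allowed).
#' @param bounds bounds matrix (rownames are the parameter names).
#' @param config a [mcmc_config()].
#' @param init optional start value; default: the posterior mode located by
#'   bounded quasi-Newton refinement of the best of `n_init` seeded draws.
#'   Starting the random-walk chain at the mode removes the long burn-in
#'   transit through a sharply peaked posterior; the burn-in half is still
#'   discarded.
#' @param n_init number of random starting candidates scored before the run.
#' @param init_optim refine the best candidates with `optim(L-BFGS-B)` before
#'   sampling.
#' @param optim_starts number of top-scoring candidates refined.
#' @param optim_maxit iteration cap per refinement.
#' @return a `soc_chain`: list with `samples` (post-burn-in matrix),
#'   `log_lik`, `mle` (sample with maximal log-likelihood), `mle_log_lik`,
#'   `acceptance_rate` (post-burn-in), `D_final`, `bounds`, `config`.
#' @export
run_mcmc <- function(log_lik, bounds, config = mcmc_config(), init = NULL,
                     n_init = 50, init_optim = TRUE, optim_starts = 6,
                     optim_maxit = 500) {
  if (!is.null(config$seed)) set.seed(config$seed)
  npar <- nrow(bounds)
  nm <- rownames(bounds)
  lo <- bounds[, "min"]; hi <- bounds[, "max"]
  if (is.null(init)) {
    # rate-like parameters span several decades: seed candidates
    # log-uniformly there, or uniform draws never visit slow kinetics
    wide <- lo > 0 & hi / lo >= 100
    cand <- matrix(NA_real_, n_init, npar)
    for (j in seq_len(npar)) {
      cand[, j] <- if (wide[j])
        exp(stats::runif(n_init, log(lo[j]), log(hi[j])))
      else stats::runif(n_init, lo[j], hi[j])
    }
    cand <- rbind((lo + hi) / 2, cand)
    ll_cand <- apply(cand, 1, function(v) log_lik(stats::setNames(v, nm)))
    init <- cand[which.max(ll_cand), ]
    if (init_optim) {
      # multi-start mode search in box-normalized coordinates, so
      # finite-difference steps are commensurate across parameters
      # spanning orders of magnitude; the likelihood surface is multimodal
      # and a single start regularly strands in a local optimum
      negll_u <- function(u) {
        val <- log_lik(stats::setNames(lo + u * (hi - lo), nm))
        if (is.finite(val)) -val else 1e10
      }
      starts <- cand[order(ll_cand, decreasing = TRUE)[
        seq_len(min(optim_starts, nrow(cand)))], , drop = FALSE]
      best_val <- -log_lik(stats::setNames(init, nm))
      for (j in seq_len(nrow(starts))) {
        u0 <- (starts[j, ] - lo) / (hi - lo)
        opt <- try(stats::optim(u0, negll_u, method = "L-BFGS-B",
                                lower = 1e-10, upper = 1 - 1e-10,
                                control = list(maxit = optim_maxit)), silent = TRUE)
        if (!inherits(opt, "try-error") && is.finite(opt$value) &&
            opt$value < best_val) {
          best_val <- opt$value
          init <- lo + opt$par * (hi - lo)
        }
      }
    }
  }
  theta <- stats::setNames(pmin(pmax(init, lo), hi), nm)
  ll <- log_lik(theta)
  if (!is.finite(ll)) stop("initial value has zero likelihood")

  S <- config$S
  D <- config$D
  burn <- floor(config$burn_frac * S)
  # adaptation blocks must fit inside the burn-in several times over
  block <- max(50L, min(config$adapt_every, burn %/% 5L))
  # phase 1 of burn-in: bounded uniform-box proposals with D tuning;
  # phase 2: Gaussian proposals with the empirical covariance of phase 1
  # (scaled 2.38/sqrt(npar), scalar factor tuned like D), reflected into
  # the box; frozen after burn-in
  use_cov <- isTRUE(config$covariance) && npar > 1
  phase1 <- if (use_cov) max(2L * block, floor(0.4 * burn)) else burn
  cholR <- NULL
  sfac <- 1
  samples <- matrix(NA_real_, S, npar, dimnames = list(NULL, nm))
  lls <- numeric(S)
  acc <- 0L; acc_block <- 0L; acc_post <- 0L
  for (s in seq_len(S)) {
    if (stats::runif(1) < 0.1) {
      # symmetric mode-hopping move: redraw one coordinate uniformly from
      # its prior interval (constant proposal density, so the Metropolis
      # ratio is untouched); disperses flat directions and lets the chain
      # cross between separated likelihood modes
      j <- sample.int(npar, 1)
      prop <- theta
      prop[j] <- stats::runif(1, lo[j], hi[j])
    } else if (is.null(cholR)) {
      prop <- propose(theta, bounds, D)
    } else {
      step <- as.numeric(stats::rnorm(npar) %*% cholR) * sfac
      prop <- reflect(theta + step, lo, hi)
    }
    llp <- log_lik(prop)
    if (is.finite(llp) && log(stats::runif(1)) < llp - ll) {
      theta <- prop; ll <- llp
      acc <- acc + 1L; acc_block <- acc_block + 1L
      if (s > burn) acc_post <- acc_post + 1L
    }
    samples[s, ] <- theta
    lls[s] <- ll
    if (use_cov && s == phase1) {
      emp <- stats::cov(samples[seq_len(s), , drop = FALSE])
      emp <- emp + diag(pmax(1e-12 * (hi - lo)^2,
                             1e-8 * diag(emp) + 1e-300), npar)
      ch <- try(chol(emp), silent = TRUE)
      if (!inherits(ch, "try-error")) {
        cholR <- ch * (2.38 / sqrt(npar))
        acc_block <- 0L
      }
    } else if (s <= burn && s %% block == 0) {
      rate <- acc_block / block
      if (is.null(cholR)) {
        if (rate < config$accept_range[1]) D <- D * 2
        else if (rate > config$accept_range[2]) D <- D / 2
      } else {
        if (rate < config$accept_range[1]) sfac <- sfac / 2
        else if (rate > config$accept_range[2]) sfac <- sfac * 2
      }
      acc_block <- 0L
    }
  }
  keep <- (burn + 1):S
  rate_post <- acc_post / length(keep)
  if (rate_post < 0.01)
    stop("post-adaptation acceptance rate ", format(rate_post),
         " below 1%: revise bounds or step divisor D")
  best <- which.max(lls[keep])
  structure(list(samples = samples[keep, , drop = FALSE],
                 log_lik = lls[keep],
                 mle = samples[keep, , drop = FALSE][best, ],
                 mle_log_lik = lls[keep][best],
                 acceptance_rate = rate_post,
                 D_final = D, bounds = bounds, config = config),
            class = "soc_chain")
}

#' @export
print.soc_chain <- function(x, ...) {
  cat("<soc_chain> ", nrow(x$samples), " retained samples, acceptance ",
      round(x$acceptance_rate, 3), ", max log-lik ",
      round(x$mle_log_lik, 2), "\n", sep = "")
  invisible(x)
}

#' Study calibration objective
#'
#' Builds the log-likelihood closure for one study and model: simulate the
#' control and substrate-addition arms from a candidate parameter vector and
#' score the three cumulative-CO2 series. Structurally invalid candidates
#' (e.g. `f_N + f_B > 1`) and divergent simulations return `-Inf`.
#'
#' @param spec a `soc_model`.
#' @param obs a `soc_obs`.
#' @param dt integrator step (days).
#' @return function(named parameter vector) -> log-likelihood.
#' @export
study_objective <- function(spec, obs, dt = 0.05) {
  o <- obs$observations
  sigma <- obs_sigma(obs, warn = FALSE)
  series_code <- match(o$series, SERIES_LEVELS) - 1L
  soc <- obs$soc; added <- obs$added
  force(dt)
  function(theta) {
    if (spec$name == "conventional" &&
        theta[["a_LN"]] + theta[["a_RN"]] > 1) return(-Inf)
    if (spec$name %in% c("michaelis_menten", "reverse_michaelis_menten") &&
        theta[["f_N"]] + theta[["f_B"]] > 1) return(-Inf)
    y0c <- initial_state(spec, theta, soc, added = 0)
    y0t <- initial_state(spec, theta, soc, added = added)
    study_loglik_cpp(spec$id,
                     core_params(spec, theta, "control"), y0c,
                     core_params(spec, theta, "treatment"), y0t,
                     o$time_d, o$cum_co2, sigma, series_code, dt)
  }
}

#' Calibrate a model to one study
#'
#' Convenience wrapper: [study_objective()] + [run_mcmc()].
#'
#' @inheritParams study_objective
#' @param config a [mcmc_config()].
#' @param retry rerun once with a much heavier multi-start when the best
#'   log-likelihood is far below what the observation noise allows
#'   (a stranded mode search, detected as `mle_log_lik < -1.5 n_obs`).
#' @param ... passed on to [run_mcmc()] (e.g. `optim_starts`).
#' @param bounds prior bounds; default [interactive_fit_bounds()] for the
#'   interactive model, [default_bounds()] otherwise.
#' @return a `soc_chain` with attributes `spec` and `obs` attached.
#' @export
fit_study <- function(spec, obs, config = mcmc_config(), bounds = NULL,
                      dt = 0.05, retry = TRUE, ...) {
  if (is.null(bounds))
    bounds <- if (spec$name == "interactive") interactive_fit_bounds()
              else default_bounds(spec$name)
  obj <- study_objective(spec, obs, dt = dt)
  chain <- run_mcmc(obj, bounds, config, ...)
  # a best fit much worse than the observation noise allows is almost
  # always a stranded mode search, not the model's limit: retry once with
  # a far heavier multi-start before accepting it
  n_obs <- nrow(obs$observations)
  if (retry && chain$mle_log_lik < -1.5 * n_obs) {
    cfg2 <- config
    if (!is.null(cfg2$seed))
      cfg2$seed <- (cfg2$seed + 1L) %% .Machine$integer.max
    chain2 <- run_mcmc(obj, bounds, cfg2, n_init = 1000,
                       optim_starts = 5, optim_maxit = 300)
    if (chain2$mle_log_lik > chain$mle_log_lik) chain <- chain2
  }
  attr(chain, "spec") <- spec
  attr(chain, "obs") <- obs
  chain
}

#' Posterior-predictive bands for the three series
#'
#' Simulates trajectories over (a subsample of) the posterior and returns the
#' requested quantiles of each cumulative-CO2 series at each time.
#'
#' @param chain a `soc_chain`.
#' @param spec a `soc_model`.
#' @param obs a `soc_obs`.
#' @param times output times (days); default: the observation times.
#' @param quantiles probabilities in (0, 1); default the 95% band.
#' @param n_draws maximum number of posterior draws simulated.
#' @return data frame with `series`, `time_d`, one column per quantile and
#'   `mean`.
#' @export
posterior_predictive <- function(chain, spec = attr(chain, "spec"),
                                 obs = attr(chain, "obs"), times = NULL,
                                 quantiles = c(0.025, 0.975),
                                 n_draws = 400) {
  if (nrow(chain$samples) == 0) stop("empty chain")
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly between 0 and 1")
  if (is.null(times)) times <- sort(unique(obs$observations$time_d))
  idx <- unique(round(seq(1, nrow(chain$samples),
                          length.out = min(n_draws, nrow(chain$samples)))))
  sims <- array(NA_real_, c(length(idx), length(times), 3))
  for (k in seq_along(idx)) {
    th <- chain$samples[idx[k], ]
    trt <- simulate_model(spec, th, soc = obs$soc, added = obs$added,
                          times = times, arm = "treatment")
    ctl <- simulate_model(spec, th, soc = obs$soc, added = 0,
                          times = times, arm = "control")
    sims[k, , 1] <- ctl$co2_unlabeled
    sims[k, , 2] <- trt$co2_unlabeled
    sims[k, , 3] <- trt$co2_labeled
  }
  out <- NULL
  for (j in 1:3) {
    m <- matrix(sims[, , j], nrow = length(idx))
    qm <- matrix(apply(m, 2, stats::quantile, probs = quantiles,
                       names = FALSE), nrow = length(quantiles))
    df <- data.frame(series = SERIES_LEVELS[j], time_d = times)
    for (i in seq_along(quantiles))
      df[[paste0("q", quantiles[i])]] <- qm[i, ]
    df$mean <- colMeans(m)
    out <- rbind(out, df)
  }
  out
}

#' Export / import a chain as CSV
#'
#' Header of parameter names plus a `log_lik` column.
#'
#' @param chain a `soc_chain`.
#' @param path file path.
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(data.frame(chain$samples, log_lik = chain$log_lik,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @return `read_chain()`: a list with `samples` and `log_lik` usable by
#'   [dic()].
#' @export
read_chain <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  list(samples = as.matrix(d[setdiff(names(d), "log_lik")]),
       log_lik = d$log_lik)
}
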