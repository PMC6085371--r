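test_that("log-likelihood reproduces hand-summed residuals", {
  obs <- toy_obs()
  spec <- model_spec("interactive")
  th <- params_interactive()
  tt <- c(0, sort(unique(obs$observations$time_d)))
  trt <- simulate_model(spec, th, soc = obs$soc, added = obs$added,
                        times = tt)
  ctl <- simulate_model(spec, th, soc = obs$soc, added = 0, times = tt)
  ll <- log_likelihood(trt, ctl, obs)
  # independent spreadsheet-style summation
  o <- obs$observations
  x <- numeric(nrow(o))
  for (i in seq_len(nrow(o))) {
    traj <- if (o$series[i] == "old_control") ctl else trt
    col <- if (o$series[i] == "new_treatment") "co2_labeled"
           else "co2_unlabeled"
    x[i] <- approx(traj$time, traj[[col]], xout = o$time_d[i])$y
  }
  brute <- -sum((o$cum_co2 - x)^2 / (2 * o$sd^2))
  expect_equal(ll, brute, tolerance = 1e-12)

  # perfect fit scores zero: replace observations by the modeled values
  o2 <- o; o2$cum_co2 <- x
  obs2 <- observation_set("toy", obs$soc, obs$added, "low", o2)
  expect_equal(log_likelihood(trt, ctl, obs2), 0)

  # a single point one SD away scores -1/2
  o3 <- o[1, ]; o3$cum_co2 <- x[1] + o3$sd
  obs3 <- observation_set("toy", obs$soc, obs$added, "low", o3,
                          validate = FALSE)
  expect_equal(log_likelihood(trt, ctl, obs3), -0.5, tolerance = 1e-12)

  # permutation invariance
  o4 <- o[sample(nrow(o)), ]
  obs4 <- observation_set("toy", obs$soc, obs$added, "low", o4)
  expect_equal(log_likelihood(trt, ctl, obs4), ll, tolerance = 1e-12)
})

test_that("the C++ study objective agrees with the R likelihood path", {
  st <- quick_synth(seed = 11, noise_cv = 0.05)
  obs <- st$obs
  spec <- model_spec("interactive")
  obj <- study_objective(spec, obs, dt = 0.05)
  th <- st$truth$params
  tt <- c(0, sort(unique(obs$observations$time_d)))
  trt <- simulate_model(spec, th, soc = obs$soc, added = obs$added,
                        times = tt)
  ctl <- simulate_model(spec, th, soc = obs$soc, added = 0, times = tt)
  expect_equal(obj(th), log_likelihood(trt, ctl, obs), tolerance = 1e-8)
})

test_that("missing SDs fall back with a warning", {
  o <- toy_obs()$observations
  o$sd[2] <- NA
  obs <- observation_set("toy", 20, 1, "low", o)
  expect_warning(s <- obs_sigma(obs), "without SD")
  expect_equal(s[2], max(0.05 * o$cum_co2[2], 0.01 * 1))
  expect_equal(s[-2], o$sd[-2])
})

test_that("proposal follows the bounded random-walk rule with reflection", {
  b <- cbind(min = c(0, 1), max = c(2, 3))
  rownames(b) <- c("a", "b")
  th <- c(a = 1, b = 2)
  # d = 0 leaves the value unchanged
  expect_equal(propose(th, b, D = 5, d = c(0, 0)), th)
  # hand-checked step: theta + d * width / D
  expect_equal(unname(propose(th, b, D = 5, d = c(0.25, -0.5))),
               c(1 + 0.25 * 2 / 5, 2 - 0.5 * 2 / 5))
  # at the upper boundary a positive step reflects back inside
  th2 <- c(a = 2, b = 3)
  expect_equal(unname(propose(th2, b, D = 5, d = c(0.5, 0.5))),
               c(2 - 0.1 * 2, 3 - 0.1 * 2))
})

test_that("proposal increments are uniform with width (range)/D", {
  set.seed(1)
  b <- cbind(min = 0, max = 10)
  rownames(b) <- "a"
  D <- 5
  th <- c(a = 5) # far from bounds: no reflection for width 10/D = 2
  inc <- replicate(1e5, propose(th, b, D)[["a"]]) - 5
  expect_gt(suppressWarnings(
    ks.test(inc, "punif", -1, 1)$p.value), 0.01)
})

test_that("chains are reproducible under a seed and honour the bounds", {
  st <- quick_synth(seed = 5, noise_cv = 0.05)
  cfg <- mcmc_config(S = 1500, adapt_every = 250, seed = 9)
  ch1 <- fit_study(model_spec("interactive"), st$obs, config = cfg,
                   dt = 0.2, n_init = 10, optim_starts = 1,
                   optim_maxit = 40)
  ch2 <- fit_study(model_spec("interactive"), st$obs, config = cfg,
                   dt = 0.2, n_init = 10, optim_starts = 1,
                   optim_maxit = 40)
  expect_identical(ch1$samples, ch2$samples)
  b <- ch1$bounds
  expect_true(all(t(ch1$samples) >= b[, "min"] & t(ch1$samples) <= b[, "max"]))
  expect_equal(nrow(ch1$samples), 750) # burn-in half discarded
  expect_equal(ch1$mle_log_lik, max(ch1$log_lik))
})

test_that("posterior matches the conjugate answer on a linear-Gaussian toy", {
  # one observation z of a single parameter theta with prior U(-10, 10):
  # posterior is N(z, sigma^2) truncated to the box
  z <- 1.3; sigma <- 0.4
  ll <- function(theta) -(z - theta[["a"]])^2 / (2 * sigma^2)
  b <- cbind(min = -10, max = 10)
  rownames(b) <- "a"
  ch <- run_mcmc(ll, b, mcmc_config(S = 40000, D = 50, seed = 3),
                 init_optim = FALSE)
  expect_equal(mean(ch$samples[, "a"]), z, tolerance = 0.02)
  expect_equal(sd(ch$samples[, "a"]), sigma, tolerance = 0.05)
  # split-half stationarity: halves agree within Monte-Carlo error
  h1 <- ch$samples[seq_len(10000), "a"]
  h2 <- ch$samples[10001:20000, "a"]
  se <- sd(ch$samples[, "a"]) / sqrt(200) # generous effective size
  expect_lt(abs(mean(h1) - mean(h2)), 3 * se)
})

test_that("noise-free interactive data are recovered with tight bounds", {
  st <- quick_synth(seed = 21, noise_cv = 0)
  tr <- st$truth$params
  b <- cbind(min = tr * 0.7, max = tr * 1.3)
  rownames(b) <- names(tr)
  ch <- fit_study(model_spec("interactive"), st$obs,
                  config = mcmc_config(S = 4000, adapt_every = 250,
                                       seed = 2),
                  bounds = b, dt = 0.1)
  expect_lt(max(abs(ch$mle / tr - 1)[c("K_N", "K_O", "r", "f_N")]), 0.01)
})

test_that("posterior predictive bands behave like order statistics", {
  st <- quick_synth(seed = 31, noise_cv = 0.05)
  spec <- model_spec("interactive")
  th <- st$truth$params
  degenerate <- structure(list(
    samples = matrix(rep(th, 5), nrow = 5, byrow = TRUE,
                     dimnames = list(NULL, names(th))),
    log_lik = rep(0, 5)), class = "soc_chain")
  attr(degenerate, "spec") <- spec
  attr(degenerate, "obs") <- st$obs
  pp <- posterior_predictive(degenerate)
  expect_equal(pp$q0.025, pp$q0.975, tolerance = 1e-12) # zero-width band
  # adding a dispersed sample can only widen the band
  th2 <- th * c(1.5, 1, 1, 1, 1, 1)
  aug <- degenerate
  aug$samples <- rbind(degenerate$samples, th2)
  aug$log_lik <- c(degenerate$log_lik, -1)
  pp2 <- posterior_predictive(aug)
  expect_true(all(pp2$q0.975 - pp2$q0.025 >= pp$q0.975 - pp$q0.025 - 1e-12))
  expect_error(posterior_predictive(degenerate, quantiles = c(0, 1.2)),
               "strictly between")
})
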