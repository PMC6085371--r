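test_that("replenishment plus labelled CO2 conserves the added amount", {
  spec <- model_spec("interactive")
  tr <- simulate_model(spec, params_interactive(), soc = 20, added = 1,
                       times = seq(0, 365, by = 5))
  expect_equal(replenishment_at(tr, 1, 0), 1)  # all of it at t = 0
  for (t in c(10, 66, 200, 365)) {
    r <- replenishment_at(tr, 1, t)
    co2 <- approx(tr$time, tr$co2_labeled, xout = t)$y
    expect_lt(abs(r + co2 - 1), 1e-6)
    # equals the labelled C summed over pools
    pools <- approx(tr$time, tr$N_l + tr$O_l, xout = t)$y
    expect_equal(r, pools, tolerance = 1e-6)
  }
  expect_error(replenishment_at(tr, 1, 400), "outside")
})

test_that("replenishment matches the closed-form integral oracle", {
  # isolated substrate, no old-C feedback: remaining N = exp(-K_N t) and
  # labelled old C accrued = r * (1 - exp(-K_N t)); K_O ~ 0 so labelled O
  # barely respires over the window
  p <- params_interactive(K_N = 0.05, K_O = 1e-9, r = 0.4, K_p = 0, f_N = 0)
  tr <- simulate_model(model_spec("interactive"), p, soc = 1e-9, added = 1,
                       times = c(0, 66))
  expect_equal(replenishment_at(tr, 1, 66),
               exp(-3.3) + 0.4 * (1 - exp(-3.3)), tolerance = 1e-6)
})

test_that("priming vanishes without addition or without a priming term", {
  spec <- model_spec("interactive")
  p <- params_interactive(K_p = 0.002)
  tt <- seq(0, 365, by = 5)
  ctl <- simulate_model(spec, p, soc = 20, added = 0, times = tt)
  expect_equal(priming_at(ctl, ctl, 365), 0)
  p0 <- params_interactive(K_p = 0)
  trt <- simulate_model(spec, p0, soc = 20, added = 1, times = tt)
  ctl0 <- simulate_model(spec, p0, soc = 20, added = 0, times = tt)
  for (t in c(30, 180, 365))
    expect_lt(abs(priming_at(trt, ctl0, t)), 1e-9)
})

test_that("priming matches a quadrature oracle for the f_N = 0 case", {
  # with f_N = 0 the unlabelled old pool obeys
  # dO/dt = -(K_O + K_p N(t)^p) O with N(t) = added * exp(-K_N t), so
  # O(t) = O0 exp(-K_O t - K_p int_0^t N(s)^p ds) and priming is the
  # difference of the control and treatment survival curves
  p <- params_interactive(K_N = 0.04, K_O = 5e-4, r = 0.45, K_p = 3e-4,
                          p = 0.7, f_N = 0)
  soc <- 20; added <- 1.5
  tt <- seq(0, 365, by = 1)
  spec <- model_spec("interactive")
  trt <- simulate_model(spec, p, soc = soc, added = added, times = tt)
  ctl <- simulate_model(spec, p, soc = soc, added = 0, times = tt)
  for (t in c(66, 200, 365)) {
    intN <- integrate(function(s) (added * exp(-p[["K_N"]] * s))^p[["p"]],
                      0, t, rel.tol = 1e-10)$value
    o_trt <- soc * exp(-p[["K_O"]] * t - p[["K_p"]] * intN)
    o_ctl <- soc * exp(-p[["K_O"]] * t)
    expect_equal(priming_at(trt, ctl, t), o_ctl - o_trt, tolerance = 1e-6)
  }
})

test_that("net change is the exact difference and reproduces the worked case", {
  expect_equal(net_change(40.2, 37.1), 3.1, tolerance = 1e-12)
  expect_equal(net_change(12, 0), 12)
  expect_equal(net_change(7.3, 7.3), 0)
})

test_that("percent-of-added-C fluxes are invariant to the added amount when linear", {
  p <- params_interactive(K_p = 0)
  spec <- model_spec("interactive")
  f1 <- socprime:::flux_point(spec, p, soc = 20, added = 1, horizon = 365)
  f2 <- socprime:::flux_point(spec, p, soc = 20, added = 2, horizon = 365)
  expect_equal(f1[["replenishment"]], f2[["replenishment"]],
               tolerance = 1e-8)
})

test_that("flux summaries respect conservation and degenerate chains", {
  st <- quick_synth(seed = 13, noise_cv = 0)
  spec <- model_spec("interactive")
  th <- st$truth$params
  degen <- structure(list(
    samples = matrix(rep(th, 4), nrow = 4, byrow = TRUE,
                     dimnames = list(NULL, names(th))),
    log_lik = rep(0, 4)), class = "soc_chain")
  attr(degen, "spec") <- spec
  attr(degen, "obs") <- st$obs
  fs <- standardized_summary(degen)
  expect_equal(fs$lo95, fs$hi95, tolerance = 1e-12)  # zero-width bands
  expect_equal(fs$mean[fs$metric == "net"],
               fs$mean[fs$metric == "replenishment"] -
                 fs$mean[fs$metric == "priming"], tolerance = 1e-10)
  expect_equal(fs$mean[fs$metric == "replenishment"] +
                 fs$mean[fs$metric == "loss"], 100, tolerance = 1e-6)
  expect_equal(fs$mean[fs$metric == "net"],
               st$truth$flux_365[["net"]], tolerance = 1e-4)
  expect_error(standardized_summary(degen, horizon_days = -1), "positive")
})

test_that("fluxes are stable under output-grid refinement", {
  p <- params_interactive()
  spec <- model_spec("interactive")
  coarse <- socprime:::flux_point(spec, p, soc = 20, added = 1,
                                  horizon = 365, dt = 0.05)
  fine <- socprime:::flux_point(spec, p, soc = 20, added = 1,
                                horizon = 365, dt = 0.01)
  expect_lt(max(abs(coarse - fine)), 1e-4)
})

test_that("the traditional percent-increase expression behaves", {
  p <- params_interactive(K_p = 5e-4)
  spec <- model_spec("interactive")
  tt <- seq(0, 66, by = 2)
  trt <- simulate_model(spec, p, soc = 20, added = 1, times = tt)
  ctl <- simulate_model(spec, p, soc = 20, added = 0, times = tt)
  pct <- priming_percent_increase(trt, ctl, 66)
  expect_gt(pct, 0)
  mg <- priming_at(trt, ctl, 66)
  ctl66 <- approx(ctl$time, ctl$co2_unlabeled, xout = 66)$y
  expect_equal(pct, 100 * mg / ctl66, tolerance = 1e-9)
})
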