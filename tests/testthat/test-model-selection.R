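test_that("DIC of a degenerate chain collapses to the plug-in deviance", {
  st <- quick_synth(seed = 3, noise_cv = 0.05)
  spec <- model_spec("interactive")
  obj <- study_objective(spec, st$obs)
  th <- st$truth$params
  ch <- structure(list(
    samples = matrix(rep(th, 10), nrow = 10, byrow = TRUE,
                     dimnames = list(NULL, names(th))),
    log_lik = rep(obj(th), 10)), class = "soc_chain")
  d <- dic(ch, log_lik = obj)
  expect_equal(unname(d["p_D"]), 0, tolerance = 1e-10)
  expect_equal(unname(d["DIC"]), -2 * obj(th), tolerance = 1e-10)
})

test_that("DIC recomputed from a serialized chain matches in-memory", {
  st <- quick_synth(seed = 4, noise_cv = 0.05)
  spec <- model_spec("interactive")
  ch <- fit_study(spec, st$obs,
                  config = mcmc_config(S = 1500, adapt_every = 250, seed = 8),
                  dt = 0.2, n_init = 10, optim_starts = 1, optim_maxit = 40)
  obj <- study_objective(spec, st$obs, dt = 0.2)
  d1 <- dic(ch, log_lik = obj)
  f <- tempfile(fileext = ".csv")
  write_chain(ch, f)
  re <- read_chain(f)
  d2 <- dic(re, log_lik = obj)
  expect_lt(max(abs(d1 - d2)), 1e-9)
  # independent summation from the CSV
  dbar <- mean(-2 * re$log_lik)
  pd <- dbar + 2 * obj(colMeans(re$samples))
  expect_equal(unname(d1["DIC"]), dbar + pd, tolerance = 1e-9)
})

test_that("effective parameter count is about 1 for a 1-parameter toy", {
  z <- 0.7; sigma <- 0.25
  ll <- function(theta) -(z - theta[["a"]])^2 / (2 * sigma^2)
  b <- cbind(min = -10, max = 10); rownames(b) <- "a"
  ch <- run_mcmc(ll, b, mcmc_config(S = 40000, D = 50, seed = 12),
                 init_optim = FALSE)
  d <- dic(ch, log_lik = ll)
  expect_equal(unname(d["p_D"]), 1, tolerance = 0.1)
})

test_that("weighted DIC is the data-point-weighted average", {
  expect_equal(weighted_dic(c(20, 40), c(10, 30)), 35)
  expect_equal(weighted_dic(c(20, 40), c(5, 5)), 30)   # equal n: plain mean
  expect_equal(weighted_dic(42, 17), 42)               # single study
  expect_error(weighted_dic(numeric(0), numeric(0)), "no studies")
  d <- runif(10, 10, 60); n <- sample(5:30, 10)
  w <- weighted_dic(d, n)
  expect_gte(w, min(d)); expect_lte(w, max(d))
})

test_that("model likelihood reproduces the published four-model comparison", {
  # weighted DICs from a published four-model evaluation of this kind
  dic_w <- c(conventional = 50.92, interactive = 16.66,
             michaelis_menten = 30.58, reverse_michaelis_menten = 18.47)
  ml <- model_likelihood(dic_w)
  expect_equal(unname(ml$L["interactive"]), 1)
  expect_lt(ml$L[["conventional"]], 0.01)
  expect_lt(ml$L[["michaelis_menten"]], 0.01)
  expect_equal(unname(ml$L["reverse_michaelis_menten"]), 0.41,
               tolerance = 0.02)  # printed value is rounded to 2 digits
  expect_identical(ml$selected, "interactive")
  # invariance to a constant shift and ties
  ml2 <- model_likelihood(dic_w + 100)
  expect_equal(ml$L, ml2$L, tolerance = 1e-12)
  tie <- model_likelihood(c(a = 5, b = 5, c = 9))
  expect_equal(unname(tie$L[c("a", "b")]), c(1, 1))
})

test_that("within-sample regression matches the closed-form OLS oracle", {
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2)
  y <- c(0.15, 0.45, 1.05, 1.30, 2.25)
  ev <- within_sample_eval(x, y)
  # textbook least squares
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  r2 <- 1 - sum((y - ahat - bhat * x)^2) / sum((y - mean(y))^2)
  expect_equal(ev$slope, bhat, tolerance = 1e-10)
  expect_equal(ev$intercept, ahat, tolerance = 1e-10)
  expect_equal(ev$r_squared, r2, tolerance = 1e-10)
  # perfect and proportional predictions (lm warns about the exact fit)
  ev2 <- suppressWarnings(within_sample_eval(x, x))
  expect_equal(ev2$slope, 1); expect_equal(ev2$r_squared, 1)
  expect_equal(suppressWarnings(within_sample_eval(x, 2 * x))$slope, 2)
  expect_error(within_sample_eval(rep(1, 5), x), "zero variance")
  expect_error(within_sample_eval(x[1:2], y[1:2]), "at least 3")
})

test_that("fixed-mode validation on same-soil data recovers the design", {
  # train and validation studies generated from the same soil and truth,
  # differing only in the added-C amount; noise-free
  spec <- model_spec("interactive")
  th <- params_interactive()
  soc <- 20
  make_obs <- function(added, id) {
    tt <- seq(7, 70, by = 7)
    trt <- simulate_model(spec, th, soc = soc, added = added,
                          times = c(0, tt))
    ctl <- simulate_model(spec, th, soc = soc, added = 0, times = c(0, tt))
    rows <- rbind(
      data.frame(series = "old_control", time_d = tt,
                 cum_co2 = ctl$co2_unlabeled[-1]),
      data.frame(series = "old_treatment", time_d = tt,
                 cum_co2 = trt$co2_unlabeled[-1]),
      data.frame(series = "new_treatment", time_d = tt,
                 cum_co2 = trt$co2_labeled[-1]))
    rows$sd <- pmax(0.05 * rows$cum_co2, 0.01 * added)
    observation_set(id, soc = soc, added = added, nc_category = "low",
                    observations = rows)
  }
  train <- make_obs(0.4, "train")   # 2% of SOC
  valid <- make_obs(1.0, "valid")   # 5% of SOC
  ev <- validate_fixed(spec, train, valid,
                       config = mcmc_config(S = 2000, adapt_every = 250,
                                            seed = 5), bounds = NULL)
  expect_gt(ev$r_squared, 0.95)
  expect_equal(ev$slope, 1, tolerance = 0.1)
  expect_error(validate_fixed(spec, train,
                              make_obs_soc_mismatch <- {
                                v <- valid; v$soc <- 30; v
                              }), "same soil")
})

test_that("stratified half-split balances the added-C distribution", {
  set.seed(14)
  frac <- exp(runif(20, log(0.01), log(0.2)))
  ps <- replicate(20, {
    g1 <- stratified_half_split(frac)
    suppressWarnings(ks.test(frac[g1], frac[-g1])$p.value)
  })
  expect_gt(mean(ps > 0.05), 0.9)
  # group sizes are balanced
  g1 <- stratified_half_split(frac)
  expect_lte(abs(length(g1) - 10), 2)
})

test_that("random-mode validation is deterministic given the split seed", {
  set.seed(1)
  coll <- generate_collection(synth_config(n_studies = 8, noise_cv = 0,
                                           seed = 77))
  v1 <- validate_random(model_spec("interactive"), coll$studies,
                        split_seed = 3,
                        config = mcmc_config(S = 1500, adapt_every = 250),
                        dt = 0.2, n_init = 15, optim_starts = 2,
                        optim_maxit = 80)
  v2 <- validate_random(model_spec("interactive"), coll$studies,
                        split_seed = 3,
                        config = mcmc_config(S = 1500, adapt_every = 250),
                        dt = 0.2, n_init = 15, optim_starts = 2,
                        optim_maxit = 80)
  expect_identical(v1$train_ids, v2$train_ids)
  expect_equal(v1$eval$r_squared, v2$eval$r_squared, tolerance = 1e-12)
  # noise-free synthetic collection: near-perfect out-of-sample agreement
  expect_gt(v1$eval$r_squared, 0.95)
  expect_error(validate_random(model_spec("interactive"),
                               coll$studies[1:3], split_seed = 1),
               "at least 4")
})
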