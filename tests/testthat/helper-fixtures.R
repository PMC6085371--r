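# shared fixtures: small valid parameter sets and a toy observation builder

params_interactive <- function(K_N = 0.03, K_O = 5e-4, r = 0.45,
                               K_p = 1e-4, p = 0.5, f_N = 0.05) {
  c(K_N = K_N, K_O = K_O, r = r, K_p = K_p, p = p, f_N = f_N)
}

params_conventional <- function() {
  c(K_N = 0.04, a_LN = 0.3, a_RN = 0.15, f_L = 0.1,
    K_L_c = 0.03, K_R_c = 6e-4, a_LR_c = 0.05, a_RL_c = 0.3,
    K_L_t = 0.035, K_R_t = 9e-4, a_LR_t = 0.05, a_RL_t = 0.35)
}

params_mm <- function() {
  c(V_N = 0.5, V_O = 0.05, K_N = 5, K_O = 50, mu_B = 0.02, eps = 0.4,
    f_N = 0.04, f_B = 0.02)
}

params_rmm <- function() {
  c(mu_N = 0.1, mu_O = 0.002, mu_B = 0.02, K_B = 2, eps = 0.4,
    f_N = 0.04, f_B = 0.02)
}

all_model_params <- function() {
  list(conventional = params_conventional(),
       interactive = params_interactive(),
       michaelis_menten = params_mm(),
       reverse_michaelis_menten = params_rmm())
}

# random valid parameter draw within realistic scales, per model
random_params <- function(model, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  u <- function(a, b) stats::runif(1, a, b)
  switch(model,
    conventional = c(K_N = u(0.01, 0.2), a_LN = u(0.1, 0.5),
                     a_RN = u(0.05, 0.4), f_L = u(0.05, 0.3),
                     K_L_c = u(0.01, 0.1), K_R_c = u(1e-4, 2e-3),
                     a_LR_c = u(0, 0.2), a_RL_c = u(0.1, 0.5),
                     K_L_t = u(0.01, 0.1), K_R_t = u(1e-4, 2e-3),
                     a_LR_t = u(0, 0.2), a_RL_t = u(0.1, 0.5)),
    interactive = params_interactive(K_N = u(0.01, 0.1), K_O = u(1e-4, 2e-3),
                                     r = u(0.2, 0.7), K_p = u(0, 5e-4),
                                     p = u(0.2, 1.2), f_N = u(0, 0.2)),
    michaelis_menten = c(V_N = u(0.1, 2), V_O = u(0.01, 0.2),
                         K_N = u(1, 20), K_O = u(10, 80),
                         mu_B = u(0.005, 0.05), eps = u(0.2, 0.6),
                         f_N = u(0, 0.1), f_B = u(0.01, 0.05)),
    reverse_michaelis_menten = c(mu_N = u(0.02, 0.3), mu_O = u(5e-4, 5e-3),
                                 mu_B = u(0.005, 0.05), K_B = u(0.5, 10),
                                 eps = u(0.2, 0.6), f_N = u(0, 0.1),
                                 f_B = u(0.01, 0.05)))
}

# toy observation set with hand-set values (valid under selection criteria)
toy_obs <- function(times = c(7, 21, 35), z = list(
                      old_control = c(0.2, 0.5, 0.7),
                      old_treatment = c(0.25, 0.62, 0.9),
                      new_treatment = c(0.3, 0.5, 0.6)),
                    sd = 0.05, soc = 20, added = 1) {
  rows <- do.call(rbind, lapply(names(z), function(s)
    data.frame(series = s, time_d = times, cum_co2 = z[[s]], sd = sd)))
  observation_set("toy", soc = soc, added = added, nc_category = "low",
                  observations = rows)
}

# quick noise-free synthetic study + truth at a fixed seed
quick_synth <- function(seed = 42, noise_cv = 0) {
  generate_study(synth_config(noise_cv = noise_cv, seed = seed), seed = seed)
}
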