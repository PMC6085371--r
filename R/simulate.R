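#' Forcing: substrate additions and continuous C input
#'
#' @param impulses data frame with columns `time` (day), `amount`
#'   (mg C per g soil) and `labeled` (logical); one-time substrate additions.
#' @param input_times,input_rates breakpoints of a piecewise-linear continuous
#'   input rate I(t) (mg C per g soil per day); empty means no continuous input.
#' @param input_labeled whether the continuous input is isotope-labelled.
#' @return a `soc_forcing` list.
#' @export
forcing <- function(impulses = NULL, input_times = numeric(),
                    input_rates = numeric(), input_labeled = FALSE) {
  if (is.null(impulses))
    impulses <- data.frame(time = numeric(), amount = numeric(),
                           labeled = logical())
  stopifnot(all(c("time", "amount", "labeled") %in% names(impulses)),
            length(input_times) == length(input_rates))
  if (any(impulses$amount < 0)) stop("impulse amounts must be nonnegative")
  if (any(input_rates < 0)) stop("input rates must be nonnegative")
  if (is.unsorted(input_times)) stop("input_times must be nondecreasing")
  structure(list(impulses = impulses[order(impulses$time), , drop = FALSE],
                 input_times = as.numeric(input_times),
                 input_rates = as.numeric(input_rates),
                 input_labeled = isTRUE(input_labeled)),
            class = "soc_forcing")
}

# total C added up to each time (impulses + integral of the input schedule)
cumulative_input <- function(forc, times) {
  imp <- vapply(times, function(t)
    sum(forc$impulses$amount[forc$impulses$time <= t + 1e-9]), numeric(1))
  if (length(forc$input_times) == 0) return(imp)
  ft <- forc$input_times; fr <- forc$input_rates
  rate_at <- function(t) {
    if (t <= ft[1]) return(fr[1])
    if (t >= ft[length(ft)]) return(fr[length(fr)])
    stats::approx(ft, fr, xout = t)$y
  }
  integral_to <- function(t) {
    if (t <= 0) return(0)
    knots <- c(0, ft[ft > 0 & ft < t], t)
    knots <- sort(unique(knots))
    r <- vapply(knots, rate_at, numeric(1))
    sum(diff(knots) * (utils::head(r, -1) + utils::tail(r, -1)) / 2)
  }
  imp + vapply(times, integral_to, numeric(1))
}

#' Simulate a soil C decomposition model
#'
#' Fixed-step classical 4th-order Runge-Kutta (default `dt = 0.05` day) with
#' linear interpolation onto the requested output times. All compartments are
#' tracked separately for labelled and unlabelled C, and cumulative CO2 is
#' accounted by source pool (new substrate vs old SOC) and label, so
#' (pools + cumulative CO2 - cumulative inputs) is conserved.
#'
#' @param spec a `soc_model` from [model_spec()].
#' @param params named parameter vector (validated against `spec`).
#' @param state0 initial state from [initial_state()], or `NULL` to build one
#'   from `soc`/`added`.
#' @param times output times in days, sorted, `>= 0`.
#' @param forc a [forcing()] object; default: nothing beyond `state0`.
#' @param soc,added convenience shortcut for [initial_state()].
#' @param arm `"treatment"` or `"control"`; selects the conventional model's
#'   arm-specific parameter set (ignored by the other models).
#' @param dt integrator step, days.
#' @return a `soc_trajectory`: data frame with `time` and the model's state
#'   columns, plus derived columns `co2_new` (labelled + unlabelled from the
#'   new pool), `co2_old`, `co2_labeled`, `co2_unlabeled` and `total_c`.
#' @export
#' @examples
#' sp <- model_spec("interactive")
#' p <- c(K_N = 0.02, K_O = 5e-4, r = 0.4, K_p = 1e-4, p = 0.5, f_N = 0.05)
#' tr <- simulate_model(sp, p, soc = 20, added = 1, times = 0:70)
#' head(tr)
simulate_model <- function(spec, params, state0 = NULL, times,
                           forc = forcing(), soc = NULL, added = 0,
                           arm = "treatment", dt = 0.05) {
  # prior boxes are a calibration concern; simulation enforces structure only
  nm <- spec$parameter_names
  if (!all(nm %in% names(params)))
    stop("missing parameters: ", paste(setdiff(nm, names(params)), collapse = ", "))
  params <- params[nm]
  if (any(!is.finite(params))) stop("non-finite parameter values")
  check_structural(spec, params)
  if (is.null(state0)) {
    if (is.null(soc)) stop("provide state0 or soc")
    state0 <- initial_state(spec, params, soc, added)
  }
  if (length(state0) != length(state_names(spec)))
    stop("state0 length does not match model ", spec$name)
  if (any(state0 < 0)) stop("state0 must be nonnegative")
  if (is.unsorted(times, strictly = FALSE) || any(times < 0))
    stop("times must be sorted and nonnegative")
  cp <- core_params(spec, params, arm)
  res <- simulate_cpp(spec$id, cp, as.numeric(state0), as.numeric(times), dt,
                      forc$input_times, forc$input_rates, forc$input_labeled,
                      forc$impulses$time, forc$impulses$amount,
                      forc$impulses$labeled)
  if (!res$ok)
    stop("divergent simulation: non-finite or negative state for model ",
         spec$name, " (reject this parameter set)")
  y <- res$state
  colnames(y) <- state_names(spec)
  out <- data.frame(time = as.numeric(times), y, check.names = FALSE)
  out$co2_new <- out$co2_new_labeled + out$co2_new_unlabeled
  out$co2_old <- out$co2_old_labeled + out$co2_old_unlabeled
  out$co2_labeled <- out$co2_new_labeled + out$co2_old_labeled
  out$co2_unlabeled <- out$co2_new_unlabeled + out$co2_old_unlabeled
  pool_cols <- setdiff(state_names(spec),
                       c("co2_new_labeled", "co2_new_unlabeled",
                         "co2_old_labeled", "co2_old_unlabeled"))
  out$total_c <- rowSums(out[pool_cols]) + out$co2_new + out$co2_old
  attr(out, "spec") <- spec
  attr(out, "pool_cols") <- pool_cols
  attr(out, "initial_total") <- sum(state0)
  attr(out, "inputs") <- cumulative_input(forc, times)
  class(out) <- c("soc_trajectory", "data.frame")
  out
}

check_structural <- function(spec, params) {
  rates <- switch(spec$name,
    conventional = c("K_N", "K_L_c", "K_R_c", "K_L_t", "K_R_t"),
    interactive = c("K_N", "K_O"),
    michaelis_menten = c("V_N", "V_O", "K_N", "K_O", "mu_B"),
    reverse_michaelis_menten = c("mu_N", "mu_O", "mu_B", "K_B"))
  if (any(params[rates] <= 0)) stop("rate parameters must be positive")
  fracs <- intersect(names(params),
                     c("r", "eps", "f_L", "f_N", "f_B",
                       "a_LN", "a_RN", "a_LR_c", "a_RL_c", "a_LR_t", "a_RL_t"))
  if (any(params[fracs] < 0 | params[fracs] > 1))
    stop("fractions and transfer coefficients must lie in [0, 1]")
  if ("K_p" %in% names(params) && params["K_p"] < 0) stop("K_p must be >= 0")
  if ("p" %in% names(params) && params["p"] < 0) stop("p must be >= 0")
  invisible(params)
}

#' Mass-balance residual of a trajectory
#'
#' (total pool C + total cumulative CO2) - (initial pool C + cumulative
#' inputs) at every output time; zero up to solver tolerance.
#'
#' @param traj a `soc_trajectory`.
#' @return numeric vector of residuals, mg C per g soil.
#' @export
mass_balance <- function(traj) {
  traj$total_c - attr(traj, "initial_total") - attr(traj, "inputs")
}

#' Tidy export of a trajectory
#'
#' @param traj a `soc_trajectory`.
#' @return data frame with columns `time_d`, `series`, `value`.
#' @export
tidy_trajectory <- function(traj) {
  cols <- setdiff(names(traj), "time")
  data.frame(
    time_d = rep(traj$time, length(cols)),
    series = rep(cols, each = nrow(traj)),
    value = unlist(traj[cols], use.names = FALSE))
}

#' Closed-form decay of an isolated new-C pool
#'
#' `N(t) = N0 * exp(-K_N * t)`; analytic oracle for integrator validation.
#'
#' @param N0 initial mass (mg C per g soil), `>= 0`.
#' @param K_N decay rate per day, `> 0`.
#' @param t time in days, `>= 0`.
#' @return remaining mass.
#' @export
closed_form_new_pool <- function(N0, K_N, t) {
  stopifnot(N0 >= 0, K_N > 0)
  if (any(t < 0)) stop("t must be nonnegative")
  N0 * exp(-K_N * t)
}

#' Steady state under constant C input
#'
#' For the interactive model the fixed point is algebraic:
#' `N* = I / K_N`, `O* = r * I / (K_O + K_p * N*^p)`; the result is verified
#' against the model derivatives. Other models are solved by long forward
#' integration until all derivatives fall below `tol`.
#'
#' @param spec a `soc_model`.
#' @param params named parameter vector.
#' @param input_rate constant input I, mg C per g soil per day, `> 0`
#'   (`0` returns the empty state).
#' @param tol derivative tolerance (mg C per g soil per day).
#' @param max_days integration cap for the numerical fallback.
#' @return named pool vector at steady state (no CO2 ledger).
#' @export
steady_state <- function(spec, params, input_rate, tol = 1e-10,
                         max_days = 2e5) {
  stopifnot(input_rate >= 0)
  pool_nm <- utils::head(state_names(spec), -4)
  if (input_rate == 0)
    return(stats::setNames(rep(0, length(pool_nm)), pool_nm))
  if (spec$name == "interactive") {
    Nst <- input_rate / params[["K_N"]]
    Ost <- params[["r"]] * input_rate /
      (params[["K_O"]] + params[["K_p"]] * Nst^params[["p"]])
    st <- c(N_l = 0, O_l = 0, N_u = unname(Nst), O_u = unname(Ost))
    d <- interactive_derivs(params, st, input_rate)
    if (max(abs(d)) > tol)
      stop("steady-state residual ", format(max(abs(d))), " exceeds tolerance")
    return(st)
  }
  # numerical spin-up for the other models
  npool <- length(state_names(spec)) - 4
  st <- rep(0, npool + 4)
  forc <- forcing(input_times = c(0, max_days),
                  input_rates = c(input_rate, input_rate))
  span <- 5000
  t_done <- 0
  repeat {
    tr <- simulate_model(spec, params, state0 = st, times = c(0, span),
                         forc = forc)
    new <- as.numeric(tr[2, 1 + seq_len(npool + 4)])
    rate <- max(abs(new[seq_len(npool)] - st[seq_len(npool)])) / span
    st <- new
    st[npool + seq_len(4)] <- 0
    t_done <- t_done + span
    if (rate < tol) break
    if (t_done >= max_days)
      stop("steady state not reached: residual rate ", format(rate))
  }
  stats::setNames(st[seq_len(npool)], utils::head(state_names(spec), -4))
}

# derivatives of the interactive model's four pools (used for verification)
interactive_derivs <- function(params, st, input_rate = 0,
                               input_labeled = FALSE) {
  KN <- params[["K_N"]]; KO <- params[["K_O"]]; r <- params[["r"]]
  Kp <- params[["K_p"]]; pw <- params[["p"]]
  N <- st[["N_l"]] + st[["N_u"]]
  ktot <- KO + if (N > 0 && Kp > 0) Kp * N^pw else 0
  Il <- if (input_labeled) input_rate else 0
  Iu <- if (input_labeled) 0 else input_rate
  c(N_l = Il - KN * st[["N_l"]],
    O_l = KN * st[["N_l"]] * r - ktot * st[["O_l"]],
    N_u = Iu - KN * st[["N_u"]],
    O_u = KN * st[["N_u"]] * r - ktot * st[["O_u"]])
}
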