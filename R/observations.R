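SERIES_LEVELS <- c("old_control", "old_treatment", "new_treatment")

#' Construct an incubation observation set
#'
#' Bundles one study's three cumulative-CO2 series - CO2 from old SOC in the
#' control, from old SOC under substrate addition, and from the added
#' (labelled) substrate - with the study metadata the models need.
#'
#' @param study_id character scalar.
#' @param soc native SOC content, mg C per g soil.
#' @param added labelled substrate added at `t = 0`, mg C per g soil.
#' @param nc_category substrate N:C category: `"none"`, `"low"` or `"high"`.
#' @param observations data frame with columns `series` (one of
#'   `"old_control"`, `"old_treatment"`, `"new_treatment"`), `time_d`,
#'   `cum_co2` (mg C per g soil) and `sd` (same units; `NA` allowed, see
#'   [obs_sigma()]).
#' @param n_rep replicate count reported by the study (used as the
#'   meta-analysis sample size).
#' @param validate check the data-collection selection criteria
#'   (see [validate_study()]).
#' @return an object of class `soc_obs`.
#' @export
observation_set <- function(study_id, soc, added,
                            nc_category = c("none", "low", "high"),
                            observations, n_rep = 3, validate = TRUE) {
  nc_category <- match.arg(nc_category)
  stopifnot(is.data.frame(observations),
            all(c("series", "time_d", "cum_co2", "sd") %in% names(observations)),
            soc > 0, added >= 0, n_rep >= 1)
  if (!all(observations$series %in% SERIES_LEVELS))
    stop("unknown series label(s): ",
         paste(setdiff(observations$series, SERIES_LEVELS), collapse = ", "))
  observations <- observations[order(match(observations$series, SERIES_LEVELS),
                                     observations$time_d), , drop = FALSE]
  rownames(observations) <- NULL
  obj <- structure(list(study_id = as.character(study_id), soc = soc,
                        added = added, nc_category = nc_category,
                        observations = observations, n_rep = n_rep),
                   class = "soc_obs")
  if (validate) validate_study(obj)
  obj
}

#' @export
print.soc_obs <- function(x, ...) {
  cat("<soc_obs> study ", x$study_id, ": SOC ", x$soc, ", added ", x$added,
      " mg C/g (", round(100 * x$added / x$soc, 1), "% of SOC), N:C ",
      x$nc_category, ", ", nrow(x$observations), " observations\n", sep = "")
  invisible(x)
}

#' Validate a study against the data-collection selection criteria
#'
#' The selection rules applied to candidate incubation studies: (1) both a
#' control and a labelled-addition treatment are present (all three series),
#' (2) SOC content, added C amount and more than 2 time points per series are
#' reported, (3) the experiment lasted at least 28 days. Cumulative series
#' must be nondecreasing with strictly increasing times.
#'
#' @param obs a `soc_obs` (or a list with the same fields).
#' @return `TRUE` invisibly; otherwise an error listing every violation.
#' @export
validate_study <- function(obs) {
  problems <- character()
  o <- obs$observations
  missing_series <- setdiff(SERIES_LEVELS, unique(o$series))
  if (length(missing_series))
    problems <- c(problems, paste0("missing series: ",
                                   paste(missing_series, collapse = ", ")))
  if (!isTRUE(obs$soc > 0)) problems <- c(problems, "SOC content not reported")
  if (!isTRUE(obs$added > 0))
    problems <- c(problems, "added C amount not reported")
  for (s in intersect(SERIES_LEVELS, unique(o$series))) {
    d <- o[o$series == s, ]
    if (nrow(d) <= 2)
      problems <- c(problems, paste0(s, ": needs > 2 time points"))
    if (any(diff(d$time_d) <= 0))
      problems <- c(problems, paste0(s, ": times not strictly increasing"))
    if (any(diff(d$cum_co2) < 0))
      problems <- c(problems, paste0(s, ": cumulative CO2 decreases"))
    if (max(d$time_d) < 28)
      problems <- c(problems,
                    paste0(s, ": minimum duration 28 days not reached"))
  }
  if (any(o$cum_co2 < 0)) problems <- c(problems, "negative cumulative CO2")
  if (length(problems))
    stop("study ", obs$study_id, " fails selection criteria:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Measurement standard deviations with fallback
#'
#' Missing or non-positive SDs fall back to
#' `max(5% of the observed value, 1% of the added C)`, with a warning.
#'
#' @param obs a `soc_obs`.
#' @param warn warn when the fallback is used.
#' @return numeric vector of SDs aligned with `obs$observations`.
#' @export
obs_sigma <- function(obs, warn = TRUE) {
  o <- obs$observations
  sd <- o$sd
  bad <- !is.finite(sd) | sd <= 0
  if (any(bad)) {
    if (warn)
      warning("study ", obs$study_id, ": ", sum(bad),
              " observation(s) without SD; using max(5% of value, 1% of added C)")
    sd[bad] <- pmax(0.05 * o$cum_co2[bad], 0.01 * obs$added)
  }
  sd
}

#' Gaussian log-likelihood of a fitted trajectory pair
#'
#' `-(1/2) * sum over series and times of (Z - X)^2 / sigma^2`, the log of the
#' calibration likelihood up to an additive constant. `X` is read from the
#' simulated cumulative-CO2 series: unlabelled CO2 for the two old-SOC series
#' (control/treatment arm respectively), labelled CO2 for the new-substrate
#' series.
#'
#' @param traj_treatment,traj_control `soc_trajectory` objects covering all
#'   observation times.
#' @param obs a `soc_obs`.
#' @param sigma optional SD vector; default [obs_sigma()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(traj_treatment, traj_control, obs, sigma = NULL) {
  o <- obs$observations
  if (is.null(sigma)) sigma <- obs_sigma(obs, warn = FALSE)
  x <- modeled_values(traj_treatment, traj_control, o)
  -sum((o$cum_co2 - x)^2 / (2 * sigma^2))
}

modeled_values <- function(traj_treatment, traj_control, o) {
  pick <- function(traj, col, tt) {
    if (min(tt) < min(traj$time) - 1e-9 || max(tt) > max(traj$time) + 1e-9)
      stop("trajectory does not cover the observation times")
    stats::approx(traj$time, traj[[col]], xout = tt)$y
  }
  x <- numeric(nrow(o))
  i <- o$series == "old_control"
  if (any(i)) x[i] <- pick(traj_control, "co2_unlabeled", o$time_d[i])
  i <- o$series == "old_treatment"
  if (any(i)) x[i] <- pick(traj_treatment, "co2_unlabeled", o$time_d[i])
  i <- o$series == "new_treatment"
  if (any(i)) x[i] <- pick(traj_treatment, "co2_labeled", o$time_d[i])
  x
}

#' Read / write observation sets as CSV
#'
#' CSV dialect: comma-separated, UTF-8, header, one observation per row with
#' columns `study_id, series, time_d, cum_co2, sd, soc, added, nc_category,
#' n_rep` (metadata repeated per row). A file may hold several studies.
#'
#' @param path file path.
#' @return `read_observations()`: a named list of `soc_obs`.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "series", "time_d", "cum_co2", "sd", "soc", "added",
            "nc_category", "n_rep")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  out <- lapply(split(d, d$study_id), function(s) {
    observation_set(s$study_id[1], soc = s$soc[1], added = s$added[1],
                    nc_category = s$nc_category[1],
                    observations = s[c("series", "time_d", "cum_co2", "sd")],
                    n_rep = s$n_rep[1])
  })
  out[order(names(out))]
}

#' @rdname read_observations
#' @param studies a `soc_obs` or list of them.
#' @export
write_observations <- function(studies, path) {
  if (inherits(studies, "soc_obs")) studies <- list(studies)
  rows <- lapply(studies, function(s) {
    cbind(study_id = s$study_id, s$observations,
          soc = s$soc, added = s$added, nc_category = s$nc_category,
          n_rep = s$n_rep)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
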