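#' Monte Carlo patient-cohort simulation
#'
#' Seedable stochastic counterpart of the analytic model, used as an
#' independent check on the quadrature expectations. Each simulated patient
#' draws a growth rate `g ~ Normal(g_mean, g_sd)`; local control at delay
#' `t` is a Bernoulli event with the Poisson-zero probability
#' `exp(-s * p0 * e^{g t})`, and a new metastasis occurs with probability
#' `1 - exp(-Lambda(g, t))` from the cumulative hazard. All draws are made
#' in a fixed vectorized order from the single seed: patient `i` always
#' consumes the `i`-th variate of each stream, so the result does not
#' depend on evaluation order and identical seeds give identical results.
#'
#' @param params A [tumor_params()].
#' @param t Delay (months, >= 0).
#' @param n Cohort size (>= 1).
#' @param seed Integer RNG seed.
#' @param control_mode `"bernoulli"` (default) draws the control event
#'   directly with the Poisson-zero probability; `"poisson_count"` samples
#'   the surviving clonogen count and declares control iff it is zero. The
#'   two are identical in distribution.
#' @return An object of class `cohort_result`: a list with `n`,
#'   `control_fraction`, `metastasis_fraction`, binomial standard errors
#'   `control_se` and `metastasis_se`, the `seed`, the delay `t`, and a
#'   parameter fingerprint.
#' @examples
#' hn <- published_parameters("head_and_neck")
#' simulate_cohort(hn, t = 2, n = 1e4, seed = 1)
#' @export
simulate_cohort <- function(params, t, n, seed,
                            control_mode = c("bernoulli", "poisson_count")) {
  control_mode <- match.arg(control_mode)
  check_delay(t)
  if (!is.numeric(n) || n < 1) stop("cohort size n must be >= 1")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- stats::rnorm(n, params$g_mean, params$g_sd)
  p_control <- tumor_control_probability(params, g, t)
  controlled <- if (control_mode == "bernoulli") {
    stats::runif(n) < p_control
  } else {
    stats::rpois(n, params$s * primary_cell_count(params, g, t)) == 0L
  }
  p_met <- metastasis_probability(params, g, t)
  metastasized <- stats::runif(n) < p_met
  cf <- mean(controlled)
  mf <- mean(metastasized)
  structure(
    list(n = n,
         control_fraction = cf,
         metastasis_fraction = mf,
         control_se = sqrt(cf * (1 - cf) / n),
         metastasis_se = sqrt(mf * (1 - mf) / n),
         seed = seed, t = t,
         control_mode = control_mode,
         params_fingerprint = params_fingerprint(params)),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "Cohort of %d at t = %g months (seed %s):\n", x$n, x$t,
    format(x$seed)))
  cat(sprintf("  local control    %.4f (SE %.2g)\n",
              x$control_fraction, x$control_se))
  cat(sprintf("  new metastasis   %.4f (SE %.2g)\n",
              x$metastasis_fraction, x$metastasis_se))
  invisible(x)
}

params_fingerprint <- function(params) {
  paste(params$label,
        paste(format(c(params$p0, params$s, params$g_mean, params$g_sd,
                       params$k, params$m0), digits = 17),
              collapse = ","),
        sep = ":")
}

#' Serialize a cohort result to JSON
#'
#' @param result A `cohort_result` from [simulate_cohort()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string or (invisibly) `path`.
#' @export
cohort_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  x <- unclass(result)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Simulate metastasis event times for one patient
#'
#' Draws the event times of the nonhomogeneous Poisson metastasis process
#' with rate `M(u)` on `[0, t_max]` by thinning: candidate events from a
#' homogeneous process at the majorant rate `M(t_max)` (the hazard is
#' nondecreasing in time for every sign of `g`, since the primary count is
#' positive) are accepted with probability `M(u) / M(t_max)`. The empirical
#' first-event distribution converges to [metastasis_probability()].
#'
#' @param params A [tumor_params()].
#' @param g Growth rate for this patient.
#' @param t_max Simulation horizon (months, >= 0).
#' @param seed Integer RNG seed.
#' @return Sorted numeric vector of event times in `[0, t_max]` (possibly
#'   empty).
#' @export
simulate_event_times <- function(params, g, t_max, seed) {
  check_delay(t_max)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rate_max <- metastasis_hazard(params, g, t_max)
  if (rate_max <= 0 || t_max == 0) return(numeric(0))
  n_cand <- stats::rpois(1L, rate_max * t_max)
  if (n_cand == 0L) return(numeric(0))
  u <- stats::runif(n_cand, 0, t_max)
  keep <- stats::runif(n_cand) < metastasis_hazard(params, g, u) / rate_max
  sort(u[keep])
}
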