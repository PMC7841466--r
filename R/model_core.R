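#' Construct a tumor parameter set
#'
#' Bundles the five adjustable parameters of the delay-risk model, plus the
#' initial metastasis hazard, for one cancer type. The model tracks a primary
#' tumor growing exponentially from `p0` cells at diagnosis, seeding new
#' metastases at a hazard proportional to the current cell count, and treated
#' at delay `t` with clonogen surviving fraction `s`.
#'
#' @param p0 Initial number of primary tumor cells at diagnosis (> 0).
#' @param s Surviving fraction of tumor cells after treatment, in (0, 1).
#' @param g_mean Mean tumor growth rate G (per month).
#' @param g_sd Standard deviation of the growth rate across patients
#'   (per month, >= 0). Zero gives the single-growth-rate model.
#' @param k Metastasis formation proportionality constant
#'   (per month per cell, >= 0).
#' @param m0 Initial metastasis hazard at diagnosis (per month, >= 0).
#'   Zero corresponds to no metastases at primary diagnosis.
#' @param label Cancer-type identifier.
#'
#' @return An object of class `tumor_params`.
#' @examples
#' hn <- tumor_params(p0 = 1.41e9, s = 7.45e-11, g_mean = 0.210,
#'                    g_sd = 0.0282, k = 1.51e-12, label = "head_and_neck")
#' tumor_control_probability(hn, g = hn$g_mean, t = 2)
#' @export
tumor_params <- function(p0, s, g_mean, g_sd, k, m0 = 0, label = "tumor") {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(g_mean), length(g_mean) == 1L, is.finite(g_mean),
            is.numeric(g_sd), length(g_sd) == 1L, is.finite(g_sd),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(m0), length(m0) == 1L, is.finite(m0))
  if (p0 <= 0) stop("p0 must be positive")
  if (s <= 0 || s >= 1) stop("s must lie strictly between 0 and 1")
  if (g_sd < 0) stop("g_sd must be nonnegative")
  if (k < 0) stop("k must be nonnegative")
  if (m0 < 0) stop("m0 must be nonnegative")
  structure(
    list(p0 = p0, s = s, g_mean = g_mean, g_sd = g_sd, k = k, m0 = m0,
         label = as.character(label)),
    class = "tumor_params"
  )
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("Tumor parameter set:", x$label, "\n")
  cat(sprintf("  P0 (cells)        %.3g\n", x$p0))
  cat(sprintf("  S  (surv. frac.)  %.3g\n", x$s))
  cat(sprintf("  G  (per month)    %.3g\n", x$g_mean))
  cat(sprintf("  sigma (per month) %.3g\n", x$g_sd))
  cat(sprintf("  k  (/month/cell)  %.3g\n", x$k))
  cat(sprintf("  M0 (per month)    %.3g\n", x$m0))
  invisible(x)
}

check_delay <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("delay time t must be nonnegative and finite (months)")
  }
  t
}

#' Primary tumor cell count after a treatment delay
#'
#' Exponential growth of the primary tumor: `P(t) = P0 * exp(g * t)`.
#' Negative growth rates (spontaneous regression) and `g = 0` (dormancy)
#' are valid.
#'
#' @param params A [tumor_params()] object.
#' @param g Growth rate (per month); may be negative, zero, or positive.
#' @param t Delay since diagnosis (months, >= 0). Vectorized over `g` and `t`.
#' @return Cell count(s).
#' @export
primary_cell_count <- function(params, g, t) {
  check_delay(t)
  params$p0 * exp(g * t)
}

# (exp(x) - 1) / x, continuous through x = 0.
# Series branch below 1e-8 guards the normal-mixture integration, which
# crosses g = 0 whenever g_sd is comparable to g_mean.
expm1_over_x <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)
  out[x == 0] <- 1
  out
}

# (exp(x) - 1 - x) / x^2, continuous through x = 0.
expm1m_over_x2 <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 0.5 + x / 6, (expm1(x) - x) / x^2)
  out[x == 0] <- 0.5
  out
}

#' Metastasis hazard at a given delay
#'
#' Instantaneous rate of new metastasis formation,
#' `M(t) = M0 + k * P0 * (exp(g*t) - 1) / g`, with the analytic limit
#' `M0 + k * P0 * t` at `g = 0`. The hazard is the time-integral of
#' `k * P(u)` plus the initial hazard, and is nondecreasing in `t` for any
#' sign of `g` because the primary count stays positive.
#'
#' @inheritParams primary_cell_count
#' @return Hazard(s) per month.
#' @export
metastasis_hazard <- function(params, g, t) {
  check_delay(t)
  params$m0 + params$k * params$p0 * t * expm1_over_x(g * t)
}

#' Cumulative metastasis hazard over a delay interval
#'
#' `Lambda(t) = integral of M(u) du` from 0 to `t`; in closed form
#' `M0*t + (k*P0/g) * ((exp(g*t) - 1)/g - t)`, with limit
#' `M0*t + k*P0*t^2/2` at `g = 0`.
#'
#' @inheritParams primary_cell_count
#' @return Dimensionless cumulative hazard(s).
#' @export
cumulative_hazard <- function(params, g, t) {
  check_delay(t)
  params$m0 * t + params$k * params$p0 * t^2 * expm1m_over_x2(g * t)
}

#' Probability of a new metastasis by a given delay
#'
#' Survival against the nonhomogeneous Poisson metastasis process:
#' `PM(t) = 1 - exp(-Lambda(t))`. Zero at `t = 0` when `m0 = 0`, and
#' monotone nondecreasing in `t`, `k`, and `p0`.
#'
#' @inheritParams primary_cell_count
#' @return Probability in \[0, 1).
#' @export
metastasis_probability <- function(params, g, t) {
  -expm1(-cumulative_hazard(params, g, t))
}

#' Local tumor control probability after a treatment delay
#'
#' Poisson clonogen-survival model: treatment at delay `t` leaves an expected
#' `S * P(t)` surviving tumor cells, and control requires zero survivors, so
#' `TCP(t) = exp(-S * P0 * exp(g*t))`. At `t = 0` this is `exp(-S*P0)`
#' regardless of the growth rate.
#'
#' @inheritParams primary_cell_count
#' @return Probability in (0, 1).
#' @export
tumor_control_probability <- function(params, g, t) {
  check_delay(t)
  exp(-params$s * params$p0 * exp(g * t))
}
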