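# Gauss-Hermite nodes are cached per node count; the probabilists' change
# of variables g = G + sqrt(2)*sigma*x turns the physicists' rule into an
# expectation over Normal(G, sigma).
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  }
  .gh_cache[[key]]
}

Z975 <- stats::qnorm(0.975)  # 1.959964...

#' Growth-rate probability density
#'
#' Density of the normal growth-rate mixture, mean `g_mean` and standard
#' deviation `g_sd`. Models inter-patient heterogeneity: some tumors grow
#' faster than average, some are dormant (`g = 0`), and some regress
#' (`g < 0`).
#'
#' @param params A [tumor_params()] with `g_sd > 0`.
#' @param g Growth rate(s) at which to evaluate the density.
#' @return Density value(s).
#' @export
growth_rate_density <- function(params, g) {
  if (params$g_sd <= 0) {
    stop("growth_rate_density requires g_sd > 0; ",
         "the degenerate case is handled by the expectation operators")
  }
  stats::dnorm(g, mean = params$g_mean, sd = params$g_sd)
}

#' Expectation of a model quantity over the growth-rate distribution
#'
#' Computes `E_g[f(g, t)]` for `g ~ Normal(g_mean, g_sd)` by Gauss-Hermite
#' quadrature. With `g_sd = 0` the mixture is degenerate and `f(g_mean, t)`
#' is returned directly.
#'
#' @param params A [tumor_params()].
#' @param t Delay time (months, >= 0).
#' @param f Function of `(g, t)`, vectorized in `g` — typically one of the
#'   closed-form model functions with `params` fixed.
#' @param nodes Number of quadrature nodes (default 128).
#' @return The expected value.
#' @examples
#' hn <- published_parameters("head_and_neck")
#' expect_over_growth(hn, 2, function(g, t) tumor_control_probability(hn, g, t))
#' @export
expect_over_growth <- function(params, t, f, nodes = 128L) {
  check_delay(t)
  if (params$g_sd == 0) {
    val <- f(params$g_mean, t)
  } else {
    rule <- gh_rule(nodes)
    g <- params$g_mean + sqrt(2) * params$g_sd * rule$x
    fx <- f(g, t)
    if (any(!is.finite(fx))) stop("non-finite integrand in growth-rate mixture")
    val <- sum(rule$w * fx) / sqrt(pi)
  }
  val
}

#' Percentile of a monotone model quantity over the growth-rate distribution
#'
#' For a quantity monotone in `g` at fixed `t` (true of tumor size,
#' metastasis probability, and TCP), the `q`-quantile of `f(g, t)` under
#' `g ~ Normal(g_mean, g_sd)` is `f` evaluated at a normal quantile of `g`:
#' at `g_mean + z_q * g_sd` when `f` is increasing in `g`, and at
#' `g_mean - z_q * g_sd` when decreasing (TCP decreases in `g`, so its
#' 2.5th percentile sits at the 97.5th growth-rate quantile).
#' Monotonicity is checked numerically on a probe grid and non-monotone
#' requests are rejected.
#'
#' @inheritParams expect_over_growth
#' @param q Quantile level in (0, 1).
#' @param increasing Is `f` increasing in `g`? If `NULL` (default), the
#'   direction is detected on a probe grid over `g_mean +/- 4 g_sd`.
#' @return The quantile value.
#' @export
quantile_over_growth <- function(params, t, f, q, increasing = NULL) {
  check_delay(t)
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  probe <- params$g_mean +
    seq(-4, 4, length.out = 17L) * max(params$g_sd, 1e-6)
  fp <- f(probe, t)
  d <- diff(fp)
  detected <- if (all(d >= -1e-13)) {
    TRUE
  } else if (all(d <= 1e-13)) {
    FALSE
  } else {
    stop("f is not monotone in g at this t; percentile semantics undefined")
  }
  if (is.null(increasing)) increasing <- detected
  z <- stats::qnorm(q)
  g_q <- params$g_mean + (if (increasing) z else -z) * params$g_sd
  f(g_q, t)
}

risk_estimate <- function(quantity, t, mean, lo, hi) {
  data.frame(quantity = quantity, t = t, mean = mean, lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Local-control loss from a treatment delay
#'
#' Expected loss of local tumor control probability, in percentage points,
#' relative to the no-delay baseline `exp(-s * p0)`:
#' `100 * (TCP(0) - E_g[TCP(t)])`. The 95% interval is the plug-in
#' percentile interval from TCP evaluated at `g_mean -/+ 1.96 * g_sd`
#' (TCP is decreasing in `g`, so the favorable bound `lo` comes from the
#' slow-growth quantile). When fast regression mass pushes the
#' 97.5th-percentile TCP above baseline the `lo` bound is negative; it is
#' reported as computed here and floored at 0 only for display.
#'
#' @param params A [tumor_params()].
#' @param t Delay (months); vectorized.
#' @param nodes Quadrature nodes for the mean.
#' @return A data frame with columns `quantity`, `t`, `mean`, `lo`, `hi`
#'   (percentage points).
#' @export
tcp_loss <- function(params, t, nodes = 128L) {
  check_delay(t)
  tcp0 <- exp(-params$s * params$p0)
  rows <- lapply(t, function(tt) {
    m <- expect_over_growth(params, tt, function(g, u) {
      tumor_control_probability(params, g, u)
    }, nodes = nodes)
    tcp_hi <- tumor_control_probability(params,
                                        params$g_mean - Z975 * params$g_sd, tt)
    tcp_lo <- tumor_control_probability(params,
                                        params$g_mean + Z975 * params$g_sd, tt)
    risk_estimate("tcp_loss", tt,
                  mean = 100 * (tcp0 - m),
                  lo = 100 * (tcp0 - tcp_hi),
                  hi = 100 * (tcp0 - tcp_lo))
  })
  do.call(rbind, rows)
}

#' New-metastasis risk from a treatment delay
#'
#' Expected probability of at least one new metastasis by delay `t`, in
#' percentage points: `100 * E_g[PM(t)]`, with the 95% percentile interval
#' from PM at `g_mean +/- 1.96 * g_sd` (PM is increasing in `g` for
#' `t > 0`). Zero at `t = 0` because the initial metastasis hazard is 0.
#'
#' @inheritParams tcp_loss
#' @return A data frame with columns `quantity`, `t`, `mean`, `lo`, `hi`
#'   (percentage points).
#' @export
metastasis_risk <- function(params, t, nodes = 128L) {
  check_delay(t)
  rows <- lapply(t, function(tt) {
    m <- expect_over_growth(params, tt, function(g, u) {
      metastasis_probability(params, g, u)
    }, nodes = nodes)
    pm_lo <- metastasis_probability(params,
                                    params$g_mean - Z975 * params$g_sd, tt)
    pm_hi <- metastasis_probability(params,
                                    params$g_mean + Z975 * params$g_sd, tt)
    risk_estimate("metastasis_prob", tt,
                  mean = 100 * m, lo = 100 * pm_lo, hi = 100 * pm_hi)
  })
  do.call(rbind, rows)
}

#' Delay-risk table for several cancers
#'
#' One row per (cancer, delay) with the local-control loss and
#' new-metastasis risk estimates, full precision. Use
#' [format_risk_table()] for the display-rounded variant.
#'
#' @param param_sets A list of [tumor_params()] objects (unique labels) or a
#'   single object.
#' @param delays Delay times in months.
#' @param nodes Quadrature nodes.
#' @return A data frame with columns `cancer`, `delay_months`,
#'   `tcp_loss_mean`, `tcp_loss_lo`, `tcp_loss_hi`, `met_risk_mean`,
#'   `met_risk_lo`, `met_risk_hi`.
#' @examples
#' sets <- lapply(cancer_labels(), published_parameters)
#' delay_risk_table(sets, c(2, 6))
#' @export
delay_risk_table <- function(param_sets, delays, nodes = 128L) {
  if (inherits(param_sets, "tumor_params")) param_sets <- list(param_sets)
  if (!length(param_sets) || !length(delays)) {
    stop("param_sets and delays must be nonempty")
  }
  labels <- vapply(param_sets, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate cancer labels in param_sets")
  rows <- lapply(param_sets, function(p) {
    loss <- tcp_loss(p, delays, nodes = nodes)
    met <- metastasis_risk(p, delays, nodes = nodes)
    data.frame(cancer = p$label, delay_months = delays,
               tcp_loss_mean = loss$mean, tcp_loss_lo = loss$lo,
               tcp_loss_hi = loss$hi,
               met_risk_mean = met$mean, met_risk_lo = met$lo,
               met_risk_hi = met$hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Display-round a delay-risk table
#'
#' Rounds to 2 decimal places and floors negative TCP-loss lower bounds at
#' 0.00 (a 97.5th-percentile TCP above baseline means the favorable outcome
#' is no loss at all).
#'
#' @param tab Output of [delay_risk_table()].
#' @return The table with rounded, floored numeric columns.
#' @export
format_risk_table <- function(tab) {
  num <- setdiff(names(tab), c("cancer", "delay_months"))
  tab[num] <- lapply(tab[num], function(x) pmax(round(x, 2), 0))
  tab
}

#' Mean and percentile risk curves over a delay grid
#'
#' Samples [tcp_loss()] and [metastasis_risk()] on a time grid, giving the
#' data behind delay-response curves (mean line plus 2.5th/97.5th percentile
#' band) for one cancer.
#'
#' @param params A [tumor_params()].
#' @param t_grid Nondecreasing, nonnegative delay grid (months); default
#'   0 to 12 by 0.25.
#' @param nodes Quadrature nodes.
#' @return A long data frame with columns `cancer`, `quantity`, `t`, `mean`,
#'   `lo`, `hi`.
#' @export
delay_curves <- function(params, t_grid = seq(0, 12, by = 0.25),
                         nodes = 128L) {
  check_delay(t_grid)
  if (is.unsorted(t_grid)) stop("t_grid must be sorted nondecreasing")
  loss <- tcp_loss(params, t_grid, nodes = nodes)
  met <- metastasis_risk(params, t_grid, nodes = nodes)
  out <- rbind(loss, met)
  out <- cbind(cancer = params$label, out, stringsAsFactors = FALSE)
  out
}
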