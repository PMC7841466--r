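# Report-layer functions behind the command-line interface. Each is a pure
# function of (configuration, bundled data, seed); the CLI script in
# inst/cli/ is a thin argument-parsing wrapper around these.

resolve_param_sets <- function(cancer = NULL, params_file = NULL,
                               precision = "printed", k_mode = "point") {
  if (!is.null(params_file)) {
    return(list(read_parameter_config(params_file, k_mode = k_mode)))
  }
  labels <- if (is.null(cancer)) cancer_labels() else cancer
  lapply(labels, published_parameters, precision = precision, k_mode = k_mode)
}

#' Calibration report
#'
#' Runs the calibration chain for the requested cancers and reports the
#' derived parameters step by step, noting the days-to-months convention.
#'
#' @param cancer Bundled label(s); `NULL` means all three.
#' @param params_file Optional config file overriding the bundled inputs.
#' @param k_mode `"point"` or `"distributional"` calibration of `k`.
#' @return A data frame with one row per cancer: the literature inputs and
#'   the derived `p0`, `s`, `g_mean`, `g_sd`, `k`, with attribute
#'   `"days_per_month"`.
#' @export
run_calibrate <- function(cancer = NULL, params_file = NULL,
                          k_mode = c("point", "distributional")) {
  k_mode <- match.arg(k_mode)
  sets <- resolve_param_sets(cancer, params_file, precision = "derived",
                             k_mode = k_mode)
  rows <- lapply(sets, function(p) {
    data.frame(cancer = p$label, p0 = p$p0, s = p$s, g_mean = p$g_mean,
               g_sd = p$g_sd, k = p$k, m0 = p$m0,
               k_mode = attr(p, "k_mode") %||% k_mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "days_per_month") <- DAYS_PER_MONTH
  out
}

#' Delay-risk table report
#'
#' Reproduces the delay-risk table: local-control loss and new-metastasis
#' risk (mean and 95% percentile bounds, percentage points) for each cancer
#' and delay.
#'
#' @inheritParams run_calibrate
#' @param delays Delay times in months (default 2 and 6).
#' @param precision `"printed"` (default; published rounded `k`) or
#'   `"derived"`.
#' @param display Round to 2 decimals and floor negative loss bounds at 0.
#' @return A data frame (see [delay_risk_table()]).
#' @export
run_table <- function(cancer = NULL, params_file = NULL, delays = c(2, 6),
                      precision = c("printed", "derived"),
                      k_mode = c("point", "distributional"),
                      display = TRUE) {
  precision <- match.arg(precision)
  k_mode <- match.arg(k_mode)
  sets <- resolve_param_sets(cancer, params_file, precision, k_mode)
  tab <- delay_risk_table(sets, delays)
  if (display) format_risk_table(tab) else tab
}

#' Delay-response curve report
#'
#' Mean and 2.5th/97.5th percentile curves of local-control loss and
#' new-metastasis risk on a dense delay grid, per cancer.
#'
#' @inheritParams run_table
#' @param grid_max Grid end (months, default 12).
#' @param grid_step Grid step (months, default 0.25).
#' @return A long data frame from [delay_curves()], all cancers stacked.
#' @export
run_curves <- function(cancer = NULL, params_file = NULL, grid_max = 12,
                       grid_step = 0.25,
                       precision = c("printed", "derived"),
                       k_mode = c("point", "distributional")) {
  precision <- match.arg(precision)
  k_mode <- match.arg(k_mode)
  if (grid_max < 0 || grid_step <= 0) stop("invalid curve grid")
  sets <- resolve_param_sets(cancer, params_file, precision, k_mode)
  grid <- seq(0, grid_max, by = grid_step)
  do.call(rbind, lapply(sets, delay_curves, t_grid = grid))
}

#' Analytic-versus-simulation comparison report
#'
#' Runs the Monte Carlo cohort next to the quadrature expectations and
#' reports z-scores `(simulated - analytic) / SE` for the control and
#' metastasis fractions at each (cancer, delay).
#'
#' @inheritParams run_table
#' @param n Cohort size per (cancer, delay).
#' @param seed Root RNG seed; per-cell seeds are derived deterministically.
#' @return A data frame with analytic and simulated values, standard errors,
#'   z-scores, and an `agree` flag (|z| < 3); attribute `"all_agree"`.
#' @export
run_simulate <- function(cancer = NULL, params_file = NULL, delays = c(2, 6),
                         n = 1e5, seed = 1,
                         precision = c("printed", "derived"),
                         k_mode = c("point", "distributional")) {
  precision <- match.arg(precision)
  k_mode <- match.arg(k_mode)
  sets <- resolve_param_sets(cancer, params_file, precision, k_mode)
  rows <- list()
  cell <- 0L
  for (p in sets) {
    for (tt in delays) {
      cell <- cell + 1L
      res <- simulate_cohort(p, tt, n, seed = seed + 1000L * cell)
      e_tcp <- expect_over_growth(p, tt, function(g, u) {
        tumor_control_probability(p, g, u)
      })
      e_pm <- expect_over_growth(p, tt, function(g, u) {
        metastasis_probability(p, g, u)
      })
      z_tcp <- (res$control_fraction - e_tcp) / max(res$control_se, 1e-12)
      z_pm <- (res$metastasis_fraction - e_pm) / max(res$metastasis_se, 1e-12)
      rows[[cell]] <- data.frame(
        cancer = p$label, delay_months = tt, n = res$n,
        tcp_analytic = e_tcp, control_fraction = res$control_fraction,
        control_se = res$control_se, z_control = z_tcp,
        pm_analytic = e_pm, metastasis_fraction = res$metastasis_fraction,
        metastasis_se = res$metastasis_se, z_metastasis = z_pm,
        agree = abs(z_tcp) < 3 && abs(z_pm) < 3,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "all_agree") <- all(out$agree)
  out
}

#' Write a report data frame as CSV or JSON
#'
#' @param x A data frame from one of the `run_*` report functions.
#' @param path Output path; `format` defaults from the extension.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
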