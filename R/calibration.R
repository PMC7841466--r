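DAYS_PER_MONTH <- 30

#' Doubling-time summary
#'
#' Median and spread of literature-reported tumor volume doubling times.
#' The spread is either the full reported range or an interquartile range;
#' the two are converted to a growth-rate standard deviation with different
#' normal-quantile multipliers (see [growth_sd_from_spread()]).
#'
#' @param median_days Median doubling time (days, > 0).
#' @param lower_days Lower spread bound (days).
#' @param upper_days Upper spread bound (days).
#' @param spread_kind `"full_range"` or `"interquartile"`.
#' @return An object of class `doubling_summary`.
#' @export
doubling_summary <- function(median_days, lower_days, upper_days,
                             spread_kind = c("full_range", "interquartile")) {
  spread_kind <- match.arg(spread_kind)
  stopifnot(is.numeric(median_days), is.numeric(lower_days),
            is.numeric(upper_days))
  if (!(lower_days > 0 && lower_days <= median_days &&
        median_days <= upper_days)) {
    stop("doubling-time bounds must satisfy 0 < lower <= median <= upper")
  }
  structure(list(median_days = median_days, lower_days = lower_days,
                 upper_days = upper_days, spread_kind = spread_kind),
            class = "doubling_summary")
}

#' Tumor cell count from diameter and cell density
#'
#' Spherical-geometry estimate of the initial primary tumor burden:
#' `density * (4/3) * pi * (diameter/2)^3`.
#'
#' @param diameter_cm Initial tumor diameter (cm, > 0).
#' @param cell_density_per_cm3 Tumor cell density (cells per cm^3, > 0);
#'   default `1e8`, the standard assumption for solid tumors.
#' @return Cell count.
#' @examples
#' cells_from_diameter(3.0)  # ~1.41e9: a 3 cm head-and-neck primary
#' @export
cells_from_diameter <- function(diameter_cm, cell_density_per_cm3 = 1e8) {
  if (!is.numeric(diameter_cm) || diameter_cm <= 0) {
    stop("diameter_cm must be positive")
  }
  if (!is.numeric(cell_density_per_cm3) || cell_density_per_cm3 <= 0) {
    stop("cell_density_per_cm3 must be positive")
  }
  cell_density_per_cm3 * (4 / 3) * pi * (diameter_cm / 2)^3
}

#' Surviving fraction from a baseline control probability
#'
#' Inverts the Poisson TCP model at zero delay: given a target control
#' probability `tcp0` for treatment without delay and an initial burden
#' `p0`, the clonogen surviving fraction is `S = -ln(tcp0) / p0`, so that
#' `exp(-S * p0) = tcp0` exactly.
#'
#' @param tcp0 Baseline local control probability, in (0, 1).
#' @param p0 Initial tumor cell count (> 0).
#' @return Surviving fraction.
#' @export
surviving_fraction_from_baseline <- function(tcp0, p0) {
  if (!is.numeric(tcp0) || tcp0 <= 0 || tcp0 >= 1) {
    stop("tcp0 must lie strictly between 0 and 1")
  }
  if (!is.numeric(p0) || p0 <= 0) stop("p0 must be positive")
  -log(tcp0) / p0
}

#' Growth rate from a doubling time
#'
#' `g = ln(2) / (doubling time in months)`, with days converted at 30 days
#' per month.
#'
#' @param days Doubling time (days, > 0).
#' @return Growth rate per month.
#' @examples
#' growth_rate_from_doubling_time(99)  # ~0.210 per month
#' @export
growth_rate_from_doubling_time <- function(days) {
  if (!is.numeric(days) || any(days <= 0)) {
    stop("doubling time must be positive")
  }
  log(2) / (days / DAYS_PER_MONTH)
}

#' Growth-rate standard deviation from a doubling-time spread
#'
#' Treats the spread bounds as symmetric normal quantiles of the growth-rate
#' distribution. A shorter doubling time means a faster growth rate, so the
#' lower doubling-time bound maps to the upper growth-rate bound. Each bound
#' gives a one-sided estimate, `sigma_up = (g(lower_days) - G) / z` and
#' `sigma_low = (G - g(upper_days)) / z`, with `z = 2` when the spread is a
#' full range and `z = 0.674` when it is an interquartile range; the returned
#' value is their geometric mean.
#'
#' @param summary A [doubling_summary()].
#' @return Growth-rate standard deviation per month.
#' @examples
#' growth_sd_from_spread(doubling_summary(99, 61, 112))  # ~0.0282
#' @export
growth_sd_from_spread <- function(summary) {
  stopifnot(inherits(summary, "doubling_summary"))
  g_mid <- growth_rate_from_doubling_time(summary$median_days)
  g_hi <- growth_rate_from_doubling_time(summary$lower_days)
  g_lo <- growth_rate_from_doubling_time(summary$upper_days)
  z <- if (summary$spread_kind == "full_range") 2 else 0.674
  sigma_up <- (g_hi - g_mid) / z
  sigma_low <- (g_mid - g_lo) / z
  if (sigma_up < 0 || sigma_low < 0) {
    stop("spread bounds invert after conversion to growth rates")
  }
  sqrt(sigma_up * sigma_low)
}

#' Calibrate the metastasis formation constant
#'
#' Solves for `k` so that the model's metastasis probability matches an
#' observed upstaging fraction at a stated delay. In `"point"` mode the
#' model is evaluated at the single growth rate `g = g_mean` with `m0 = 0`,
#' giving the closed form
#' `k = -ln(1 - p) * g^2 / (p0 * (exp(g*t) - 1 - g*t))`.
#' In `"distributional"` mode `k` is root-solved so the growth-rate-averaged
#' metastasis probability over `Normal(g_mean, g_sd)` equals the observation;
#' this requires `g_sd`.
#'
#' @param probability Observed fraction with new metastases, in (0, 1).
#' @param at_months Delay at which the fraction was observed (months, > 0).
#' @param p0 Initial tumor cell count.
#' @param g_mean Mean growth rate (per month).
#' @param g_sd Growth-rate standard deviation; needed for
#'   `mode = "distributional"`.
#' @param mode `"point"` (default) or `"distributional"`.
#' @return `k` (per month per cell) with the calibration mode attached as
#'   attribute `"mode"`.
#' @export
calibrate_metastasis_rate <- function(probability, at_months, p0, g_mean,
                                      g_sd = NULL,
                                      mode = c("point", "distributional")) {
  mode <- match.arg(mode)
  if (!is.numeric(probability) || probability < 0 || probability >= 1) {
    stop("observed probability must lie in [0, 1)")
  }
  if (!is.numeric(at_months) || at_months <= 0) {
    stop("at_months must be positive")
  }
  if (p0 <= 0) stop("p0 must be positive")
  target_lambda <- -log1p(-probability)
  t <- at_months
  # denominator of the closed form: p0 * t^2 * (e^x - 1 - x)/x^2 at x = g*t
  denom <- p0 * t^2 * expm1m_over_x2(g_mean * t)
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate calibration denominator; check p0, g_mean, at_months")
  }
  k_point <- target_lambda / denom
  if (mode == "point") {
    return(structure(k_point, mode = "point"))
  }
  if (is.null(g_sd) || g_sd < 0) {
    stop("distributional calibration requires a nonnegative g_sd")
  }
  if (g_sd == 0) {
    return(structure(k_point, mode = "distributional"))
  }
  # PM averaged over g is increasing in k; bracket around the point solution
  pm_bar <- function(k) {
    pars <- tumor_params(p0 = p0, s = 0.5, g_mean = g_mean, g_sd = g_sd,
                         k = k, m0 = 0)
    expect_over_growth(pars, t, function(g, tt) {
      metastasis_probability(pars, g, tt)
    }) - probability
  }
  # tol is absolute in k, which is tiny; scale it to the point solution
  root <- stats::uniroot(pm_bar, lower = k_point / 100, upper = k_point * 100,
                         tol = k_point * 1e-10)
  structure(root$root, mode = "distributional")
}

#' Build a full parameter set from literature inputs
#'
#' Chains the four calibration steps at full precision, in the order the
#' parameters depend on each other: initial burden from sphere geometry,
#' surviving fraction from the baseline control probability, growth-rate
#' mean and spread from the doubling-time summary, and the metastasis
#' constant from the observed upstaging fraction. The initial metastasis
#' hazard is fixed at 0 (no metastases at primary diagnosis).
#'
#' @param diameter_cm Initial tumor diameter (cm).
#' @param baseline_tcp Local control probability without delay, in (0, 1).
#' @param doubling A [doubling_summary()].
#' @param metastasis_prob Observed new-metastasis fraction, in (0, 1).
#' @param metastasis_at_months Delay of that observation (months).
#' @param label Cancer-type identifier.
#' @param cell_density_per_cm3 Tumor cell density (cells per cm^3).
#' @param k_mode Calibration mode for `k`, `"point"` or `"distributional"`.
#' @return A [tumor_params()] object with attribute `"k_mode"`.
#' @export
build_parameter_set <- function(diameter_cm, baseline_tcp, doubling,
                                metastasis_prob, metastasis_at_months,
                                label, cell_density_per_cm3 = 1e8,
                                k_mode = c("point", "distributional")) {
  k_mode <- match.arg(k_mode)
  p0 <- cells_from_diameter(diameter_cm, cell_density_per_cm3)
  s <- surviving_fraction_from_baseline(baseline_tcp, p0)
  g_mean <- growth_rate_from_doubling_time(doubling$median_days)
  g_sd <- growth_sd_from_spread(doubling)
  k <- calibrate_metastasis_rate(metastasis_prob, metastasis_at_months,
                                 p0, g_mean, g_sd, mode = k_mode)
  out <- tumor_params(p0 = p0, s = s, g_mean = g_mean, g_sd = g_sd,
                      k = as.numeric(k), m0 = 0, label = label)
  attr(out, "k_mode") <- attr(k, "mode")
  out
}

# Bundled literature inputs for the three studied cancers.
# Diameters are the assumed initial stage-specific diameters; doubling-time
# summaries and upstaging observations are the published clinical estimates.
literature_inputs <- function() {
  list(
    head_and_neck = list(
      cancer_label = "head_and_neck",
      diameter_cm = 3.0, cell_density_per_cm3 = 1e8, baseline_tcp = 0.9,
      doubling_median_days = 99, doubling_lower_days = 61,
      doubling_upper_days = 112, spread_kind = "full_range",
      metastasis_prob = 0.60, metastasis_at_months = 14.9,
      k_printed = 1.51e-12
    ),
    colorectal = list(
      cancer_label = "colorectal",
      diameter_cm = 5.0, cell_density_per_cm3 = 1e8, baseline_tcp = 0.9,
      doubling_median_days = 211, doubling_lower_days = 112,
      doubling_upper_days = 404, spread_kind = "full_range",
      metastasis_prob = 0.17, metastasis_at_months = 5,
      k_printed = 1.95e-12
    ),
    lung = list(
      cancer_label = "lung",
      diameter_cm = 0.5, cell_density_per_cm3 = 1e8, baseline_tcp = 0.9,
      doubling_median_days = 348, doubling_lower_days = 222,
      doubling_upper_days = 492, spread_kind = "interquartile",
      metastasis_prob = 0.08, metastasis_at_months = 12,
      k_printed = 1.40e-10
    )
  )
}

#' Bundled cancer labels
#'
#' @return Character vector of the bundled cancer-type labels.
#' @export
cancer_labels <- function() names(literature_inputs())

#' Published parameter sets
#'
#' Returns the calibrated parameter set for one of the bundled cancer types.
#' Two precision modes are available. `"printed"` runs the calibration chain
#' at full precision but substitutes the published rounded value of the
#' metastasis constant `k`; this mode reproduces the published delay-risk
#' table. `"derived"` uses the full-precision chain throughout, including
#' `k` recomputed from the upstaging observation.
#'
#' @param label One of [cancer_labels()]: `"head_and_neck"`, `"colorectal"`,
#'   or `"lung"`.
#' @param precision `"printed"` (default) or `"derived"`.
#' @param k_mode Calibration mode for `k` when `precision = "derived"`.
#' @return A [tumor_params()] object.
#' @examples
#' published_parameters("head_and_neck")
#' @export
published_parameters <- function(label = cancer_labels(),
                                 precision = c("printed", "derived"),
                                 k_mode = c("point", "distributional")) {
  label <- match.arg(label)
  precision <- match.arg(precision)
  k_mode <- match.arg(k_mode)
  inp <- literature_inputs()[[label]]
  pars <- build_parameter_set(
    diameter_cm = inp$diameter_cm,
    baseline_tcp = inp$baseline_tcp,
    doubling = doubling_summary(inp$doubling_median_days,
                                inp$doubling_lower_days,
                                inp$doubling_upper_days,
                                inp$spread_kind),
    metastasis_prob = inp$metastasis_prob,
    metastasis_at_months = inp$metastasis_at_months,
    label = inp$cancer_label,
    cell_density_per_cm3 = inp$cell_density_per_cm3,
    k_mode = k_mode
  )
  if (precision == "printed") {
    pars$k <- inp$k_printed
    attr(pars, "k_mode") <- "printed"
  }
  attr(pars, "precision") <- precision
  pars
}

#' Read a parameter-set configuration file
#'
#' Reads a flat key-value YAML or JSON file describing the literature inputs
#' for one cancer, validates it, and runs the calibration chain.
#' Required keys: `cancer_label`, `diameter_cm`, `cell_density_per_cm3`,
#' `baseline_tcp`, `doubling_median_days`, `doubling_lower_days`,
#' `doubling_upper_days`, `spread_kind`, `metastasis_prob`,
#' `metastasis_at_months`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @param k_mode Calibration mode for `k`.
#' @return A [tumor_params()] object.
#' @export
read_parameter_config <- function(path, k_mode = c("point", "distributional")) {
  k_mode <- match.arg(k_mode)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  required <- c("cancer_label", "diameter_cm", "cell_density_per_cm3",
                "baseline_tcp", "doubling_median_days", "doubling_lower_days",
                "doubling_upper_days", "spread_kind", "metastasis_prob",
                "metastasis_at_months")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required keys: ", paste(missing, collapse = ", "))
  }
  build_parameter_set(
    diameter_cm = cfg$diameter_cm,
    baseline_tcp = cfg$baseline_tcp,
    doubling = doubling_summary(cfg$doubling_median_days,
                                cfg$doubling_lower_days,
                                cfg$doubling_upper_days,
                                cfg$spread_kind),
    metastasis_prob = cfg$metastasis_prob,
    metastasis_at_months = cfg$metastasis_at_months,
    label = cfg$cancer_label,
    cell_density_per_cm3 = cfg$cell_density_per_cm3,
    k_mode = k_mode
  )
}

#' Write a calibrated parameter set with its inputs
#'
#' Emits the input schema of [read_parameter_config()] plus the derived
#' parameters (`p0`, `s`, `g_mean`, `g_sd`, `k`) and the calibration mode,
#' as YAML or JSON by extension.
#'
#' @param inputs Named list in the config schema (see
#'   [read_parameter_config()]).
#' @param params The calibrated [tumor_params()] for those inputs.
#' @param path Output path (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(inputs, params, path) {
  out <- c(inputs, list(
    derived = list(p0 = params$p0, s = params$s, g_mean = params$g_mean,
                   g_sd = params$g_sd, k = params$k, m0 = params$m0),
    k_mode = attr(params, "k_mode") %||% "point",
    days_per_month = DAYS_PER_MONTH
  ))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(out, path),
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config extension: ", ext)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
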