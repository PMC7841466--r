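test_that("sphere geometry reproduces the published initial cell counts", {
  expect_equal(signif(cells_from_diameter(0.5), 3), 6.54e6)
  expect_equal(signif(cells_from_diameter(3.0), 3), 1.41e9)
  expect_equal(signif(cells_from_diameter(5.0), 3), 6.54e9)
  expect_error(cells_from_diameter(-1), "positive")
  expect_error(cells_from_diameter(1, 0), "positive")
})

test_that("surviving fraction inverts the baseline TCP exactly", {
  expect_equal(signif(surviving_fraction_from_baseline(0.9, 1.41e9), 3),
               7.45e-11)
  expect_equal(signif(surviving_fraction_from_baseline(0.9, 6.54e6), 3),
               1.61e-8)
  expect_equal(surviving_fraction_from_baseline(exp(-1), 1), 1)
  expect_error(surviving_fraction_from_baseline(1.1, 1e9), "between")
  # round-trip through the TCP model at t = 0
  for (tcp0 in c(0.5, 0.9, 0.99)) {
    p0 <- 2.3e8
    s <- surviving_fraction_from_baseline(tcp0, p0)
    p <- tumor_params(p0, s, 0.1, 0.02, 1e-12)
    expect_equal(tumor_control_probability(p, g = 0.1, t = 0), tcp0,
                 tolerance = 1e-14)
  }
})

test_that("doubling times convert to growth rates at 30 days per month", {
  expect_equal(signif(growth_rate_from_doubling_time(99), 3), 0.210)
  expect_equal(signif(growth_rate_from_doubling_time(211), 2), 0.099)
  expect_equal(growth_rate_from_doubling_time(30), log(2))
  expect_error(growth_rate_from_doubling_time(0), "positive")
})

test_that("growth-rate SD from spread matches the published sigmas", {
  expect_equal(signif(growth_sd_from_spread(doubling_summary(99, 61, 112)), 3),
               0.0282)
  expect_equal(signif(growth_sd_from_spread(doubling_summary(211, 112, 404)),
                      2), 0.032)
  expect_equal(
    signif(growth_sd_from_spread(
      doubling_summary(348, 222, 492, "interquartile")), 3),
    0.0361)
  expect_error(doubling_summary(99, 120, 112), "bounds")
})

test_that("symmetric spreads give the one-sided SD back", {
  # choose bounds so both one-sided growth-rate deviations are equal
  g_mid <- growth_rate_from_doubling_time(100)
  dev <- 0.02
  lower <- 30 * log(2) / (g_mid + 2 * dev)
  upper <- 30 * log(2) / (g_mid - 2 * dev)
  ds <- doubling_summary(100, lower, upper)
  expect_equal(growth_sd_from_spread(ds), dev, tolerance = 1e-12)
})

test_that("point-mode k matches the published values within 3 percent", {
  printed <- c(head_and_neck = 1.51e-12, colorectal = 1.95e-12,
               lung = 1.40e-10)
  for (lbl in cancer_labels()) {
    p <- published_parameters(lbl, precision = "derived", k_mode = "point")
    expect_lt(abs(p$k / printed[[lbl]] - 1), 0.03)
  }
})

test_that("distributional-mode k is below point-mode k (PM convex in g)", {
  # averaging the convex PM(g) raises the mixture metastasis probability,
  # so matching the same observation needs a smaller rate constant
  for (lbl in cancer_labels()) {
    kp <- published_parameters(lbl, precision = "derived", k_mode = "point")$k
    kd <- published_parameters(lbl, precision = "derived",
                               k_mode = "distributional")$k
    expect_lt(kd, kp)
    expect_gt(kd, 0.9 * kp)
  }
})

test_that("k calibration round-trips through the metastasis probability", {
  for (prob in c(0.05, 0.17, 0.60)) {
    k <- calibrate_metastasis_rate(prob, 9, p0 = 2e9, g_mean = 0.15)
    p <- tumor_params(2e9, 0.5, 0.15, 0.02, as.numeric(k))
    expect_equal(metastasis_probability(p, g = 0.15, t = 9), prob,
                 tolerance = 1e-12)
  }
  # distributional mode round-trips through the growth-rate-averaged PM
  k <- calibrate_metastasis_rate(0.3, 9, p0 = 2e9, g_mean = 0.15,
                                 g_sd = 0.04, mode = "distributional")
  p <- tumor_params(2e9, 0.5, 0.15, 0.04, as.numeric(k))
  pm_bar <- expect_over_growth(p, 9, function(g, t) {
    metastasis_probability(p, g, t)
  })
  expect_equal(pm_bar, 0.3, tolerance = 1e-9)
  expect_equal(as.numeric(calibrate_metastasis_rate(0, 5, 1e9, 0.2)), 0)
  expect_error(calibrate_metastasis_rate(1, 5, 1e9, 0.2), "probability")
})

test_that("the full chain reproduces the published parameter sets", {
  hn <- published_parameters("head_and_neck", precision = "derived")
  expect_equal(signif(hn$p0, 3), 1.41e9)
  expect_equal(signif(hn$s, 3), 7.45e-11)
  expect_equal(signif(hn$g_mean, 3), 0.210)
  expect_equal(signif(hn$g_sd, 3), 0.0282)
  expect_equal(hn$m0, 0)
  lung <- published_parameters("lung", precision = "derived")
  expect_equal(signif(lung$p0, 3), 6.54e6)
  expect_equal(signif(lung$s, 3), 1.61e-8)
  expect_equal(signif(lung$g_mean, 3), 0.0598)
  expect_equal(signif(lung$g_sd, 3), 0.0361)
  # printed mode swaps in the published rounded k only
  hn_pr <- published_parameters("head_and_neck", precision = "printed")
  expect_identical(hn_pr$k, 1.51e-12)
  expect_identical(hn_pr$p0, hn$p0)
  # determinism
  expect_identical(unclass(published_parameters("colorectal")),
                   unclass(published_parameters("colorectal")))
})

test_that("parameter configs round-trip through YAML and JSON", {
  inp <- list(cancer_label = "toy", diameter_cm = 2, cell_density_per_cm3 = 1e8,
              baseline_tcp = 0.9, doubling_median_days = 120,
              doubling_lower_days = 80, doubling_upper_days = 200,
              spread_kind = "full_range", metastasis_prob = 0.25,
              metastasis_at_months = 8)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("toy.", ext))
    yaml_like <- inp
    if (ext == "yaml") yaml::write_yaml(yaml_like, path)
    if (ext == "json") {
      jsonlite::write_json(yaml_like, path, auto_unbox = TRUE, digits = NA)
    }
    p <- read_parameter_config(path)
    expect_s3_class(p, "tumor_params")
    expect_equal(p$p0, cells_from_diameter(2))
    expect_equal(p$g_mean, growth_rate_from_doubling_time(120))
    # writer emits inputs plus derived block; reader accepts it again
    out_path <- file.path(tempdir(), paste0("toy-out.", ext))
    write_parameter_config(inp, p, out_path)
    p2 <- read_parameter_config(out_path)
    expect_equal(p2$k, p$k)
    unlink(c(path, out_path))
  }
  bad <- file.path(tempdir(), "bad.yaml")
  yaml::write_yaml(list(cancer_label = "x"), bad)
  expect_error(read_parameter_config(bad), "missing required keys")
  unlink(bad)
})
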