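lib <- default_component_library()

make_series <- function(...) {
  sims <- list(...)
  timepoint_series(
    week = seq_along(sims) - 1L,
    spectra = purrr::map(sims, "spectra"),
    assays = purrr::map(sims, "assays")
  )
}

test_that("timepoint_series validates its structure", {
  s1 <- simulate_calibration_set(mixture_design(n = 5, seed = 61))
  s2 <- simulate_calibration_set(mixture_design(n = 5, seed = 62))
  ser <- make_series(s1, s2)
  expect_s3_class(ser, "timepoint_series")
  expect_equal(ser$label, c("Initial", "Week 1"))
  expect_error(
    timepoint_series(c(1, 1), spectra = list(s1$spectra, s2$spectra),
                     assays = list(s1$assays, s2$assays)),
    class = "wp_usage_error"
  )
  bad_assays <- s2$assays
  bad_assays$sample_id <- paste0("x", bad_assays$sample_id)
  expect_error(
    timepoint_series(0:1, spectra = list(s1$spectra, s2$spectra),
                     assays = list(s1$assays, bad_assays)),
    class = "wp_data_error"
  )
})

test_that("a noise-free timepoint correlates its own assay perfectly at 520 nm", {
  # anthocyanin-only mixtures: A520 is exactly proportional to the assay
  sim <- simulate_calibration_set(noise_free_design(
    12, seed = 63,
    ranges = list(anthocyanin = c(50, 900), tannin = c(0, 0), tip = c(0, 0))
  ))
  ser <- make_series(sim)
  tab <- assay_wavelength_table(ser)
  expect_equal(tab$Initial[tab$phenolic_id == "Anthos @520"], 1,
               tolerance = 1e-10)
  expect_identical(tab$phenolic_id,
                   c("Anthos @520", "TIPs@520", "Tannin@520",
                     "Anthos@280", "TIPs@280", "Tannin@280"))
})

test_that("tables are invariant to sample order within a timepoint", {
  sim <- simulate_calibration_set(mixture_design(n = 10, seed = 64))
  shuffled <- sim
  perm <- c(4, 9, 1, 7, 3, 10, 2, 6, 8, 5)
  shuffled$spectra <- sim$spectra[perm, ]
  t1 <- assay_wavelength_table(make_series(sim))
  t2 <- assay_wavelength_table(make_series(shuffled))
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("assay cross table tracks exact linear relationships", {
  sim <- simulate_calibration_set(mixture_design(n = 8, seed = 65))
  a <- sim$assays
  a$tannins <- 2 * a$anthocyanins
  a$tips <- 1000 - a$anthocyanins
  sim$assays <- a
  tab <- assay_cross_table(make_series(sim))
  expect_equal(tab$Initial[tab$phenolic_id == "Tannins"], 1, tolerance = 1e-12)
  expect_equal(tab$Initial[tab$phenolic_id == "TIPs"], -1, tolerance = 1e-12)
  expect_identical(tab$phenolic_id, c("TIPs", "Tannins"))
})

test_that("a timepoint with fewer than 2 usable samples warns and yields NA", {
  sim <- simulate_calibration_set(mixture_design(n = 6, seed = 66))
  tiny <- simulate_calibration_set(mixture_design(n = 1, seed = 67))
  ser <- timepoint_series(0:1,
                          spectra = list(sim$spectra, tiny$spectra),
                          assays = list(sim$assays, tiny$assays))
  # one warning per skipped cell (two rows at the tiny timepoint)
  expect_warning(
    expect_warning(tab <- assay_cross_table(ser), "fewer than 2"),
    "fewer than 2"
  )
  expect_true(all(is.na(tab[["Week 1"]])))
  expect_true(all(is.finite(tab[["Initial"]])))
})

test_that("peak_correlation_wavelength finds a planted signal", {
  set.seed(68)
  n <- 50
  assay <- runif(n, 100, 900)
  m <- matrix(rnorm(n * 471, sd = 1), n, 471)
  colnames(m) <- as.character(230:700)
  m[, "333"] <- 2 * assay + rnorm(n, sd = 1)
  peak <- peak_correlation_wavelength(spectra_set(m), assay)
  expect_equal(peak$wavelength, 333L)
  expect_gt(peak$correlation, 0.99)
  expect_equal(peak$n, n)

  # anti-correlated signals are found by absolute value, sign preserved
  m[, "333"] <- -2 * assay + rnorm(n, sd = 1)
  peak2 <- peak_correlation_wavelength(spectra_set(m), assay)
  expect_equal(peak2$wavelength, 333L)
  expect_lt(peak2$correlation, -0.99)

  expect_error(peak_correlation_wavelength(spectra_set(m), rep(1, n)),
               class = "wp_data_error")
})

test_that("default aging series reproduces the documented correlation drift", {
  base <- simulate_calibration_set(default_aging_design())
  series <- simulate_aging_series(base)
  expect_equal(series$week, 0:4)
  wltab <- assay_wavelength_table(series)
  anth520 <- unlist(wltab[wltab$phenolic_id == "Anthos @520", -1])
  expect_gt(anth520[["Initial"]], 0.5)
  expect_lt(anth520[["Week 4"]], anth520[["Initial"]])
  cross <- assay_cross_table(series)
  expect_lt(cross[["Week 4"]][cross$phenolic_id == "Tannins"], 0)
  expect_lt(cross[["Week 4"]][cross$phenolic_id == "TIPs"], 0)
})

test_that("week-4 anthocyanin-tannin correlation falls as conversion rises", {
  base <- simulate_calibration_set(default_aging_design())
  r_at <- vapply(c(0.05, 0.2, 0.4), function(cv) {
    series <- simulate_aging_series(base, aging_model(conversion = cv))
    cross <- assay_cross_table(series)
    cross[["Week 4"]][cross$phenolic_id == "Tannins"]
  }, numeric(1))
  expect_true(all(diff(r_at) < 0))
})

test_that("aging truth ledger conserves anthocyanin equivalents", {
  base <- simulate_calibration_set(default_aging_design(n = 20, seed = 8))
  series <- simulate_aging_series(base, aging_model(weeks = 3))
  truth <- attr(series, "wp_truth")
  t0 <- truth[truth$week == 0, ]
  for (w in 1:3) {
    tw <- truth[truth$week == w, ]
    expect_equal(t0$anthocyanin - tw$anthocyanin,
                 tw$pigment_anthocyanin_equiv, tolerance = 1e-9)
    expect_true(all(tw$anthocyanin >= 0))
    expect_true(all(tw$polymeric_pigment >= 0))
  }
})

test_that("zero conversion reproduces the base observations every week", {
  base <- simulate_calibration_set(default_aging_design(n = 15, seed = 9))
  series <- simulate_aging_series(
    base, aging_model(conversion = 0, tannin_incorporation = 0, weeks = 2)
  )
  for (k in 1:3) {
    expect_equal(spectra_matrix(series$spectra[[k]]),
                 spectra_matrix(base$spectra), tolerance = 1e-12)
    expect_equal(series$assays[[k]], base$assays, tolerance = 1e-12)
  }
})

test_that("full uniform conversion empties the anthocyanin pool in one week", {
  base <- simulate_calibration_set(default_aging_design(n = 10, seed = 10))
  series <- simulate_aging_series(
    base, aging_model(conversion = 1, weeks = 1, tannin_rate_scaling = FALSE)
  )
  truth <- attr(series, "wp_truth")
  expect_equal(truth$anthocyanin[truth$week == 1], rep(0, 10))
  expect_equal(series$assays[[2]]$anthocyanins, rep(0, 10))
})
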