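mg_grid <- seq(0.2, 1.4, by = 0.2)

test_that("bell fit recovers exact Gaussian parameters and symmetric optima", {
  rate <- 100 * exp(-(mg_grid - 0.8)^2 / (2 * 0.3^2))
  fit <- fit_bell(mg = mg_grid, rate = rate)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$optimum, 0.8, tolerance = 1e-6)
  expect_equal(fit$width, 0.3, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  # data symmetric about 0.8 -> optimum exactly 0.8
  sym <- c(1, 4, 9, 10, 9, 4, 1)
  expect_equal(fit_bell(mg = mg_grid, rate = sym)$optimum, 0.8,
               tolerance = 1e-7)
  # amplitude scaling leaves the optimum unchanged
  f1 <- fit_bell(mg = mg_grid, rate = sym * 7)
  expect_equal(f1$optimum, 0.8, tolerance = 1e-7)
  expect_error(fit_bell(mg = c(0.2, 0.4, 0.6), rate = c(1, 2, 1)),
               "4 distinct")
  expect_error(fit_bell(mg = mg_grid, rate = rep(3, 7)), "degenerate")
})

test_that("mg_optimum returns the fitted center and rejects unfitted input", {
  fit <- fit_bell(mg = mg_grid, rate = c(1, 4, 9, 10, 9, 4, 1))
  expect_equal(mg_optimum(fit), fit$optimum)
  expect_error(mg_optimum(list(a = 1)), "fitted curve")
})

test_that("fitted center agrees with the grid argmax within one grid step", {
  cons <- paper_constructs()
  p <- scanning_preset("paper2014")
  for (cn in c("M7-Luc-M7", "beta-Luc-M7", "1AUC2AUC-Luc-M7")) {
    prof <- flux_profile(cons[[cn]], p, mg_grid, 60)
    argmax <- prof$Mg[which.max(prof$flux)]
    fitted <- fit_bell(mg = prof$Mg, rate = prof$flux)$optimum
    expect_lte(abs(fitted - argmax), 0.2 + 1e-6)
  }
})

sim_rates <- function(noise_sd = 0, k = 60, lysates = data.frame(
                        lysate = "lysate1", mg_offset = 0), seed = 21) {
  design <- experiment_design(
    constructs = c("M7-Luc-M7", "beta-Luc-M7"), k_levels = k,
    replicates = if (noise_sd > 0) 3L else 1L, lysates = lysates,
    noise_sd = noise_sd, seed = seed)
  sim <- simulate_experiment(design, scanning_preset("paper2014"))
  rate_table(sim$traces)
}

test_that("extract calibration tracks a basal-Mg offset", {
  rates <- sim_rates(lysates = data.frame(lysate = c("L0", "Lplus"),
                                          mg_offset = c(0, 0.1)))
  curves <- response_curves(rates)
  cal0 <- calibrate_extract(Filter(function(cv) cv$lysate == "L0", curves))
  calp <- calibrate_extract(Filter(function(cv) cv$lysate == "Lplus", curves))
  # +0.1 mM basal Mg means the optimum needs ~0.1 mM less added Mg (the
  # curve is resampled on a shifted grid, so recovery is approximate)
  expect_lt(abs((calp$optimum - cal0$optimum) + 0.1), 0.03)
  expect_gt(cal0$peak_rate, 0)
  # peak rate is the fitted bell amplitude of the reference curve
  ref <- Filter(function(cv) cv$construct == "M7-Luc-M7" && cv$lysate == "L0",
                curves)[[1]]
  expect_equal(cal0$peak_rate, ref$bell$amplitude)
  # relative optima are preserved across lysates after calibration
  d0 <- compare_optima(
    Filter(function(cv) cv$construct == "beta-Luc-M7" && cv$lysate == "L0", curves)[[1]],
    Filter(function(cv) cv$construct == "M7-Luc-M7" && cv$lysate == "L0", curves)[[1]])
  dp <- compare_optima(
    Filter(function(cv) cv$construct == "beta-Luc-M7" && cv$lysate == "Lplus", curves)[[1]],
    Filter(function(cv) cv$construct == "M7-Luc-M7" && cv$lysate == "Lplus", curves)[[1]])
  expect_lt(abs(d0 - dp), 0.05)
})

test_that("reference normalisation is idempotent and scale invariant", {
  rates <- sim_rates()
  curves <- response_curves(rates)
  cal <- calibrate_extract(curves)
  norm1 <- normalize_to_reference(curves, cal)
  ref <- Filter(function(cv) cv$construct == "M7-Luc-M7", norm1)[[1]]
  expect_equal(ref$bell$amplitude, 1, tolerance = 1e-9)
  # idempotence
  norm2 <- normalize_to_reference(norm1, cal)
  expect_equal(vapply(norm2, function(cv) cv$bell$amplitude, numeric(1)),
               vapply(norm1, function(cv) cv$bell$amplitude, numeric(1)))
  # doubling every rate changes nothing after normalisation
  rates2 <- rates
  rates2$max_rate <- rates2$max_rate * 2
  curves2 <- response_curves(rates2)
  norm1b <- normalize_to_reference(curves2, calibrate_extract(curves2))
  expect_equal(vapply(norm1b, function(cv) cv$points$rate[4], numeric(1)),
               vapply(norm1, function(cv) cv$points$rate[4], numeric(1)),
               tolerance = 1e-9)
  # lysate mismatch is an error
  calx <- cal
  calx$lysate <- "other"
  expect_error(normalize_to_reference(curves, calx), "lysate mismatch")
})

test_that("optima comparison is per-K only", {
  rates <- rbind(sim_rates(k = 60), sim_rates(k = 120))
  curves <- response_curves(rates)
  pick <- function(cn, k) Filter(function(cv) cv$construct == cn &&
                                   cv$k_mM == k, curves)[[1]]
  expect_equal(compare_optima(pick("M7-Luc-M7", 60), pick("M7-Luc-M7", 60)), 0)
  expect_error(compare_optima(pick("M7-Luc-M7", 60), pick("M7-Luc-M7", 120)),
               "different K")
})

test_that("dual-luciferase normalisation is a guarded ratio", {
  expect_equal(normalize_dual_reporter(10, 2), 5)
  expect_equal(normalize_dual_reporter(0, 5), 0)
  expect_equal(normalize_dual_reporter(3 * 10, 3 * 2),
               normalize_dual_reporter(10, 2))
  expect_error(normalize_dual_reporter(1, 0), "positive")
})
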