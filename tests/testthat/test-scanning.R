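test_that("loading rate is a bell with a potassium-shifted center", {
  p <- algebra_params()
  center60 <- unname(p$loading_center["intercept"] + 60 * p$loading_center["slope"])
  expect_equal(loading_rate(p, center60, 60), p$loading_amp)
  # argmax over Mg increases with K when the center slope is positive
  mg <- seq(0.05, 2.5, by = 0.001)
  a60 <- mg[which.max(loading_rate(p, mg, 60))]
  a150 <- mg[which.max(loading_rate(p, mg, 150))]
  expect_gt(a150, a60)
  # uncapped scaling
  expect_equal(loading_rate(p, 0.8, 60, capped = FALSE),
               0.05 * loading_rate(p, 0.8, 60))
  p0 <- algebra_params()
  p0$uncapped_scale <- 0
  expect_equal(loading_rate(p0, c(0.2, 0.8, 1.4), 60, capped = FALSE),
               c(0, 0, 0))
  expect_error(scanning_params(loading_width = c(lo = -0.1, hi = 0.3)),
               "positive")
})

test_that("site initiation probability follows the class logistic", {
  p <- algebra_params(u0 = 0.1, u1 = 0.9, mid = 0.8, steep = 0.2)
  # low-Mg tail reaches the floor (probe a steep variant so the 10-steepness
  # point stays at positive Mg) and the midpoint halves the span
  p_steep <- algebra_params(u0 = 0.1, u1 = 0.9, mid = 0.8, steep = 0.05)
  expect_lt(abs(site_init_prob(p_steep, "adequate", 0.8 - 10 * 0.05) - 0.1),
            1e-4)
  expect_equal(site_init_prob(p, "adequate", 0.8), 0.5)
  # monotone nondecreasing in Mg
  mg <- seq(0.2, 1.4, by = 0.05)
  expect_true(all(diff(site_init_prob(p, "adequate", mg)) >= 0))
  expect_gt(site_init_prob(p, "adequate", 1.4),
            site_init_prob(p, "adequate", 0.6))
  expect_error(site_init_prob(p, "superb", 0.8), "unknown context class")
})

test_that("strong contexts must be flat across the working Mg range", {
  expect_error(
    scanning_params(ctx = list(
      strong = c(floor = 0.1, ceil = 0.9, mid = 0.8, steep = 0.2),
      adequate = c(floor = 0.02, ceil = 0.97, mid = 0.72, steep = 0.045),
      weak = c(floor = 0.005, ceil = 0.4, mid = 0.9, steep = 0.2))),
    "strong-class")
})

test_that("closed-form flux matches the algebraic branch-tree solution", {
  cons <- paper_constructs()
  p <- algebra_params(p_strong = 0.55, u0 = 0.15, u1 = 0.85, q = 0.25)
  for (mg in c(0.4, 0.8, 1.2)) {
    L <- loading_rate(p, mg, 60)
    p1 <- site_init_prob(p, "strong", mg)   # uAUG1 and main AUG share class
    p2 <- site_init_prob(p, "adequate", mg)
    q <- p$reinit_prob
    wt <- closed_form_flux(cons[["M7-Luc-M7"]], p, mg, 60)
    expect_equal(wt$reporter_flux,
                 L * (1 - p1) * (1 - p2 * (1 - q)) * p1, tolerance = 1e-12)
    expect_equal(closed_form_flux(cons[["1AUC-Luc-M7"]], p, mg, 60)$reporter_flux,
                 L * (1 - p2 * (1 - q)) * p1, tolerance = 1e-12)
    expect_equal(closed_form_flux(cons[["2AUC-Luc-M7"]], p, mg, 60)$reporter_flux,
                 L * (1 - p1) * p1, tolerance = 1e-12)
    expect_equal(closed_form_flux(cons[["1AUC2AUC-Luc-M7"]], p, mg, 60)$reporter_flux,
                 L * p1, tolerance = 1e-12)
    expect_equal(closed_form_flux(cons[["2stopCGA-Luc-M7"]], p, mg, 60)$reporter_flux,
                 L * (1 - p1) * (1 - p2) * p1, tolerance = 1e-12)
    expect_equal(closed_form_flux(cons[["2ndLuc-M7"]], p, mg, 60)$reporter_flux,
                 L * (1 - p1) * p2, tolerance = 1e-12)
  }
})

test_that("branch probabilities are conserved across constructs and conditions", {
  cons <- paper_constructs()
  p <- scanning_preset("paper2014")
  for (cn in names(cons)) {
    for (mg in c(0.2, 0.7, 1.4)) {
      for (k in c(60, 150)) {
        fr <- closed_form_flux(cons[[cn]], p, mg, k)
        expect_lt(abs(sum(fr$branch_probabilities) - 1), 1e-12)
        expect_true(all(fr$branch_probabilities >= 0))
      }
    }
  }
})

test_that("degenerate scanning paths give the expected limits", {
  cons <- paper_constructs()
  # both uAUGs knocked out: flux = loading * p_reporter
  p <- algebra_params()
  no_uorf <- closed_form_flux(cons[["1AUC2AUC-Luc-M7"]], p, 0.8, 60)
  expect_equal(no_uorf$reporter_flux,
               no_uorf$loading * site_init_prob(p, "strong", 0.8))
  # p1 = 1 at an overlapping uORF sequesters everything
  p1 <- algebra_params(p_strong = 1)
  seq_all <- closed_form_flux(cons[["M7-Luc-M7"]], p1, 0.8, 60)
  expect_equal(seq_all$reporter_flux, 0)
  expect_equal(unname(seq_all$branch_probabilities["init_uORF_101"]), 1)
})

test_that("reporter flux is nonincreasing in the uAUG1 initiation probability", {
  cons <- paper_constructs()
  fluxes <- vapply(seq(0.05, 0.95, by = 0.1), function(ps) {
    closed_form_flux(cons[["2ndLuc-M7"]], algebra_params(p_strong = ps),
                     0.8, 60)$reporter_flux
  }, numeric(1))
  expect_true(all(diff(fluxes) <= 1e-12))
})

test_that("mutation operators compose and validate their targets", {
  cons <- paper_constructs()
  wt <- cons[["M7-Luc-M7"]]
  u <- wt$annotation$uorfs
  dbl <- apply_mutation(apply_mutation(wt, aug_knockout(u$start[1])),
                        aug_knockout(u$start[2]))
  expect_setequal(dbl$knocked_out_augs, u$start)
  p <- algebra_params()
  expect_equal(closed_form_flux(dbl, p, 0.8, 60)$reporter_flux,
               closed_form_flux(cons[["1AUC2AUC-Luc-M7"]], p, 0.8, 60)$reporter_flux)
  stopko <- apply_mutation(wt, stop_knockout(u$stop_start[2]))
  path <- magscan:::scan_path(stopko)
  expect_true(all(path$sites$sequesters))
  fused <- apply_mutation(wt, fuse_reporter(u$start[2]))
  expect_equal(fused$reporter_at, u$start[2])
  expect_error(apply_mutation(wt, aug_knockout(999)), "no uAUG")
  expect_error(apply_mutation(wt, stop_knockout(1)), "no uORF stop")
  expect_error(apply_mutation(wt, fuse_reporter(5)), "no AUG")
  # original construct untouched
  expect_length(wt$knocked_out_augs, 0)
})

test_that("Monte-Carlo scanning agrees with the closed form", {
  cons <- paper_constructs()
  p <- scanning_preset("paper2014")
  # deterministic probabilities: exact agreement for any n
  pdet <- algebra_params(p_strong = 1, u0 = 0, u1 = 0, q = 0)
  mc <- simulate_scanning(cons[["1AUC-Luc-M7"]], pdet, 0.8, 60,
                          n_ribosomes = 17, seed = 3)
  cf <- closed_form_flux(cons[["1AUC-Luc-M7"]], pdet, 0.8, 60)
  expect_equal(mc$reporter_flux, cf$reporter_flux)
  # single ribosome: flux is 0 or loading
  one <- simulate_scanning(cons[["M7-Luc-M7"]], p, 0.8, 60,
                           n_ribosomes = 1, seed = 5)
  expect_true(one$reporter_flux %in% c(0, one$loading))
  expect_equal(sum(one$branch_probabilities), 1)
  # reproducibility under a fixed seed
  a <- simulate_scanning(cons[["M7-Luc-M7"]], p, 0.8, 60, 500, seed = 11)
  b <- simulate_scanning(cons[["M7-Luc-M7"]], p, 0.8, 60, 500, seed = 11)
  expect_identical(a$branch_probabilities, b$branch_probabilities)
  # statistical agreement at moderate n (3 binomial SEs per branch)
  n <- 50000L
  mc <- simulate_scanning(cons[["M7-Luc-M7"]], p, 0.8, 60, n, seed = 7)
  cf <- closed_form_flux(cons[["M7-Luc-M7"]], p, 0.8, 60)
  for (nm in names(cf$branch_probabilities)) {
    pb <- cf$branch_probabilities[[nm]]
    se <- sqrt(pb * (1 - pb) / n)
    expect_lt(abs(mc$branch_probabilities[[nm]] - pb), 3 * se + 1e-9)
  }
})
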