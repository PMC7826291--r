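# Corrections, equivalence-point extraction, enhancement ratios and the
# inverse model fit.

make_two_segment <- function(break_x = 3, slope = 100,
                             ratios = seq(0, 6, by = 0.5)) {
  y <- ifelse(ratios < break_x, 50 + slope * ratios, 50 + slope * break_x)
  titration_series(ratios, y)
}

test_that("correct_series handles background, dilution and validation", {
  pts <- data.frame(ratio = 0:5, volume = rep(100, 6),
                    counts = c(10, 20, 30, 40, 40, 40))
  # no background, no added volume: identity
  s <- correct_series(pts)
  expect_identical(s$intensity, pts$counts)
  expect_identical(s$F_0, 10)
  # constant background is subtracted before dilution scaling
  bg <- data.frame(ratio = c(0, 5), counts = c(4, 4))
  s2 <- correct_series(pts, bg)
  expect_identical(s2$intensity, pts$counts - 4)
  # dilution undone by V/V0
  pts3 <- pts
  pts3$volume <- 100 * (1 + 0.02 * (0:5))
  pts3$counts <- pts$counts / (1 + 0.02 * (0:5))
  s3 <- correct_series(pts3)
  expect_equal(s3$intensity, pts$counts, tolerance = 1e-12)
  # normalized values are <= 1 with max exactly 1
  expect_equal(max(s3$normalized), 1)
  expect_error(correct_series(pts, data.frame(ratio = c(1, 2),
                                              counts = c(1, 1))), "cover")
  pts_bad <- pts
  pts_bad$volume <- c(100, 99, 100, 100, 100, 100)
  expect_error(correct_series(pts_bad), "non-decreasing")
})

test_that("normalization is idempotent", {
  s <- make_two_segment()
  s2 <- titration_series(s$ratio, s$normalized)
  expect_equal(s2$normalized, s$normalized)
})

test_that("equivalence point is exact on noise-free two-segment data", {
  s <- make_two_segment(break_x = 3)
  eq <- equivalence_point(s)
  expect_equal(eq$stoichiometry, 3, tolerance = 1e-10)
  expect_true(is.na(eq$uncertainty))
  # replicate aggregation: mean and sd over per-replicate intersections
  s_b <- make_two_segment(break_x = 2.9)
  eq2 <- equivalence_point(list(s, s_b))
  expect_equal(eq2$stoichiometry, mean(c(3, 2.9)), tolerance = 1e-10)
  expect_equal(eq2$uncertainty, stats::sd(c(3, 2.9)), tolerance = 1e-10)
  expect_length(eq2$per_series, 2L)
})

test_that("equivalence point rejects degenerate inputs", {
  flat <- titration_series(seq(0, 6, 0.5), rep(100, 13) + seq(0, 6, 0.5))
  expect_error(equivalence_point(flat), "parallel")
  short <- titration_series(0:8, c(1:5, 5, 5, 5, 5) + 10)
  expect_error(equivalence_point(short), "at least 12")
})

test_that("enhancement ratio behaves and is scale invariant", {
  ratios <- seq(0, 6, by = 0.5)
  flat <- titration_series(ratios, rep(200, length(ratios)))
  expect_equal(enhancement_ratio(flat, 3), 1)
  s <- make_two_segment()
  e1 <- enhancement_ratio(s, 3)
  s_scaled <- titration_series(s$ratio, s$intensity * 37.5)
  expect_equal(enhancement_ratio(s_scaled, 3), e1, tolerance = 1e-12)
  expect_equal(e1, 350 / 50)
  expect_error(enhancement_ratio(s, 5), "over-saturation")
})

test_that("equivalence estimates concentrate on the generator truth", {
  # bias of the first-six/last-six estimator vanishes as noise shrinks
  cfg_lo <- generator_config(params = ligand_params(7, 1e10, 1e8),
                             noise_sd = 0.001, replicates_fluor = 1L)
  ests <- vapply(1:6, function(s) {
    fl <- generate_fluorescence_titration(cfg_lo, constructs = "21T9",
                                          seed = s)
    analyze_titrations(fl$titrations, fl$background)$per_replicate$stoichiometry
  }, numeric(1))
  expect_lt(abs(mean(ests) - 3 * cfg_lo$active_fraction), 0.03)

  # seed sweep at default noise over the full default design (8 constructs,
  # 3 replicates): median recovered stoichiometry within 0.1 of the stated
  # truth (2.9)
  cfg <- generator_config()
  ests2 <- unlist(lapply(1:20, function(s) {
    fl <- generate_fluorescence_titration(cfg, seed = s)
    analyze_titrations(fl$titrations, fl$background)$per_replicate$stoichiometry
  }))
  expect_lt(abs(stats::median(ests2) - 2.9), 0.1)
})

test_that("binding-model fit recovers moderate-affinity generator parameters", {
  truth <- ligand_params(7, 2e5, 20)
  # concentrated stock: negligible dilution, matching the fitter's
  # fixed-concentration model
  cfg <- generator_config(params = truth, noise_sd = 0,
                          active_fraction = 0.95, gp32_stock = 1,
                          replicates_fluor = 1L)
  fl <- generate_fluorescence_titration(cfg, constructs = "21T9", seed = 1)
  s <- correct_series(fl$titrations, fl$background, construct = "21T9")
  keep <- seq(1, length(s$ratio), by = 2)
  s2 <- titration_series(s$ratio[keep], s$intensity[keep])
  fit <- fit_binding_model(s2, parse_construct_name("21T9"), 1e-6,
                           params_init = ligand_params(7, 3e5, 14),
                           active_init = 0.95, R_init = 4.5,
                           fix_active = TRUE, fix_R = TRUE, maxit = 500)
  expect_lt(abs(fit$estimates$K_a - 2e5) / 2e5, 0.05)
  expect_lt(abs(fit$estimates$omega - 20) / 20, 0.05)
  expect_true(fit$identifiable)
  expect_error(fit_binding_model(list(), parse_construct_name("21T9"), 1e-6),
               "empty")
})

test_that("stoichiometric-limit data flag K_a as a lower bound only", {
  cfg <- generator_config(noise_sd = 0, gp32_stock = 1,
                          replicates_fluor = 1L)
  fl <- generate_fluorescence_titration(cfg, constructs = "21T9", seed = 1)
  s <- correct_series(fl$titrations, fl$background, construct = "21T9")
  keep <- seq(1, length(s$ratio), by = 4)
  s2 <- titration_series(s$ratio[keep], s$intensity[keep])
  fit <- suppressWarnings(
    fit_binding_model(s2, parse_construct_name("21T9"), 1e-6,
                      params_init = ligand_params(7, 1e8, 1e6),
                      active_init = cfg$active_fraction, R_init = 4.5,
                      fix_active = TRUE, fix_R = TRUE, maxit = 30)
  )
  expect_false(fit$identifiable)
  expect_match(fit$warnings, "lower bound", all = FALSE)
})
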