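# Generator determinism, noise-free round trips and the qualitative
# footprint patterns the synthetic world must reproduce.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_fluorescence_titration(cfg, constructs = c("21T9", "21T12"),
                                       seed = 11)
  b <- generate_fluorescence_titration(cfg, constructs = c("21T9", "21T12"),
                                       seed = 11)
  expect_identical(a$titrations, b$titrations)
  expect_identical(a$background, b$background)
  c2 <- generate_fluorescence_titration(cfg, constructs = c("21T9", "21T12"),
                                        seed = 12)
  expect_false(identical(a$titrations$counts, c2$titrations$counts))

  q1 <- generate_quench_series(cfg, 1.5, constructs = "21T9", seed = 3)
  q2 <- generate_quench_series(cfg, 1.5, constructs = "21T9", seed = 3)
  expect_identical(q1$series, q2$series)

  d1 <- generate_cd_titration(cfg, constructs = "21T8,9", seed = 5)
  d2 <- generate_cd_titration(cfg, constructs = "21T8,9", seed = 5)
  expect_identical(d1$spectra, d2$spectra)
})

test_that("noise-free titrations round-trip the generator truth", {
  # deep stoichiometric limit: the break approaches capacity * active
  cfg <- generator_config(params = ligand_params(7, 1e10, 1e8),
                          noise_sd = 0, replicates_fluor = 1L)
  fl <- generate_fluorescence_titration(cfg, constructs = c("21T9", "21T12"),
                                        seed = 1)
  tit <- analyze_titrations(fl$titrations, fl$background)
  expect_equal(tit$per_replicate$stoichiometry,
               rep(3 * cfg$active_fraction, 2), tolerance = 0.02)
  # enhancement ratios recover the per-position generator parameters
  enh <- tit$per_replicate$enhancement[order(tit$per_replicate$construct)]
  expect_equal(enh, c(4.0, 4.5), tolerance = 1e-3) # 21T12 then 21T9
})

test_that("strong-binding noise-free curve breaks at capacity when fully active", {
  cfg <- generator_config(params = ligand_params(7, 1e10, 1e8),
                          active_fraction = 1, noise_sd = 0,
                          replicates_fluor = 1L)
  fl <- generate_fluorescence_titration(cfg, constructs = "21T10", seed = 1)
  tit <- analyze_titrations(fl$titrations, fl$background)
  expect_equal(tit$per_replicate$stoichiometry, 3.0, tolerance = 0.02)
})

test_that("background subtraction leaves zero-mean residual for probe-free constructs", {
  cfg <- generator_config(replicates_fluor = 1L)
  fl <- generate_fluorescence_titration(cfg, constructs = "21T", seed = 4)
  raw <- fl$titrations
  bg <- fl$background
  resid <- (raw$counts -
              stats::approx(bg$ratio, bg$counts, xout = raw$ratio)$y) *
    raw$volume / min(raw$volume)
  # residual is noise around zero, far below the probe signal scale
  expect_lt(abs(mean(resid)), 3 * cfg$background_counts * cfg$noise_sd /
              sqrt(nrow(raw)) * 3)
  expect_lt(max(abs(resid)), cfg$f0_counts * 0.01)
})

test_that("noiseless quench series reproduce K_SV and the half-quench law", {
  cfg <- generator_config(noise_sd = 0, replicates_quench = 1L)
  q <- generate_quench_series(cfg, gp32_ratio = 0, constructs = "21T9",
                              seed = 1)
  fits <- analyze_quench(q$series)$fits
  expect_equal(fits$K_SV, 3.5, tolerance = 1e-9)
  expect_equal(fits$intercept, 1, tolerance = 1e-9)
  expect_equal(half_quench_concentration(fits$K_SV), 1 / 3.5)
  # corrected intensities follow F_0/(1 + K_SV [Q]) exactly, so the
  # half-quench law F_0/F = 2 at [Q] = 1/K_SV holds along the whole series
  ser <- q$series
  corr <- ser$counts * ser$volume / min(ser$volume)
  expect_equal(corr[1] / corr, 1 + 3.5 * ser$quencher_conc,
               tolerance = 1e-9)

  # saturated loading recovers the generator's per-position constants
  qs <- generate_quench_series(cfg, gp32_ratio = 3,
                               constructs = c("21T9", "21T14"), seed = 1)
  f2 <- analyze_quench(qs$series)$fits
  k_expected <- vapply(f2$construct, function(cn) {
    unique(qs$series$ksv_true[qs$series$construct == cn])
  }, numeric(1))
  expect_equal(f2$K_SV, unname(k_expected), tolerance = 1e-9)
})

test_that("quench surface shows the footprint pattern of the design", {
  cfg <- generator_config()
  # saturation: all positions shielded, minimum at position 9
  qsat <- analyze_quench(generate_quench_series(cfg, 3, seed = 2)$series)
  expect_identical(unname(qsat$surface$min_position), 9L)
  expect_true(all(qsat$surface$matrix[, 1] < 3.5))
  expect_lt(qsat$surface$matrix["9", 1], 3.5 / 2)
  # quarter saturation: edges more exposed than the no-protein reference
  q25 <- analyze_quench(generate_quench_series(cfg, 0.75, seed = 2)$series)
  expect_gt(q25$surface$matrix["7", 1], 3.5)
  expect_gt(q25$surface$matrix["14", 1], 3.5)
  # while the 5'-proximal mid-site positions are essentially unchanged
  expect_lt(abs(q25$surface$matrix["9", 1] - 3.5), 0.35)
})

test_that("CD titrations plateau at the configured saturated amplitudes", {
  cfg <- generator_config(noise_sd = 0, cd_scans = 1L,
                          cd_wavelengths = seq(300, 400, by = 2.5))
  cd <- generate_cd_titration(cfg, seed = 1)
  res <- analyze_cd(cd$spectra, cd$metadata)
  expect_equal(res$profiles[["21T8,9"]]$plateau, 0.2, tolerance = 0.01)
  expect_equal(res$profiles[["28T22,23"]]$plateau, 0.5, tolerance = 0.01)
  amp0 <- res$amplitudes$amplitude[res$amplitudes$ratio == 0]
  expect_equal(amp0, rep(2.0, 4), tolerance = 1e-9)
  # conversion round-trips the generator truth at every ratio
  tr <- merge(res$amplitudes, cd$truth, by = c("construct", "ratio"))
  expect_equal(tr$amplitude, tr$amplitude_true, tolerance = 1e-9)
})

test_that("5'-proximal dimer probes convert before 3'-proximal ones", {
  cfg <- generator_config(cd_scans = 5L,
                          cd_wavelengths = seq(300, 400, by = 2.5))
  cd <- generate_cd_titration(cfg, seed = 3)
  res <- analyze_cd(cd$spectra, cd$metadata)
  # initial decay is steeper for 21T8,9 than for 21T13,14
  expect_lt(res$profiles[["21T8,9"]]$initial_slope,
            res$profiles[["21T13,14"]]$initial_slope)
  # the 3'-proximal 28-mer probe lags: little amplitude loss by 2 monomers
  a <- res$amplitudes
  drop_89 <- a$amplitude[a$construct == "28T8,9" & a$ratio == 0] -
    a$amplitude[a$construct == "28T8,9" & a$ratio == 2]
  drop_2223 <- a$amplitude[a$construct == "28T22,23" & a$ratio == 0] -
    a$amplitude[a$construct == "28T22,23" & a$ratio == 2]
  expect_gt(drop_89, 2 * drop_2223)
})
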