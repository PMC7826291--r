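# Exact finite-lattice statistics: recursion vs brute-force enumeration.

test_that("saturating capacity is floor(N/n)", {
  expect_identical(count_saturating_ligands(21, 7), 3L)
  expect_identical(count_saturating_ligands(28, 7), 4L)
  expect_identical(count_saturating_ligands(6, 7), 0L)
  expect_error(count_saturating_ligands(21, 0), "site_size_n")
})

test_that("enumeration produces every configuration with correct m and j", {
  cfgs <- enumerate_configurations(7, 7)
  expect_length(cfgs, 2L)
  expect_identical(vapply(cfgs, `[[`, integer(1), "m"), c(0L, 1L))

  cfgs21 <- enumerate_configurations(21, 7)
  m <- vapply(cfgs21, `[[`, integer(1), "m")
  expect_identical(sum(m == 1L), 15L)          # choose(15, 1)
  expect_identical(sum(m == 3L), 1L)           # unique tiling
  sat <- cfgs21[[which(m == 3L)]]
  expect_identical(sat$j, 2L)
  expect_identical(sat$start_positions, c(1L, 8L, 15L))

  # count with exactly m ligands equals choose(N - m*n + m, m)
  for (case in list(c(10L, 3L), c(14L, 7L), c(20L, 3L), c(28L, 7L))) {
    N <- case[1L]; n <- case[2L]
    mm <- vapply(enumerate_configurations(N, n), `[[`, integer(1), "m")
    for (k in 0:(N %/% n)) {
      expect_identical(sum(mm == k), as.integer(choose(N - k * n + k, k)),
                       label = sprintf("N=%d n=%d m=%d", N, n, k))
    }
  }
  expect_error(enumerate_configurations(41, 7), "cap")
})

test_that("configuration weights follow (K L)^m * omega^j", {
  p <- ligand_params(7, K_a = 2e6, omega = 35)
  L <- 3e-7
  KL <- p$K_a * L
  empty <- binding_configuration(integer(0), 7, 21)
  expect_identical(configuration_weight(empty, p, L), 1)
  expect_identical(configuration_weight(empty, p, 0), 1)
  sat <- binding_configuration(c(1, 8, 15), 7, 21)
  expect_equal(configuration_weight(sat, p, L), KL^3 * 35^2)
  pair <- binding_configuration(c(1, 8), 7, 14)
  expect_equal(configuration_weight(pair, p, L), KL^2 * 35)
  expect_error(binding_configuration(c(1, 5), 7, 14), "overlap")
  expect_error(binding_configuration(10, 7, 14), "fit within")
})

test_that("partition function matches closed forms", {
  p <- ligand_params(7, K_a = 1e6, omega = 12)
  L <- 2.5e-6
  KL <- p$K_a * L
  expect_equal(partition_function(7, p, L), 1 + KL)
  expect_equal(partition_function(14, p, L), 1 + 8 * KL + KL^2 * 12)
  expect_identical(partition_function(21, p, 0), 1)
  expect_equal(partition_function(14, p, L, log = TRUE),
               log(partition_function(14, p, L)))
})

test_that("recursion equals enumeration for Z, mean bound and coverage", {
  set.seed(42)
  cases <- rbind(
    expand.grid(N = c(8L, 14L, 21L, 28L), n = 7L),
    expand.grid(N = c(7L, 10L, 13L), n = 3L)
  )
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; n <- cases$n[i]
    for (draw in 1:5) {
      K <- 10^stats::runif(1, 3, 8)
      L <- 10^stats::runif(1, -9, -5)
      w <- sample(c(0, 1, 10^stats::runif(1, 0, 6)), 1L)
      p <- ligand_params(n, K, w)
      lab <- sprintf("N=%d n=%d K=%.3g w=%.3g L=%.3g", N, n, K, w, L)
      expect_equal(partition_function(N, p, L),
                   enum_partition(N, n, K, w, L),
                   tolerance = 1e-9, label = lab)
      oracle <- enum_mean_theta(N, n, K, w, L)
      prof <- mean_bound_and_coverage(N, p, L)
      expect_equal(prof$mean_bound, oracle$mean_bound,
                   tolerance = 1e-9, label = lab)
      expect_equal(prof$coverage, oracle$theta, tolerance = 1e-9, label = lab)
      # both internal routes agree as well
      prof_e <- mean_bound_and_coverage(N, p, L, method = "enumeration")
      expect_equal(prof$coverage, prof_e$coverage, tolerance = 1e-9)
    }
  }
})

test_that("mean bound and coverage obey the stated invariants", {
  p <- ligand_params(7, 1e6, 50)
  # worked example: N = 14, omega = 1, K*L = 1 gives mean bound exactly 1
  p1 <- ligand_params(7, 1, 1)
  prof1 <- mean_bound_and_coverage(14, p1, 1)
  expect_equal(prof1$mean_bound, 1.0)

  set.seed(7)
  for (draw in 1:10) {
    L <- 10^stats::runif(1, -9, -5)
    prof <- mean_bound_and_coverage(21, p, L)
    expect_true(all(prof$coverage >= 0 & prof$coverage <= 1))
    # normalization: sum theta = n * mean bound
    expect_equal(sum(prof$coverage), 7 * prof$mean_bound, tolerance = 1e-12)
    # reversal symmetry: no binding polarity in the model
    expect_equal(prof$coverage, rev(prof$coverage), tolerance = 1e-12)
  }
  # limits
  expect_equal(mean_bound_and_coverage(21, p, 0)$coverage, rep(0, 21))
  strong <- mean_bound_and_coverage(21, ligand_params(7, 1e12, 1e6), 1e-3)
  expect_equal(strong$mean_bound, 3, tolerance = 1e-6)
  expect_true(all(strong$coverage > 1 - 1e-6))
})

test_that("omega = 1 reduces to the non-cooperative combinatorial closed form", {
  n <- 7L; N <- 21L
  K <- 4e5
  for (L in c(1e-7, 1e-6, 5e-6)) {
    x <- K * L
    m_vals <- 0:(N %/% n)
    counts <- choose(N - m_vals * n + m_vals, m_vals)
    closed <- sum(m_vals * counts * x^m_vals) / sum(counts * x^m_vals)
    prof <- mean_bound_and_coverage(N, ligand_params(n, K, 1), L)
    expect_equal(prof$mean_bound, closed, tolerance = 1e-12)
  }
})

test_that("mean bound is strictly increasing in L and in K_a", {
  Ls <- 10^seq(-9, -5, length.out = 9)
  mb <- vapply(Ls, function(L) {
    mean_bound_and_coverage(21, ligand_params(7, 1e6, 100), L)$mean_bound
  }, numeric(1))
  expect_true(all(diff(mb) > 0))
  Ks <- 10^seq(4, 9, length.out = 6)
  mbK <- vapply(Ks, function(K) {
    mean_bound_and_coverage(21, ligand_params(7, K, 100), 1e-7)$mean_bound
  }, numeric(1))
  expect_true(all(diff(mbK) > 0))
})

test_that("saturated exponent is (m-1)/m", {
  expect_equal(saturated_exponent(21, 7), 2 / 3)
  expect_equal(saturated_exponent(28, 7), 3 / 4)
  expect_identical(saturated_exponent(7, 7), 0)
  expect_error(saturated_exponent(6, 7), "shorter")
})

test_that("mass balance solves and conserves ligand", {
  p <- ligand_params(7, 1e7, 1e3)
  s0 <- solve_mass_balance(0, 1e-6, 21, p)
  expect_identical(s0$free_ligand, 0)
  s1 <- solve_mass_balance(2e-6, 0, 21, p)
  expect_identical(s1$free_ligand, 2e-6)

  sol <- solve_mass_balance(1.5e-6, 1e-6, 21, p)
  expect_lt(abs(sol$residual), 1e-10 * 1.5e-6)
  # independent oracle: bisection over the enumeration-based mean bound
  f <- function(L) {
    L + 1e-6 * enum_mean_theta(21, 7, 1e7, 1e3, L)$mean_bound - 1.5e-6
  }
  root <- stats::uniroot(f, c(0, 1.5e-6), tol = 1e-18)$root
  oracle_mb <- enum_mean_theta(21, 7, 1e7, 1e3, root)$mean_bound
  expect_equal(sol$profile$mean_bound, oracle_mb, tolerance = 1e-6)

  # conservation along a titration
  for (r in c(0.5, 1.5, 3, 5)) {
    s <- solve_mass_balance(r * 1e-6, 1e-6, 21, p)
    expect_lt(abs(s$free_ligand + 1e-6 * s$profile$mean_bound - r * 1e-6),
              1e-10 * r * 1e-6 + 1e-18)
  }
})

test_that("titration curves have the stated limits", {
  con <- lattice_construct(21, 9)
  strong <- ligand_params(7, 1e9, 1e5)
  tc <- titration_curve(con, strong, c(0, 1.5, 3, 6), 1e-6)
  expect_identical(unique(tc$construct), "21T9")
  expect_equal(tc$theta[tc$ratio == 0], rep(0, 21))
  expect_equal(unique(tc$mean_bound[tc$ratio == 6]), 3, tolerance = 1e-3)
  weak <- titration_curve(con, ligand_params(7, 1e-3, 1), c(0, 3, 6), 1e-6)
  expect_lt(max(weak$mean_bound), 1e-6)
  expect_error(titration_curve(con, strong, c(3, 1), 1e-6), "sorted")
})

test_that("construct and parameter validation catch bad inputs", {
  expect_error(ligand_params(K_a = -1), "K_a")
  expect_error(ligand_params(omega = -0.1), "omega")
  expect_error(lattice_construct(21, 25), "probe positions")
  expect_error(lattice_construct(21, c(8, 10)), "adjacent")
  expect_error(probe_coverage(mean_bound_and_coverage(21, ligand_params(), 0),
                              lattice_construct(21)), "no probe")
})
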