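# Enumeration-based oracles, independent of the transfer-recursion code path.

enum_partition <- function(length_nt, site_size_n, K_a, omega, L) {
  cfgs <- enumerate_configurations(length_nt, site_size_n)
  p <- ligand_params(site_size_n, K_a, omega)
  sum(vapply(cfgs, configuration_weight, numeric(1),
             params = p, free_ligand = L))
}

enum_mean_theta <- function(length_nt, site_size_n, K_a, omega, L) {
  cfgs <- enumerate_configurations(length_nt, site_size_n)
  p <- ligand_params(site_size_n, K_a, omega)
  w <- vapply(cfgs, configuration_weight, numeric(1),
              params = p, free_ligand = L)
  Z <- sum(w)
  m <- vapply(cfgs, `[[`, numeric(1), "m")
  theta <- numeric(length_nt)
  for (i in seq_along(cfgs)) {
    for (s in cfgs[[i]]$start_positions) {
      idx <- s:(s + site_size_n - 1L)
      theta[idx] <- theta[idx] + w[i]
    }
  }
  list(mean_bound = sum(m * w) / Z, theta = theta / Z, Z = Z)
}

# a small, fast generator configuration for pipeline-level tests
tiny_config <- function(...) {
  generator_config(
    replicates_fluor = 1L, replicates_quench = 2L, cd_scans = 3L,
    cd_wavelengths = seq(300, 400, by = 5), quench_points = 7L,
    ...
  )
}
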