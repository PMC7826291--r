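# Synthetic instrument-like data generator.
#
# Emulates the three assays of the footprinting design -- stock-addition
# fluorescence titrations, acrylamide quench series and CD exciton-band
# titrations -- with the statistical structure the analysis pipeline
# assumes: stock-addition dilution, an unlabeled-construct background
# series, Gaussian multiplicative replicate noise, and a small apparent
# lattice-competence shortfall that places the measured equivalence point
# slightly below the integer capacity.

#' Generator configuration
#'
#' Defaults reproduce the stated experimental world: 1 uM lattice for
#' fluorescence work and 6 uM for CD, 40 uM gp32 and 1 M acrylamide stock
#' solutions, titration grids extending to 2x saturation, 2% relative
#' Gaussian noise per measured channel, 3 fluorescence replicates, 6 quench
#' replicates and 20 CD scans.  `active_fraction` (default 0.9667) scales
#' the lattice concentration that is actually competent to bind, so that
#' equivalence points land near `capacity * active_fraction` (2.9 monomers
#' per 21-mer) while the ratio axis keeps its nominal value.
#' `fill_priority` in `[0, 1]` sets how strongly binding sites fill in 5'
#' to 3' order during the titration (0 = uniform, 1 = strict 5'-first).
#'
#' @param params A [ligand_params] (placeholder affinities: the source
#'   experiments are stoichiometric, so only `K_a * omega^x >> 1/conc`
#'   matters).
#' @param lattice_conc Fluorescence-assay lattice concentration (M).
#' @param cd_lattice_conc CD-assay lattice concentration (M).
#' @param gp32_stock,acrylamide_stock Stock concentrations (M).
#' @param active_fraction Apparent competent fraction of the nominal lattice
#'   concentration.
#' @param noise_sd Relative Gaussian noise sd per measured channel.
#' @param replicates_fluor,replicates_quench,cd_scans Replicate counts.
#' @param f0_counts Probe fluorescence of the free construct (counts).
#' @param background_counts Unlabeled-construct background (counts).
#' @param initial_volume Starting sample volume (uL).
#' @param ratio_step_frac Fluorescence ratio-grid step as a fraction of the
#'   lattice capacity (default 1/8: 17 points from 0 to 2x saturation).
#' @param quench_max,quench_points Acrylamide grid: 0 to `quench_max` M in
#'   `quench_points` points.
#' @param fill_priority 5'-first site-filling priority strength.
#' @param fluor A [fluor_params] with per-position enhancement ratios.
#' @param quench A [quench_params].
#' @param cd Named list of [cd_params], keyed by dimer construct name.
#' @param cd_wavelengths CD wavelength grid (nm).
#' @param cd_ratio_step CD titration ratio step.
#' @param cd_path_length Cuvette path length (cm).
#' @param seed Default random seed.
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(params = ligand_params(),
                             lattice_conc = 1e-6,
                             cd_lattice_conc = 6e-6,
                             gp32_stock = 40e-6,
                             acrylamide_stock = 1.0,
                             active_fraction = 0.9667,
                             noise_sd = 0.02,
                             replicates_fluor = 3L,
                             replicates_quench = 6L,
                             cd_scans = 20L,
                             f0_counts = 1e5,
                             background_counts = 3000,
                             initial_volume = 800,
                             ratio_step_frac = 1 / 8,
                             quench_max = 0.3,
                             quench_points = 13L,
                             fill_priority = 0.6,
                             fluor = fluor_params(),
                             quench = quench_params(),
                             cd = list(
                               "21T8,9"   = cd_params(amplitude_sat = 0.2),
                               "21T13,14" = cd_params(amplitude_sat = 0.35),
                               "28T8,9"   = cd_params(amplitude_sat = 0.2),
                               "28T22,23" = cd_params(amplitude_sat = 0.5)
                             ),
                             cd_wavelengths = seq(300, 400, by = 1),
                             cd_ratio_step = 0.5,
                             cd_path_length = 1,
                             seed = 1L) {
  stopifnot(inherits(params, "ligand_params"),
            inherits(fluor, "fluor_params"),
            inherits(quench, "quench_params"))
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("'active_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (fill_priority < 0 || fill_priority > 1) {
    stop("'fill_priority' must lie in [0, 1]", call. = FALSE)
  }
  arg_names <- names(formals(generator_config))
  for (nm in c("lattice_conc", "cd_lattice_conc", "gp32_stock",
               "acrylamide_stock", "noise_sd")) {
    stopifnot_scalar_number(get(nm), nm, lower = 0)
  }
  structure(mget(arg_names), class = "generator_config")
}

# Deterministic (noise-free) occupancy table shared by all constructs of one
# lattice length: one mass-balance solve per titration point, returning the
# full coverage profile so every probe position is read from the same solve.
fluor_truth_table <- function(config, length_nt) {
  cap <- count_saturating_ligands(length_nt, config$params$site_size_n)
  ratios <- seq(0, 2 * cap, by = cap * config$ratio_step_frac)
  V0 <- config$initial_volume
  vol <- V0 + ratios * config$lattice_conc * V0 / config$gp32_stock
  dil <- V0 / vol
  coverage <- matrix(0, nrow = length(ratios), ncol = length_nt)
  mean_bound <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    sol <- solve_mass_balance(
      total_ligand = ratios[i] * config$lattice_conc * dil[i],
      lattice_conc = config$active_fraction * config$lattice_conc * dil[i],
      length_nt = length_nt, params = config$params
    )
    coverage[i, ] <- sol$profile$coverage
    mean_bound[i] <- sol$profile$mean_bound
  }
  list(ratios = ratios, volume = vol, dilution = dil,
       coverage = coverage, mean_bound = mean_bound, capacity = cap)
}

probe_theta_from_truth <- function(truth, construct) {
  if (!length(construct$probe_positions)) {
    return(rep(0, length(truth$ratios)))
  }
  rowMeans(truth$coverage[, construct$probe_positions, drop = FALSE])
}

#' Simulate stock-addition fluorescence titrations
#'
#' For each construct and replicate, produces raw 370 nm intensities along a
#' gp32 titration from 0 to twice the lattice capacity.  Raw counts are
#' `F0 * (1 + (R_p - 1) * theta_p)` scaled by the cumulative dilution factor,
#' plus the unlabeled-construct background, with multiplicative Gaussian
#' noise on both channels.  A background series per lattice length is
#' returned alongside for use by [correct_series()].
#'
#' @param config A [generator_config].
#' @param constructs Character vector of construct names (default: all
#'   monomer-probe 21-mers).
#' @param seed Random seed (defaults to `config$seed`).
#' @return An object of class `synthetic_fluorescence`: `$titrations`
#'   (construct, replicate, ratio, volume, counts, signal_true),
#'   `$background` (length_nt, ratio, volume, counts), `$config`, `$seed`.
#' @export
generate_fluorescence_titration <- function(config = generator_config(),
                                            constructs = registry_names("monomer"),
                                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cons <- lapply(constructs, parse_construct_name)
  lengths_needed <- sort(unique(vapply(cons, `[[`, integer(1), "length_nt")))
  truths <- lapply(lengths_needed, fluor_truth_table, config = config)
  names(truths) <- as.character(lengths_needed)

  rows <- list()
  for (k in seq_along(cons)) {
    cc <- cons[[k]]
    truth <- truths[[as.character(cc$length_nt)]]
    theta <- probe_theta_from_truth(truth, cc)
    Rp <- if (cc$probe_kind == "monomer") {
      r <- config$fluor$R[as.character(cc$probe_positions)]
      if (is.na(r)) 4.0 else unname(r)
    } else if (cc$probe_kind == "dimer") {
      mean(ifelse(cc$probe_positions <= 10, 4.5, 4.0))
    } else {
      1
    }
    signal_true <- if (cc$probe_kind == "none") {
      rep(0, length(theta)) # unlabeled control: background only
    } else {
      config$f0_counts * fluorescence_signal(theta, Rp)
    }
    for (rep_i in seq_len(config$replicates_fluor)) {
      np <- length(truth$ratios)
      counts <- signal_true * truth$dilution *
        (1 + config$noise_sd * stats::rnorm(np)) +
        config$background_counts * truth$dilution *
          (1 + config$noise_sd * stats::rnorm(np))
      rows[[length(rows) + 1L]] <- data.frame(
        construct = cc$name, replicate = rep_i, ratio = truth$ratios,
        volume = truth$volume, counts = counts, signal_true = signal_true
      )
    }
  }

  bg_rows <- list()
  for (ln in lengths_needed) {
    truth <- truths[[as.character(ln)]]
    np <- length(truth$ratios)
    bg_rows[[length(bg_rows) + 1L]] <- data.frame(
      length_nt = ln, ratio = truth$ratios, volume = truth$volume,
      counts = config$background_counts * truth$dilution *
        (1 + config$noise_sd * stats::rnorm(np))
    )
  }

  structure(
    list(titrations = do.call(rbind, rows),
         background = do.call(rbind, bg_rows),
         config = config, seed = seed),
    class = "synthetic_fluorescence"
  )
}

#' Simulate acrylamide quench series
#'
#' Generates fluorescence versus quencher concentration at a fixed gp32
#' loading.  The true Stern-Volmer constant per probe position is the
#' three-state [ksv_signal()] value with a transient (dynamically
#' exchanging) coverage share of `theta_p * (1 - saturation_fraction)`:
#' at sub-saturating loading the binding-site edges show elevated exposure,
#' while at saturation the stable-coverage constants apply and probe access
#' is minimal near the middle of the central binding site.  Quencher
#' concentrations are dilution-corrected under 1 M stock-addition
#' bookkeeping; counts carry the same dilution factor and multiplicative
#' noise as the titrations.
#'
#' @param config A [generator_config].
#' @param gp32_ratio gp32 monomers added per lattice (nominal).
#' @param constructs Construct names (default all monomer-probe 21-mers).
#' @param seed Random seed.
#' @return An object of class `synthetic_quench`: `$series` (construct,
#'   position, replicate, quencher_conc, volume, counts, ksv_true),
#'   `$gp32_ratio`, `$config`, `$seed`.
#' @export
generate_quench_series <- function(config = generator_config(),
                                   gp32_ratio = 0,
                                   constructs = registry_names("monomer"),
                                   seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  stopifnot_scalar_number(gp32_ratio, "gp32_ratio", lower = 0)
  set.seed(seed)
  cons <- lapply(constructs, parse_construct_name)
  lengths_needed <- sort(unique(vapply(cons, `[[`, integer(1), "length_nt")))
  profs <- lapply(lengths_needed, function(ln) {
    solve_mass_balance(
      total_ligand = gp32_ratio * config$lattice_conc,
      lattice_conc = config$active_fraction * config$lattice_conc,
      length_nt = ln, params = config$params
    )$profile
  })
  names(profs) <- as.character(lengths_needed)

  Q <- seq(0, config$quench_max, length.out = config$quench_points)
  V0 <- config$initial_volume
  vol <- V0 + Q * V0 / (config$acrylamide_stock - Q)
  dil <- V0 / vol

  rows <- list()
  for (cc in cons) {
    if (cc$probe_kind != "monomer") next
    pos <- cc$probe_positions
    prof <- profs[[as.character(cc$length_nt)]]
    theta <- prof$coverage[pos]
    transient <- theta * (1 - prof$saturation_fraction)
    qp <- config$quench
    key <- as.character(pos)
    kb <- if (key %in% names(qp$K_bound)) qp$K_bound[[key]] else 2.0
    kt <- if (key %in% names(qp$K_transient)) qp$K_transient[[key]] else 5.0
    k_true <- ksv_signal(theta, transient, qp$K_free, kb, kt)
    Rp <- config$fluor$R[key]
    if (is.na(Rp)) Rp <- 4.0
    f_unquenched <- config$f0_counts * fluorescence_signal(theta, unname(Rp))
    for (rep_i in seq_len(config$replicates_quench)) {
      counts <- f_unquenched * dil / (1 + k_true * Q) *
        (1 + config$noise_sd * stats::rnorm(length(Q)))
      rows[[length(rows) + 1L]] <- data.frame(
        construct = cc$name, position = pos, replicate = rep_i,
        quencher_conc = Q, volume = vol, counts = counts, ksv_true = k_true
      )
    }
  }

  structure(
    list(series = do.call(rbind, rows), gp32_ratio = gp32_ratio,
         config = config, seed = seed),
    class = "synthetic_quench"
  )
}

# Conversion fraction of a dimer probe under 5'-first filling priority.
# kappa is the probe's fractional site coordinate from the 5' end; with full
# priority a probe converts once the mean bound count passes kappa, with no
# priority conversion tracks overall saturation.
dimer_conversion <- function(mean_bound, capacity, probe_positions,
                             site_size_n, fill_priority) {
  kappa <- (mean(probe_positions) - 0.5) / site_size_n - 0.5
  fill_priority * clamp(mean_bound - kappa, 0, 1) +
    (1 - fill_priority) * clamp(mean_bound / capacity, 0, 1)
}

#' Simulate CD exciton-band titrations
#'
#' Generates replicate CD scans over 300-400 nm for dimer-probe constructs
#' across a gp32 titration to twice saturation.  The exciton band is a
#' single Gaussian at 325 nm whose amplitude follows [cd_amplitude()] with a
#' stacked fraction of `1 - conversion`, where the conversion of each probe
#' follows the mean bound ligand count with a 5'-first site-filling
#' priority: 5'-proximal dimer probes lose amplitude earlier in the
#' titration than 3'-proximal ones.  Scans are emitted as raw ellipticities
#' (mdeg) with additive noise, together with the conversion metadata needed
#' by [to_delta_epsilon_per_ap()].
#'
#' @param config A [generator_config].
#' @param constructs Dimer-probe construct names.
#' @param seed Random seed.
#' @return An object of class `synthetic_cd`: `$spectra` (construct, ratio,
#'   scan, wavelength, ellipticity_mdeg), `$truth` (construct, ratio,
#'   amplitude_true), `$metadata` (construct, concentration, path_length,
#'   n_ap), `$config`, `$seed`.
#' @export
generate_cd_titration <- function(config = generator_config(),
                                  constructs = registry_names("dimer"),
                                  seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cons <- lapply(constructs, parse_construct_name)
  wl <- config$cd_wavelengths
  n <- config$params$site_size_n

  mb_cache <- new.env(parent = emptyenv())
  mean_bound_at <- function(length_nt, ratio) {
    key <- paste(length_nt, ratio)
    if (!is.null(mb_cache[[key]])) return(mb_cache[[key]])
    mb <- solve_mass_balance(
      total_ligand = ratio * config$cd_lattice_conc,
      lattice_conc = config$active_fraction * config$cd_lattice_conc,
      length_nt = length_nt, params = config$params
    )$profile$mean_bound
    mb_cache[[key]] <- mb
    mb
  }

  spec_rows <- list()
  truth_rows <- list()
  meta_rows <- list()
  for (cc in cons) {
    if (cc$probe_kind != "dimer") {
      stop(sprintf("'%s' is not a dimer-probe construct", cc$name),
           call. = FALSE)
    }
    cdp <- config$cd[[cc$name]] %||% cd_params()
    cap <- count_saturating_ligands(cc$length_nt, n)
    ratios <- seq(0, 2 * cap, by = config$cd_ratio_step)
    mdeg_scale <- 32980 * config$cd_lattice_conc * config$cd_path_length * 2
    band <- exp(-(wl - cdp$peak_wavelength)^2 / (2 * cdp$band_width^2))
    for (r in ratios) {
      mb <- mean_bound_at(cc$length_nt, r)
      conv <- dimer_conversion(mb, cap, cc$probe_positions, n,
                               config$fill_priority)
      amp <- cd_amplitude(1 - conv, cdp)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        construct = cc$name, ratio = r, amplitude_true = amp
      )
      for (scan in seq_len(config$cd_scans)) {
        de <- amp * band +
          config$noise_sd * cdp$amplitude_free * stats::rnorm(length(wl))
        spec_rows[[length(spec_rows) + 1L]] <- data.frame(
          construct = cc$name, ratio = r, scan = scan, wavelength = wl,
          ellipticity_mdeg = de * mdeg_scale
        )
      }
    }
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      construct = cc$name, concentration = config$cd_lattice_conc,
      path_length = config$cd_path_length, n_ap = 2L
    )
  }

  structure(
    list(spectra = do.call(rbind, spec_rows),
         truth = do.call(rbind, truth_rows),
         metadata = do.call(rbind, meta_rows),
         config = config, seed = seed),
    class = "synthetic_cd"
  )
}
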