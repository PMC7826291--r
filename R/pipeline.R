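# End-to-end pipeline: simulate -> titrate -> quench -> cd -> report,
# with tidy CSV outputs and a JSON run manifest.

#' Analyze fluorescence titrations
#'
#' Applies [correct_series()], [equivalence_point()] and
#' [enhancement_ratio()] to every construct/replicate titration of a
#' synthetic (or identically structured) dataset.
#'
#' @param titrations Data.frame with columns `construct`, `replicate`,
#'   `ratio`, `volume`, `counts`.
#' @param background Data.frame with columns `length_nt`, `ratio`, `counts`
#'   (one series per lattice length), or `NULL`.
#' @param site_size_n Ligand site size used for the over-saturation window.
#' @return List with `per_replicate` (construct, replicate, stoichiometry,
#'   enhancement) and `summary` (construct, mean/sd stoichiometry, mean
#'   enhancement, n).
#' @export
analyze_titrations <- function(titrations, background = NULL,
                               site_size_n = 7L) {
  req <- c("construct", "replicate", "ratio", "volume", "counts")
  if (!all(req %in% names(titrations))) {
    stop("titration table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (key in split(titrations,
                    list(titrations$construct, titrations$replicate),
                    drop = TRUE)) {
    cc <- parse_construct_name(key$construct[1L])
    bg <- if (!is.null(background)) {
      background[background$length_nt == cc$length_nt, ]
    }
    if (!is.null(bg) && !nrow(bg)) bg <- NULL
    series <- correct_series(key[order(key$ratio), ], background = bg,
                             construct = cc$name,
                             replicate = key$replicate[1L])
    eq <- equivalence_point(series)
    cap <- count_saturating_ligands(cc$length_nt, site_size_n)
    enh <- enhancement_ratio(series, cap)
    rows[[length(rows) + 1L]] <- data.frame(
      construct = cc$name, replicate = key$replicate[1L],
      stoichiometry = eq$stoichiometry, enhancement = enh
    )
  }
  per_replicate <- do.call(rbind, rows)
  per_replicate <- per_replicate[order(per_replicate$construct,
                                       per_replicate$replicate), ]
  summary <- do.call(rbind, lapply(split(per_replicate,
                                         per_replicate$construct),
    function(d) data.frame(
      construct = d$construct[1L],
      stoichiometry_mean = mean(d$stoichiometry),
      stoichiometry_sd = stats::sd(d$stoichiometry),
      enhancement_mean = mean(d$enhancement),
      n_replicates = nrow(d)
    )))
  rownames(summary) <- NULL
  list(per_replicate = per_replicate, summary = summary)
}

#' Analyze quench series
#'
#' Dilution-corrects and Stern-Volmer-fits every construct/replicate series,
#' optionally across several gp32 loadings, and assembles the
#' position-by-ratio [ksv_surface()].
#'
#' @param series Data.frame with columns `construct`, `position`,
#'   `replicate`, `quencher_conc`, `volume`, `counts` and (when series from
#'   several loadings are stacked) `gp32_ratio`.
#' @return List with `fits` (one row per construct/replicate/loading:
#'   `K_SV`, `K_SV_se`, `intercept`, `r_squared`, `n_points`) and `surface`
#'   (a [ksv_surface] over replicate-averaged fits).
#' @export
analyze_quench <- function(series) {
  req <- c("construct", "position", "replicate", "quencher_conc",
           "volume", "counts")
  if (!all(req %in% names(series))) {
    stop("quench table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"gp32_ratio" %in% names(series)) series$gp32_ratio <- 0
  rows <- list()
  for (key in split(series,
                    list(series$construct, series$replicate,
                         series$gp32_ratio), drop = TRUE)) {
    key <- key[order(key$quencher_conc), ]
    sv <- correct_quench_series(key, construct = key$construct[1L],
                                position = key$position[1L])
    fit <- fit_stern_volmer(sv)
    rows[[length(rows) + 1L]] <- data.frame(
      construct = key$construct[1L], position = key$position[1L],
      replicate = key$replicate[1L], ratio = key$gp32_ratio[1L],
      K_SV = fit$K_SV, K_SV_se = fit$K_SV_se, intercept = fit$intercept,
      r_squared = fit$r_squared, n_points = fit$n_points
    )
  }
  fits <- do.call(rbind, rows)
  fits <- fits[order(fits$ratio, fits$position, fits$replicate), ]
  rownames(fits) <- NULL
  list(fits = fits, surface = ksv_surface(fits))
}

#' Analyze CD titrations
#'
#' Averages replicate scans per construct and loading, converts to
#' Delta-epsilon per 2-AP, extracts the 325 nm exciton-peak amplitude and
#' builds the titration profile per construct.
#'
#' @param spectra Data.frame with columns `construct`, `ratio`, `scan`,
#'   `wavelength`, `ellipticity_mdeg` (or `delta_epsilon` for
#'   already-converted values).
#' @param metadata Data.frame with columns `construct`, `concentration`,
#'   `path_length`, `n_ap`; required when `spectra` carries mdeg values.
#' @param site_size_n Ligand site size, for the saturation ratio.
#' @return List with `amplitudes` (construct, ratio, amplitude) and
#'   `profiles` (named list of [titration_profile] results).
#' @export
analyze_cd <- function(spectra, metadata = NULL, site_size_n = 7L) {
  raw <- "ellipticity_mdeg" %in% names(spectra)
  value_col <- if (raw) "ellipticity_mdeg" else "delta_epsilon"
  req <- c("construct", "ratio", "scan", "wavelength", value_col)
  if (!all(req %in% names(spectra))) {
    stop("CD table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (raw && is.null(metadata)) {
    stop("metadata (concentration, path_length, n_ap) required for mdeg input",
         call. = FALSE)
  }
  amp_rows <- list()
  for (key in split(spectra, list(spectra$construct, spectra$ratio),
                    drop = TRUE)) {
    cname <- key$construct[1L]
    d <- data.frame(wavelength = key$wavelength, value = key[[value_col]],
                    scan = key$scan)
    avg <- average_scans(d)
    if (raw) {
      md <- metadata[metadata$construct == cname, ]
      if (!nrow(md)) {
        stop(sprintf("no conversion metadata for construct '%s'", cname),
             call. = FALSE)
      }
      avg$units <- "mdeg"
      avg <- to_delta_epsilon_per_ap(avg, md$concentration[1L],
                                     md$path_length[1L], md$n_ap[1L])
    }
    amp_rows[[length(amp_rows) + 1L]] <- data.frame(
      construct = cname, ratio = key$ratio[1L],
      amplitude = peak_amplitude(avg)
    )
  }
  amplitudes <- do.call(rbind, amp_rows)
  amplitudes <- amplitudes[order(amplitudes$construct, amplitudes$ratio), ]
  rownames(amplitudes) <- NULL
  profiles <- lapply(split(amplitudes, amplitudes$construct), function(d) {
    cc <- parse_construct_name(d$construct[1L])
    cap <- count_saturating_ligands(cc$length_nt, site_size_n)
    titration_profile(d$ratio, d$amplitude, saturation_ratio = cap)
  })
  list(amplitudes = amplitudes, profiles = profiles)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[gp32footprint] ", fmt), ...))
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates the three assays with the supplied configuration, runs the
#' three analysis stages, writes tidy CSV outputs plus a JSON run manifest
#' (config snapshot, seed, file inventory with MD5 checksums) to `outdir`,
#' and returns the in-memory results.  Outputs are a pure function of
#' `(config, seed)`: a rerun with the same seed reproduces identical files.
#'
#' @param config A [generator_config].
#' @param outdir Output directory (created if needed).
#' @param seed Random seed (defaults to `config$seed`).
#' @param quench_ratios gp32 loadings at which quench series are simulated.
#' @param quiet Suppress stage logging?
#' @return Invisibly, a list with `manifest`, `titration`, `quench`, `cd`.
#' @export
run_pipeline <- function(config = generator_config(), outdir,
                         seed = config$seed,
                         quench_ratios = c(0, 0.75, 1.5, 3, 6),
                         quiet = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tidy_csv(df, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  pipeline_log(quiet, "simulate: fluorescence titrations (seed %d)", seed)
  fl <- generate_fluorescence_titration(config, seed = seed)
  emit(fl$titrations, "fluor_titrations.csv")
  emit(fl$background, "fluor_background.csv")

  pipeline_log(quiet, "simulate: quench series at %d gp32 loadings",
               length(quench_ratios))
  qn_list <- lapply(seq_along(quench_ratios), function(i) {
    qs <- generate_quench_series(config, gp32_ratio = quench_ratios[i],
                                 seed = seed + i)
    df <- qs$series
    df$gp32_ratio <- quench_ratios[i]
    df
  })
  qn <- do.call(rbind, qn_list)
  emit(qn, "quench_raw.csv")

  pipeline_log(quiet, "simulate: CD titrations")
  cd <- generate_cd_titration(config, seed = seed)
  emit(cd$spectra, "cd_spectra.csv")
  emit(cd$metadata, "cd_metadata.csv")

  pipeline_log(quiet, "titrate: %d series",
               length(unique(paste(fl$titrations$construct,
                                   fl$titrations$replicate))))
  tit <- analyze_titrations(fl$titrations, fl$background,
                            config$params$site_size_n)
  emit(tit$per_replicate, "stoichiometry_per_replicate.csv")
  emit(tit$summary, "stoichiometry_summary.csv")

  pipeline_log(quiet, "quench: fitting Stern-Volmer constants")
  qres <- analyze_quench(qn)
  emit(qres$fits, "quench_fits.csv")
  surf <- as.data.frame.table(qres$surface$matrix, responseName = "K_SV")
  emit(surf, "ksv_surface.csv")

  pipeline_log(quiet, "cd: exciton-peak profiles")
  cres <- analyze_cd(cd$spectra, cd$metadata, config$params$site_size_n)
  emit(cres$amplitudes, "cd_profiles.csv")

  manifest <- list(
    package = "gp32footprint",
    version = as.character(utils::packageVersion("gp32footprint")),
    seed = seed,
    config = list(
      site_size_n = config$params$site_size_n,
      K_a = config$params$K_a,
      omega = config$params$omega,
      lattice_conc = config$lattice_conc,
      cd_lattice_conc = config$cd_lattice_conc,
      active_fraction = config$active_fraction,
      noise_sd = config$noise_sd,
      fill_priority = config$fill_priority,
      replicates_fluor = config$replicates_fluor,
      replicates_quench = config$replicates_quench,
      cd_scans = config$cd_scans,
      quench_ratios = quench_ratios
    ),
    outputs = lapply(unlist(paths), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)
    })
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipeline_log(quiet, "done: %d output files in %s",
               length(paths) + 1L, outdir)
  invisible(list(manifest = manifest, titration = tit, quench = qres,
                 cd = cres))
}

read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$K_a) || !is.null(raw$omega) || !is.null(raw$site_size_n)) {
    args$params <- ligand_params(
      site_size_n = raw$site_size_n %||% 7L,
      K_a = raw$K_a %||% 1e7,
      omega = raw$omega %||% 1e3
    )
  }
  for (nm in c("lattice_conc", "cd_lattice_conc", "active_fraction",
               "noise_sd", "fill_priority", "replicates_fluor",
               "replicates_quench", "cd_scans", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(generator_config, args)
}

parse_cli_flags <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[[i + 1L]])) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write raw synthetic CSVs), `titrate`, `quench`,
#' `cd` (analyze raw CSVs in `--outdir`), `model` (lattice-model query) and
#' `run` (full pipeline).  Global flags: `--config <json>`, `--seed <int>`,
#' `--outdir <dir>`, `--quiet`.  Installed as `inst/cli/footprint.R`, run
#' with `Rscript $(Rscript -e 'cat(system.file("cli/footprint.R",
#' package = "gp32footprint"))') run --outdir out`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: footprint.R <simulate|titrate|quench|cd|model|run> [--config f] [--seed n] [--outdir d] [--quiet]\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  parsed <- parse_cli_flags(args[-1L])
  fl <- parsed$flags
  config <- if (!is.null(fl$config)) read_config_json(fl$config)
            else generator_config()
  seed <- as.integer(fl$seed %||% config$seed)
  outdir <- fl$outdir %||% "."
  quiet <- isTRUE(fl$quiet)

  status <- 0L
  tryCatch({
    if (cmd == "simulate") {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      flx <- generate_fluorescence_titration(config, seed = seed)
      write_tidy_csv(flx$titrations, file.path(outdir, "fluor_titrations.csv"))
      write_tidy_csv(flx$background, file.path(outdir, "fluor_background.csv"))
      qs <- generate_quench_series(config, gp32_ratio = as.numeric(fl$ratio %||% 0),
                                   seed = seed)
      df <- qs$series
      df$gp32_ratio <- qs$gp32_ratio
      write_tidy_csv(df, file.path(outdir, "quench_raw.csv"))
      cdx <- generate_cd_titration(config, seed = seed)
      write_tidy_csv(cdx$spectra, file.path(outdir, "cd_spectra.csv"))
      write_tidy_csv(cdx$metadata, file.path(outdir, "cd_metadata.csv"))
    } else if (cmd == "titrate") {
      tit <- analyze_titrations(
        read_tidy_csv(file.path(outdir, "fluor_titrations.csv"),
                      c("construct", "replicate", "ratio", "volume", "counts")),
        read_tidy_csv(file.path(outdir, "fluor_background.csv"),
                      c("length_nt", "ratio", "counts")),
        config$params$site_size_n
      )
      write_tidy_csv(tit$per_replicate,
                     file.path(outdir, "stoichiometry_per_replicate.csv"))
      write_tidy_csv(tit$summary, file.path(outdir, "stoichiometry_summary.csv"))
    } else if (cmd == "quench") {
      qres <- analyze_quench(
        read_tidy_csv(file.path(outdir, "quench_raw.csv"),
                      c("construct", "position", "replicate", "quencher_conc",
                        "volume", "counts"))
      )
      write_tidy_csv(qres$fits, file.path(outdir, "quench_fits.csv"))
    } else if (cmd == "cd") {
      cres <- analyze_cd(
        read_tidy_csv(file.path(outdir, "cd_spectra.csv"),
                      c("construct", "ratio", "scan", "wavelength")),
        read_tidy_csv(file.path(outdir, "cd_metadata.csv"),
                      c("construct", "concentration", "path_length", "n_ap")),
        config$params$site_size_n
      )
      write_tidy_csv(cres$amplitudes, file.path(outdir, "cd_profiles.csv"))
    } else if (cmd == "model") {
      N <- as.integer(fl$length %||% 21L)
      ratio <- as.numeric(fl$ratio %||% 3)
      sol <- solve_mass_balance(ratio * config$lattice_conc,
                                config$lattice_conc, N, config$params)
      print(sol)
      print(sol$profile)
    } else if (cmd == "run") {
      run_pipeline(config, outdir, seed = seed, quiet = quiet)
    } else {
      stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
    }
  }, error = function(e) {
    message(sprintf("[gp32footprint] stage '%s' failed: %s", cmd,
                    conditionMessage(e)))
    status <<- 1L
  })
  invisible(status)
}
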