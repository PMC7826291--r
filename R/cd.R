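# CD titration processing: replicate averaging, mdeg -> Delta-epsilon/2-AP
# conversion, 325 nm exciton-peak extraction and titration-profile summary.

#' CD spectrum container
#'
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param value Spectral values: Delta-epsilon per 2-AP (1/(M cm)) or raw
#'   ellipticity (mdeg).
#' @param sd Optional per-wavelength standard deviation (uncertainty band).
#' @param units `"delta_epsilon_per_ap"` or `"mdeg"`.
#' @param n_scans Number of averaged scans this spectrum represents.
#' @param metadata Optional list (e.g. `concentration`, `path_length`,
#'   `n_ap`) required to convert raw ellipticities.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, value, sd = NULL,
                        units = c("delta_epsilon_per_ap", "mdeg"),
                        n_scans = 1L, metadata = list()) {
  units <- match.arg(units)
  if (length(wavelength) != length(value) || !length(wavelength)) {
    stop("'wavelength' and 'value' must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("'wavelength' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, value = value, sd = sd, units = units,
         n_scans = n_scans, metadata = metadata),
    class = "cd_spectrum"
  )
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %.0f-%.0f nm, %s (%d scan%s)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$units, x$n_scans, if (x$n_scans == 1L) "" else "s"))
  invisible(x)
}

#' Average replicate CD scans
#'
#' Pointwise mean of replicate scans, retaining the per-wavelength standard
#' deviation as the uncertainty band.  Scans on different grids can be
#' linearly interpolated onto their common overlapping grid when
#' `interpolate = TRUE`.
#'
#' @param scans List of [cd_spectrum] objects (or a data.frame with columns
#'   `wavelength`, `value`, `scan`).
#' @param interpolate Allow interpolation onto a common grid?
#' @return A [cd_spectrum] with `sd` filled in and `n_scans` set.
#' @export
average_scans <- function(scans, interpolate = FALSE) {
  if (is.data.frame(scans)) {
    req <- c("wavelength", "value", "scan")
    if (!all(req %in% names(scans))) {
      stop("data.frame input needs columns wavelength, value, scan",
           call. = FALSE)
    }
    scans <- lapply(split(scans, scans$scan), function(d) {
      d <- d[order(d$wavelength), ]
      cd_spectrum(d$wavelength, d$value)
    })
  }
  if (!length(scans)) stop("no scans supplied", call. = FALSE)
  stopifnot(all(vapply(scans, inherits, logical(1), "cd_spectrum")))
  units <- unique(vapply(scans, `[[`, character(1), "units"))
  if (length(units) != 1L) {
    stop("scans mix units; convert before averaging", call. = FALSE)
  }
  grids <- lapply(scans, `[[`, "wavelength")
  same_grid <- all(vapply(grids, identical, logical(1), grids[[1L]]))
  if (same_grid) {
    grid <- grids[[1L]]
    vals <- vapply(scans, `[[`, numeric(length(grid)), "value")
  } else {
    if (!interpolate) {
      stop("scans are on different wavelength grids; set interpolate = TRUE",
           call. = FALSE)
    }
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo >= hi) stop("wavelength grids do not overlap", call. = FALSE)
    grid <- sort(unique(unlist(grids)))
    grid <- grid[grid >= lo & grid <= hi]
    vals <- vapply(scans, function(s) {
      stats::approx(s$wavelength, s$value, xout = grid)$y
    }, numeric(length(grid)))
  }
  vals <- matrix(vals, nrow = length(grid))
  cd_spectrum(grid, rowMeans(vals),
              sd = if (ncol(vals) > 1L) apply(vals, 1L, stats::sd) else NULL,
              units = units, n_scans = length(scans),
              metadata = scans[[1L]]$metadata)
}

#' Convert raw ellipticity to Delta-epsilon per 2-AP
#'
#' `Delta-epsilon/AP = mdeg / (32980 * c * l * n_AP)` with `c` the construct
#' molarity, `l` the path length in cm and `n_AP` the number of 2-AP
#' residues per construct (1 for monomer, 2 for dimer probes).  The factor
#' 32980 converts molar ellipticity (mdeg) to Delta-epsilon units.
#'
#' @param spectrum A [cd_spectrum] in mdeg units.
#' @param concentration Construct concentration (M); taken from the spectrum
#'   metadata when missing.
#' @param path_length Path length (cm); ditto.
#' @param n_ap 1 or 2; ditto.
#' @return A [cd_spectrum] in Delta-epsilon/2-AP units.
#' @export
to_delta_epsilon_per_ap <- function(spectrum, concentration = NULL,
                                    path_length = NULL, n_ap = NULL) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (spectrum$units != "mdeg") {
    stop("spectrum is not in mdeg units", call. = FALSE)
  }
  concentration <- concentration %||% spectrum$metadata$concentration
  path_length <- path_length %||% spectrum$metadata$path_length
  n_ap <- n_ap %||% spectrum$metadata$n_ap
  if (is.null(concentration) || is.null(path_length) || is.null(n_ap)) {
    stop("conversion metadata (concentration, path_length, n_ap) missing",
         call. = FALSE)
  }
  stopifnot_scalar_number(concentration, "concentration", 0, strict = TRUE)
  stopifnot_scalar_number(path_length, "path_length", 0, strict = TRUE)
  if (!n_ap %in% c(1L, 2L)) stop("'n_ap' must be 1 or 2", call. = FALSE)
  scale <- 32980 * concentration * path_length * n_ap
  cd_spectrum(spectrum$wavelength, spectrum$value / scale,
              sd = if (!is.null(spectrum$sd)) spectrum$sd / scale,
              units = "delta_epsilon_per_ap", n_scans = spectrum$n_scans,
              metadata = spectrum$metadata)
}

#' Exciton-peak amplitude at a target wavelength
#'
#' Reads the spectrum at the 325 nm exciton peak (linear interpolation when
#' the target falls between grid points).  The peak is read at a fixed
#' wavelength, not searched for, because the titration statistic is defined
#' at 325 nm.
#'
#' @param spectrum A [cd_spectrum].
#' @param target_wavelength Target (nm), default 325.
#' @return Amplitude at the target wavelength (spectrum units).
#' @export
peak_amplitude <- function(spectrum, target_wavelength = 325) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  wl <- spectrum$wavelength
  if (target_wavelength < min(wl) || target_wavelength > max(wl)) {
    stop(sprintf("target wavelength %.1f nm outside grid [%.1f, %.1f]",
                 target_wavelength, min(wl), max(wl)), call. = FALSE)
  }
  stats::approx(wl, spectrum$value, xout = target_wavelength)$y
}

#' CD titration profile at the exciton peak
#'
#' Summarizes peak amplitude versus gp32 loading: the plateau is the mean
#' amplitude over post-saturation ratios (`ratio >= saturation_ratio`) and
#' the initial slope is the OLS slope over the `0` to `slope_window`
#' monomers-per-lattice window.
#'
#' @param ratios Monomers-per-lattice ratios (sorted, including 0).
#' @param amplitudes Peak amplitude at each ratio (e.g. from
#'   [peak_amplitude()] of averaged spectra).
#' @param saturation_ratio Saturating monomers per lattice (capacity).
#' @param slope_window Upper edge of the initial-slope window (default 2).
#' @return An object of class `cd_titration_profile`: `ratios`,
#'   `amplitudes`, `plateau`, `initial_slope`.
#' @export
titration_profile <- function(ratios, amplitudes, saturation_ratio,
                              slope_window = 2) {
  if (length(ratios) != length(amplitudes) || length(ratios) < 3L) {
    stop("need >= 3 (ratio, amplitude) pairs", call. = FALSE)
  }
  if (is.unsorted(ratios) || ratios[1L] != 0) {
    stop("'ratios' must be sorted and include 0", call. = FALSE)
  }
  post <- ratios >= saturation_ratio
  if (!any(post)) {
    stop("no post-saturation points (ratio >= saturation_ratio)",
         call. = FALSE)
  }
  win <- ratios <= slope_window
  slope <- if (sum(win) >= 2L) {
    unname(fit_line(ratios[win], amplitudes[win])["slope"])
  } else NA_real_
  structure(
    list(ratios = ratios, amplitudes = amplitudes,
         plateau = mean(amplitudes[post]), initial_slope = slope),
    class = "cd_titration_profile"
  )
}

#' @export
print.cd_titration_profile <- function(x, ...) {
  cat(sprintf(
    "<cd_titration_profile> %d ratios; plateau %.3f, initial slope %.3f per ratio\n",
    length(x$ratios), x$plateau, x$initial_slope
  ))
  invisible(x)
}
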