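# Maps from lattice occupancy to the three measured observables.
#
# All three maps are affine two-state (or three-state, for quenching) mixtures
# between their free- and bound-lattice endpoint values.  The endpoint values
# are the quantities this kind of footprinting experiment actually reports;
# no functional form beyond monotone mixing is assumed.

#' Per-position fluorescence enhancement parameters
#'
#' Saturated 2-AP fluorescence enhancement ratio `R_p = F_P/F_0` per probe
#' position.  gp32 binding unstacks the probe from its neighbours and
#' enhances its emission, so `R_p >= 1`; on 21-mer oligo(dT) lattices the
#' 5'-proximal positions 7-10 saturate near 4.5 and the 3'-proximal
#' positions 11-14 at or below 4.0.
#'
#' @param positions Integer vector of probe positions.
#' @param R Enhancement ratios, recycled to `positions`; defaults to 4.5 for
#'   positions <= 10 and 4.0 otherwise.
#' @param F0 Baseline intensity in instrument counts (arbitrary).
#' @return An object of class `fluor_params`: named vector `R` and scalar
#'   `F0`.
#' @export
fluor_params <- function(positions = 7:14,
                         R = ifelse(positions <= 10, 4.5, 4.0),
                         F0 = 1e5) {
  R <- rep_len(R, length(positions))
  if (any(R < 1)) stop("enhancement ratios must be >= 1", call. = FALSE)
  stopifnot_scalar_number(F0, "F0", lower = 0, strict = TRUE)
  structure(list(R = stats::setNames(R, positions), F0 = F0),
            class = "fluor_params")
}

#' Fluorescence enhancement at partial coverage
#'
#' Affine two-state mixture: `F/F_0 = 1 + (R_p - 1) * theta_p`, equal to 1 on
#' the free lattice and to `R_p` at full coverage.
#'
#' @param theta_p Coverage of the probe position, in `[0, 1]`.
#' @param R_p Saturated enhancement ratio for that position.
#' @return Relative intensity `F/F_0`.
#' @examples
#' fluorescence_signal(1, 4.5) # 4.5
#' fluorescence_signal(0.5, 4) # 2.5
#' @export
fluorescence_signal <- function(theta_p, R_p) {
  if (any(theta_p < 0 | theta_p > 1)) {
    stop("'theta_p' must lie in [0, 1]", call. = FALSE)
  }
  1 + (R_p - 1) * theta_p
}

#' Per-position acrylamide quenching parameters
#'
#' Stern-Volmer constants for the three probe environments entering
#' [ksv_signal()]: `K_free` on the protein-free lattice (position
#' independent, about 3.5 /M for 2-AP in oligo(dT)), `K_bound` under stable
#' saturated coverage (minimum near the middle of the central binding site,
#' where the cleft shields the probe), and `K_transient` under dynamically
#' exchanging partial coverage (elevated near the binding-site edges, where
#' rapid association/dissociation transiently unstacks the probe and
#' increases solvent access).
#'
#' @param positions Probe positions (defaults 7-14 on the 21-mer).
#' @param K_free Free-lattice constant (1/M).
#' @param K_bound Stable-coverage constants (1/M), recycled.
#' @param K_transient Transient-coverage constants (1/M), recycled.
#' @return An object of class `quench_params`.
#' @export
quench_params <- function(positions = 7:14, K_free = 3.5,
                          K_bound = c(2.6, 2.0, 1.5, 1.7, 2.0, 2.4, 2.7, 3.0),
                          K_transient = c(6.0, 5.0, 3.5, 3.5, 4.5, 5.0, 5.5, 6.0)) {
  K_bound <- rep_len(K_bound, length(positions))
  K_transient <- rep_len(K_transient, length(positions))
  if (K_free < 0 || any(K_bound < 0) || any(K_transient < 0)) {
    stop("quenching constants must be non-negative", call. = FALSE)
  }
  structure(
    list(positions = as.integer(positions), K_free = K_free,
         K_bound = stats::setNames(K_bound, positions),
         K_transient = stats::setNames(K_transient, positions)),
    class = "quench_params"
  )
}

#' Stern-Volmer constant at partial coverage
#'
#' Three-state mixture over the probe's environments: free lattice
#' (`1 - theta_p`), stably covered (`theta_p - transient_fraction`) and
#' transiently/dynamically covered (`transient_fraction`):
#' `K_SV = K_free*(1 - theta) + K_bound*(theta - f_t) + K_transient*f_t`.
#' Reduces to `K_free` on the bare lattice and to `K_bound` under full
#' stable coverage; an elevated `K_transient` reproduces the sub-saturation
#' increase in probe exposure seen with rapidly exchanging ligands.
#'
#' @param theta_p Probe coverage in `[0, 1]`.
#' @param transient_fraction Dynamically exchanging share of the coverage,
#'   `0 <= transient_fraction <= theta_p`.
#' @param K_free,K_bound_p,K_transient_p Constants (1/M) for the three states.
#' @return Stern-Volmer constant (1/M).
#' @examples
#' ksv_signal(0, 0, 3.5, 1.6, 5.0)          # 3.5
#' ksv_signal(0.25, 0.25, 3.5, 1.6, 5.0)    # 3.875
#' @export
ksv_signal <- function(theta_p, transient_fraction, K_free, K_bound_p,
                       K_transient_p) {
  if (any(theta_p < 0 | theta_p > 1) ||
      any(transient_fraction < 0 | transient_fraction > 1)) {
    stop("coverages must lie in [0, 1]", call. = FALSE)
  }
  if (any(transient_fraction > theta_p + 1e-12)) {
    stop("'transient_fraction' cannot exceed 'theta_p'", call. = FALSE)
  }
  K_free * (1 - theta_p) + K_bound_p * (theta_p - transient_fraction) +
    K_transient_p * transient_fraction
}

#' CD exciton-band parameters for a dimer probe
#'
#' The 2-AP dimer probe shows an exciton-coupling CD band peaking near
#' 325 nm whose amplitude reports base-base stacking of the pair.
#' `amplitude_free` is the per-2-AP amplitude of the protein-free construct;
#' `amplitude_sat` the residual plateau at binding saturation (about 0.2 for
#' 5'-proximal dimer probes, about 0.5 for the 3'-proximal 28-mer probe,
#' where some stacking chirality is retained).
#'
#' @param peak_wavelength Band centre (nm), default 325.
#' @param band_width Gaussian band sigma (nm).
#' @param amplitude_free Free-construct amplitude, Delta-epsilon per 2-AP
#'   (1/(M cm)).
#' @param amplitude_sat Saturated plateau amplitude (same units), must not
#'   exceed `amplitude_free`.
#' @return An object of class `cd_params`.
#' @export
cd_params <- function(peak_wavelength = 325, band_width = 12,
                      amplitude_free = 2.0, amplitude_sat = 0.2) {
  if (amplitude_sat > amplitude_free) {
    stop("'amplitude_sat' must not exceed 'amplitude_free'", call. = FALSE)
  }
  stopifnot_scalar_number(band_width, "band_width", lower = 0, strict = TRUE)
  structure(
    list(peak_wavelength = peak_wavelength, band_width = band_width,
         amplitude_free = amplitude_free, amplitude_sat = amplitude_sat),
    class = "cd_params"
  )
}

#' CD exciton amplitude at partial stacking
#'
#' Affine mixture between the saturated and free endpoint amplitudes:
#' `amplitude = amplitude_sat + (amplitude_free - amplitude_sat) *
#' stacked_fraction`; monotone non-decreasing in the stacked fraction.
#'
#' @param stacked_fraction Fraction of constructs whose dimer probe is still
#'   stacked, in `[0, 1]`.
#' @param params A [cd_params].
#' @return Delta-epsilon per 2-AP (1/(M cm)).
#' @export
cd_amplitude <- function(stacked_fraction, params) {
  stopifnot(inherits(params, "cd_params"))
  if (any(stacked_fraction < 0 | stacked_fraction > 1)) {
    stop("'stacked_fraction' must lie in [0, 1]", call. = FALSE)
  }
  params$amplitude_sat +
    (params$amplitude_free - params$amplitude_sat) * stacked_fraction
}

#' ssDNA rise geometry
#'
#' Average axial rise per nucleotide of the free (largely B-form-stacked,
#' about 3.4 Angstrom/nt) and protein-saturated (extended, about 4.6
#' Angstrom/nt) ssDNA lattice.
#'
#' @param rise_free Free-lattice rise (Angstrom/nt).
#' @param rise_saturated Saturated-lattice rise (Angstrom/nt); must be at
#'   least `rise_free`.
#' @return An object of class `geometry_constants`.
#' @export
geometry_constants <- function(rise_free = 3.4, rise_saturated = 4.6) {
  if (rise_saturated < rise_free) {
    stop("'rise_saturated' must be >= 'rise_free'", call. = FALSE)
  }
  structure(list(rise_free = rise_free, rise_saturated = rise_saturated),
            class = "geometry_constants")
}

#' Increase in dimer-probe base separation at saturation
#'
#' The separation increase of the two bases of an adjacent dimer probe upon
#' lattice extension is the difference of the per-nucleotide rises,
#' `rise_saturated - rise_free` (1.2 Angstrom for the default 4.6 vs 3.4),
#' which falls in the 1-2 Angstrom window expected for loss of exciton
#' coupling.
#'
#' @param geometry A [geometry_constants].
#' @return Separation increase (Angstrom).
#' @examples
#' dimer_separation_increase(geometry_constants()) # 1.2
#' @export
dimer_separation_increase <- function(geometry = geometry_constants()) {
  stopifnot(inherits(geometry, "geometry_constants"))
  geometry$rise_saturated - geometry$rise_free
}
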