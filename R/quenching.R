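# Stern-Volmer analysis of acrylamide quench series.
#
# The working statistic is the slope of F_0/F versus quencher concentration
# obtained by ordinary least squares with a freely fitted intercept; the
# slope is reported as K_SV (an intercept far from 1 is a QC flag for
# static-quenching deviations, not an error).

#' Stern-Volmer series container
#'
#' @param quencher_conc Dilution-corrected quencher concentrations (M),
#'   strictly increasing from 0.
#' @param intensity Fluorescence at each quencher concentration
#'   (dilution-corrected).
#' @param construct,position Optional labels.
#' @return An object of class `stern_volmer_series` with fields
#'   `quencher_conc`, `intensity`, `F_0` (zero-quencher intensity) and
#'   `ratio` (`F_0/F` per point).
#' @export
stern_volmer_series <- function(quencher_conc, intensity,
                                construct = NA_character_,
                                position = NA_integer_) {
  if (length(quencher_conc) != length(intensity)) {
    stop("lengths of 'quencher_conc' and 'intensity' differ", call. = FALSE)
  }
  if (quencher_conc[1L] != 0 || any(diff(quencher_conc) <= 0)) {
    stop("'quencher_conc' must increase strictly from 0", call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  F0 <- intensity[1L]
  structure(
    list(quencher_conc = quencher_conc, intensity = intensity, F_0 = F0,
         ratio = F0 / intensity, construct = construct, position = position),
    class = "stern_volmer_series"
  )
}

#' Fit the Stern-Volmer quenching constant
#'
#' OLS regression of `F_0/F` on `[Q]`; the slope is the apparent quenching
#' constant `K_SV` (1/M) and the intercept is fitted freely (near 1 for
#' well-behaved collisional quenching).  Exact on noiseless linear data and
#' invariant under uniform rescaling of the raw fluorescence.
#'
#' @param series A [stern_volmer_series] with at least 3 points including
#'   `[Q] = 0`.
#' @return An object of class `stern_volmer_fit`: `K_SV`, `intercept`,
#'   `K_SV_se`, `r_squared`, `n_points`, plus the series labels.
#' @export
fit_stern_volmer <- function(series) {
  stopifnot(inherits(series, "stern_volmer_series"))
  q <- series$quencher_conc
  y <- series$ratio
  if (length(q) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(q) == 0) stop("zero variance in quencher_conc", call. = FALSE)
  fit <- stats::lm(y ~ q)
  # summary.lm warns on numerically perfect fits, which are legitimate here
  sm <- suppressWarnings(summary(fit))
  ksv <- unname(stats::coef(fit)[2L])
  if (ksv < 0) {
    warning("negative Stern-Volmer slope fitted; flagging, not truncating",
            call. = FALSE)
  }
  structure(
    list(K_SV = ksv,
         intercept = unname(stats::coef(fit)[1L]),
         K_SV_se = unname(sm$coefficients[2L, 2L]),
         r_squared = sm$r.squared,
         n_points = length(q),
         construct = series$construct, position = series$position),
    class = "stern_volmer_fit"
  )
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> K_SV = %.3f /M (se %.3f), intercept %.3f, R2 %.4f, n = %d\n",
    x$K_SV, x$K_SV_se, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Half-quench concentration
#'
#' The reciprocal of the quenching constant, `1/K_SV`: the quencher
#' concentration at which `F_0/F = 2`, i.e. half of the initial fluorescence
#' has been quenched.
#'
#' @param fit A [fit_stern_volmer()] result (or a positive scalar `K_SV`).
#' @return Molarity.
#' @examples
#' half_quench_concentration(3.5) # 0.2857 M
#' @export
half_quench_concentration <- function(fit) {
  ksv <- if (inherits(fit, "stern_volmer_fit")) fit$K_SV else fit
  stopifnot_scalar_number(ksv, "K_SV")
  if (ksv <= 0) {
    stop("half-quench concentration undefined for non-positive K_SV",
         call. = FALSE)
  }
  1 / ksv
}

#' Position-by-ratio K_SV summary surface
#'
#' Assembles fitted quenching constants keyed by probe position and gp32
#' loading into the summary used to read the footprint: the position-by-ratio
#' `K_SV` matrix, per-ratio means, the no-protein reference mean, and the
#' position of each per-ratio minimum (ties resolved to the lowest position
#' index).  Missing cells are reported, never imputed.
#'
#' @param fits A data.frame with columns `position`, `ratio`, `K_SV`
#'   (e.g. from rows of [fit_stern_volmer()] results).
#' @return An object of class `ksv_surface`: `matrix` (positions x ratios),
#'   `per_ratio_mean`, `reference_mean` (`NA` if no zero-protein column),
#'   `min_position` (named by ratio), `missing_cells` (data.frame).
#' @export
ksv_surface <- function(fits) {
  req <- c("position", "ratio", "K_SV")
  if (!all(req %in% names(fits))) {
    stop("'fits' needs columns position, ratio, K_SV", call. = FALSE)
  }
  positions <- sort(unique(fits$position))
  ratios <- sort(unique(fits$ratio))
  mat <- matrix(NA_real_, nrow = length(positions), ncol = length(ratios),
                dimnames = list(position = positions, ratio = ratios))
  agg <- stats::aggregate(K_SV ~ position + ratio, data = fits, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    mat[as.character(agg$position[i]), as.character(agg$ratio[i])] <-
      agg$K_SV[i]
  }
  miss <- which(is.na(mat), arr.ind = TRUE)
  missing_cells <- data.frame(
    position = positions[miss[, 1L]], ratio = ratios[miss[, 2L]]
  )
  per_ratio_mean <- colMeans(mat, na.rm = TRUE)
  min_position <- apply(mat, 2L, function(col) {
    if (all(is.na(col))) return(NA_integer_)
    positions[which.min(col)] # which.min takes the first (lowest) index on ties
  })
  reference_mean <- if ("0" %in% colnames(mat)) {
    mean(mat[, "0"], na.rm = TRUE)
  } else NA_real_
  structure(
    list(matrix = mat, per_ratio_mean = per_ratio_mean,
         reference_mean = reference_mean, min_position = min_position,
         missing_cells = missing_cells),
    class = "ksv_surface"
  )
}

#' @export
print.ksv_surface <- function(x, ...) {
  cat(sprintf("<ksv_surface> %d positions x %d ratios; no-protein mean %.3f /M\n",
              nrow(x$matrix), ncol(x$matrix), x$reference_mean))
  print(round(x$matrix, 3))
  if (nrow(x$missing_cells)) {
    cat("missing cells:\n")
    print(x$missing_cells)
  }
  invisible(x)
}

#' Dilution-correct a raw quench series
#'
#' Applies the stock-addition volume correction `V_i/V_0` to raw counts so
#' that the Stern-Volmer ratio reflects quenching alone, then builds a
#' [stern_volmer_series].  Quencher concentrations are expected to already
#' be dilution-corrected (true molarities in the cuvette).
#'
#' @param points Data.frame with columns `quencher_conc`, `volume`, `counts`.
#' @param initial_volume `V_0`; default `min(points$volume)`.
#' @param construct,position Labels forwarded to the series.
#' @return A [stern_volmer_series].
#' @export
correct_quench_series <- function(points, initial_volume = NULL,
                                  construct = NA_character_,
                                  position = NA_integer_) {
  req <- c("quencher_conc", "volume", "counts")
  if (!all(req %in% names(points))) {
    stop("'points' needs columns quencher_conc, volume, counts", call. = FALSE)
  }
  V0 <- initial_volume %||% min(points$volume)
  stern_volmer_series(points$quencher_conc,
                      points$counts * points$volume / V0,
                      construct = construct, position = position)
}
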