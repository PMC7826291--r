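# Fluorescence-titration analysis: background/dilution correction,
# normalization, equivalence-point stoichiometry by first-six/last-six
# linear extrapolation, enhancement-ratio (F_P/F_0) mapping, and an
# optional inverse fit of the lattice binding model.

#' Titration series container
#'
#' Holds one corrected titration: strictly increasing monomers-per-lattice
#' ratios, corrected 370 nm intensities, the zero-protein intensity `F_0`,
#' the titration maximum `F_max` and `F/F_max`-normalized values.
#'
#' @param ratio Monomers-per-lattice ratios (strictly increasing, starting
#'   at 0).
#' @param intensity Corrected fluorescence intensities.
#' @param construct Optional construct label.
#' @param replicate Optional replicate index.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(ratio, intensity, construct = NA_character_,
                             replicate = NA_integer_) {
  if (length(ratio) != length(intensity) || !length(ratio)) {
    stop("'ratio' and 'intensity' must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(diff(ratio) <= 0)) {
    stop("'ratio' must be strictly increasing", call. = FALSE)
  }
  F0 <- intensity[which.min(ratio)]
  if (!is.finite(F0) || F0 <= 0) {
    stop("zero-protein intensity F_0 must be positive", call. = FALSE)
  }
  Fmax <- max(intensity)
  structure(
    list(ratio = ratio, intensity = intensity, F_0 = F0, F_max = Fmax,
         normalized = intensity / Fmax, construct = construct,
         replicate = replicate),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %s rep %s: %d points, ratio %.3g-%.3g, F_P/F_0 span %.3g\n",
    x$construct, x$replicate, length(x$ratio), min(x$ratio), max(x$ratio),
    x$F_max / x$F_0
  ))
  invisible(x)
}

#' Background and dilution correction of a raw titration
#'
#' Subtracts the (ratio-interpolated) unlabeled-construct background from
#' the raw counts, then undoes the stock-addition dilution by multiplying
#' each intensity by its cumulative volume factor `V_i / V_0`.  Ratios are
#' mole ratios (added ligand per lattice) and are therefore unchanged by
#' dilution.
#'
#' @param points A data.frame with columns `ratio`, `volume`, `counts` for
#'   one titration (one construct, one replicate).
#' @param background Optional data.frame with columns `ratio`, `counts`
#'   (background series of the matching unlabeled construct); must cover
#'   the ratio range of `points`.
#' @param initial_volume Starting volume `V_0` (same units as `volume`);
#'   default `min(points$volume)`.
#' @param construct,replicate Labels forwarded to the result.
#' @return A [titration_series].
#' @export
correct_series <- function(points, background = NULL, initial_volume = NULL,
                           construct = NA_character_,
                           replicate = NA_integer_) {
  req <- c("ratio", "volume", "counts")
  if (!all(req %in% names(points))) {
    stop("'points' needs columns ratio, volume, counts", call. = FALSE)
  }
  if (any(diff(points$volume) < 0)) {
    stop("'volume' must be non-decreasing along the titration", call. = FALSE)
  }
  counts <- points$counts
  if (!is.null(background)) {
    if (min(points$ratio) < min(background$ratio) - 1e-9 ||
        max(points$ratio) > max(background$ratio) + 1e-9) {
      stop("background series does not cover the titration ratio range",
           call. = FALSE)
    }
    bg <- stats::approx(background$ratio, background$counts,
                        xout = points$ratio, rule = 2)$y
    counts <- counts - bg
  }
  V0 <- initial_volume %||% min(points$volume)
  counts <- counts * points$volume / V0
  titration_series(points$ratio, counts, construct = construct,
                   replicate = replicate)
}

fit_line <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  c(intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L]))
}

#' Equivalence-point stoichiometry by two-line intersection
#'
#' Ordinary least-squares lines are fitted through the first `n_head`
#' (rising phase) and last `n_tail` (plateau) titration points; the abscissa
#' of their intersection is the equivalence-point stoichiometry in added
#' monomers per lattice.  With a list of replicate series, per-replicate
#' intersections are computed first and then aggregated (mean and standard
#' deviation), matching the convention of estimating uncertainty from
#' replicate equivalence points.
#'
#' @param series A [titration_series] or a list of them.
#' @param n_head,n_tail Number of points in the rising / plateau fits
#'   (default 6 and 6).
#' @param slope_tol Near-parallel guard: error when the slope difference is
#'   below `slope_tol * max(|slopes|)`.
#' @return An object of class `equivalence_point_result`: `stoichiometry`,
#'   `slope_line`, `plateau_line`, `uncertainty` (replicate sd, `NA` for a
#'   single series), `per_series` (numeric vector of per-replicate
#'   estimates).
#' @export
equivalence_point <- function(series, n_head = 6L, n_tail = 6L,
                              slope_tol = 1e-6) {
  if (inherits(series, "titration_series")) series <- list(series)
  if (!length(series) ||
      !all(vapply(series, inherits, logical(1), "titration_series"))) {
    stop("'series' must be one or more titration_series", call. = FALSE)
  }
  one <- function(s) {
    np <- length(s$ratio)
    if (np < n_head + n_tail) {
      stop(sprintf("need at least %d points, got %d", n_head + n_tail, np),
           call. = FALSE)
    }
    head_idx <- seq_len(n_head)
    tail_idx <- seq.int(np - n_tail + 1L, np)
    l1 <- fit_line(s$ratio[head_idx], s$intensity[head_idx])
    l2 <- fit_line(s$ratio[tail_idx], s$intensity[tail_idx])
    dslope <- l1["slope"] - l2["slope"]
    if (abs(dslope) < slope_tol * max(abs(l1["slope"]), abs(l2["slope"]))) {
      stop("rising and plateau lines are near-parallel; no equivalence point",
           call. = FALSE)
    }
    list(x = unname((l2["intercept"] - l1["intercept"]) / dslope),
         slope_line = l1, plateau_line = l2)
  }
  fits <- lapply(series, one)
  xs <- vapply(fits, `[[`, numeric(1), "x")
  structure(
    list(stoichiometry = mean(xs),
         slope_line = fits[[1L]]$slope_line,
         plateau_line = fits[[1L]]$plateau_line,
         uncertainty = if (length(xs) > 1L) stats::sd(xs) else NA_real_,
         per_series = xs),
    class = "equivalence_point_result"
  )
}

#' @export
print.equivalence_point_result <- function(x, ...) {
  cat(sprintf("<equivalence_point> %.3f monomers/lattice (sd %.3f, n = %d)\n",
              x$stoichiometry,
              ifelse(is.na(x$uncertainty), 0, x$uncertainty),
              length(x$per_series)))
  invisible(x)
}

#' Fluorescence enhancement ratio F_P/F_0
#'
#' The plateau intensity `F_P` is the mean corrected intensity over all
#' points at or beyond `oversat_factor` times the stoichiometric capacity
#' (default 1.5x, i.e. well past the equivalence point), and the
#' enhancement ratio is `F_P / F_0`.  Invariant under uniform rescaling of
#' all intensities.
#'
#' @param series A [titration_series] including the zero-protein point.
#' @param stoichiometry Saturating monomers per lattice (e.g. `floor(N/n)`
#'   or a measured equivalence point).
#' @param oversat_factor Over-saturation threshold multiplier.
#' @param min_points Minimum number of plateau points required.
#' @return `F_P / F_0` (dimensionless).
#' @export
enhancement_ratio <- function(series, stoichiometry, oversat_factor = 1.5,
                              min_points = 3L) {
  stopifnot(inherits(series, "titration_series"))
  sel <- series$ratio >= oversat_factor * stoichiometry
  if (sum(sel) < min_points) {
    stop(sprintf("need >= %d over-saturation points (ratio >= %.3g), got %d",
                 min_points, oversat_factor * stoichiometry, sum(sel)),
         call. = FALSE)
  }
  mean(series$intensity[sel]) / series$F_0
}

#' Inverse fit of the lattice binding model to titration data
#'
#' Least-squares fit of the normalized model curve
#' `F/F_max = (1 + (R - 1) * theta_p(ratio)) / max(...)` to one or more
#' corrected titration series, over `log K_a`, `log omega`, the apparent
#' competent lattice fraction, and the saturated enhancement ratio `R`.
#' Under stoichiometric (very strong) binding the curve shape carries no
#' information on `K_a` and `omega` separately; the fit then flags `K_a` as
#' a lower bound only instead of pretending to identify it.
#'
#' @param series A [titration_series] or list of them (shared construct).
#' @param construct A [lattice_construct] with a probe.
#' @param lattice_conc Nominal lattice concentration (M).
#' @param params_init A [ligand_params] giving starting values.
#' @param active_init,R_init Starting values for the competent fraction and
#'   enhancement ratio.
#' @param fix_active,fix_R Fix the competent fraction / enhancement ratio at
#'   their starting values instead of fitting them (removes two directions
#'   of the `K_a`-`omega` ridge when they are known).
#' @param maxit Optimizer iteration budget.
#' @param stoichiometric_threshold Flag threshold on
#'   `K_a * omega^x * lattice_conc` above which the binding is treated as
#'   titrating stoichiometrically.
#' @return An object of class `binding_model_fit`: `estimates` (named list
#'   `K_a`, `omega`, `active_fraction`, `R`), `residual_norm`,
#'   `identifiable` (logical), `warnings` (character), `convergence`.
#' @export
fit_binding_model <- function(series, construct, lattice_conc,
                              params_init = ligand_params(K_a = 1e6, omega = 100),
                              active_init = 0.95, R_init = 4.2,
                              fix_active = FALSE, fix_R = FALSE,
                              maxit = 400L,
                              stoichiometric_threshold = 100) {
  if (inherits(series, "titration_series")) series <- list(series)
  if (!length(series)) stop("empty series", call. = FALSE)
  stopifnot(inherits(construct, "lattice_construct"),
            inherits(params_init, "ligand_params"))
  n <- params_init$site_size_n

  predict_norm <- function(ratios, K_a, omega, active, R) {
    p <- ligand_params(n, K_a, omega)
    th <- vapply(ratios, function(r) {
      sol <- solve_mass_balance(r * lattice_conc, active * lattice_conc,
                                construct$length_nt, p)
      probe_coverage(sol$profile, construct)
    }, numeric(1))
    sig <- 1 + (R - 1) * th
    sig / max(sig)
  }
  unpack <- function(par) {
    i <- 2L
    active <- if (fix_active) active_init else {
      i <- i + 1L
      stats::plogis(par[i])
    }
    R <- if (fix_R) R_init else {
      i <- i + 1L
      1 + exp(par[i])
    }
    list(K_a = exp(par[1L]), omega = exp(par[2L]), active = active, R = R)
  }
  obj <- function(par) {
    th <- unpack(par)
    sse <- 0
    for (s in series) {
      pred <- predict_norm(s$ratio, th$K_a, th$omega, th$active, th$R)
      sse <- sse + sum((s$normalized - pred)^2)
    }
    sse
  }
  par0 <- c(log(params_init$K_a), log(params_init$omega))
  if (!fix_active) par0 <- c(par0, stats::qlogis(active_init))
  if (!fix_R) par0 <- c(par0, log(R_init - 1))
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0) {
    warning("binding-model fit did not fully converge (code ",
            opt$convergence, ")", call. = FALSE)
  }
  th <- unpack(opt$par)
  est <- list(K_a = th$K_a, omega = th$omega,
              active_fraction = th$active, R = th$R)
  x <- saturated_exponent(construct$length_nt, n)
  keff <- est$K_a * est$omega^x * lattice_conc
  warns <- character(0)
  identifiable <- TRUE
  if (keff > stoichiometric_threshold) {
    identifiable <- FALSE
    warns <- c(warns, sprintf(
      "stoichiometric regime (K_a*omega^%.2f*conc = %.3g): K_a is a lower bound only",
      x, keff))
  }
  structure(
    list(estimates = est, residual_norm = sqrt(opt$value),
         identifiable = identifiable, warnings = warns,
         convergence = opt$convergence),
    class = "binding_model_fit"
  )
}

#' @export
print.binding_model_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_model_fit> K_a = %.3g /M, omega = %.3g, active = %.3f, R = %.2f (rss %.3g)\n",
    x$estimates$K_a, x$estimates$omega, x$estimates$active_fraction,
    x$estimates$R, x$residual_norm^2
  ))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
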