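# Exact equilibrium statistics of nonoverlapping, cooperatively interacting
# ligands of site size n on a finite one-dimensional lattice of N residues.
#
# The model is the standard nearest-neighbour large-ligand lattice model: a
# configuration with m bound ligands and j abutting ligand-ligand interfaces
# has statistical weight (K_a * L)^m * omega^j relative to the empty lattice,
# where L is the free ligand concentration, K_a the intrinsic association
# constant and omega the cooperativity parameter.  Everything here is computed
# two ways: a two-state transfer recursion (production route, works at any N)
# and a brute-force enumeration of all configurations (oracle route, small N).

#' Ligand binding parameters
#'
#' Bundle of the three thermodynamic parameters of the large-ligand lattice
#' model: the occluded site size `site_size_n` (nucleotides covered per bound
#' ligand; 7 for cooperatively bound gp32 monomers), the intrinsic association
#' constant `K_a` (per molar free ligand) and the nearest-neighbour
#' cooperativity parameter `omega` (dimensionless; 1 = non-cooperative).
#'
#' @param site_size_n Positive integer, nucleotides occluded per ligand.
#' @param K_a Intrinsic association constant (1/M), strictly positive.
#' @param omega Cooperativity parameter, non-negative (`omega = 0` forbids
#'   abutting ligands entirely).
#' @return An object of class `ligand_params`.
#' Default `K_a` and `omega` are placeholders deep in the stoichiometric,
#' all-or-none regime observed for gp32 on short lattices at low salt; they
#' set the regime, not measured thermodynamics.
#'
#' @examples
#' ligand_params(K_a = 1e8, omega = 1e6)
#' @export
ligand_params <- function(site_size_n = 7L, K_a = 1e8, omega = 1e6) {
  site_size_n <- as.integer(site_size_n)
  if (is.na(site_size_n) || site_size_n < 1L) {
    stop("'site_size_n' must be a positive integer", call. = FALSE)
  }
  stopifnot_scalar_number(K_a, "K_a", lower = 0, strict = TRUE)
  stopifnot_scalar_number(omega, "omega", lower = 0)
  structure(
    list(site_size_n = site_size_n, K_a = K_a, omega = omega),
    class = "ligand_params"
  )
}

#' @export
print.ligand_params <- function(x, ...) {
  cat(sprintf(
    "<ligand_params> n = %d nt, K_a = %.3g /M, omega = %.3g\n",
    x$site_size_n, x$K_a, x$omega
  ))
  invisible(x)
}

#' ssDNA lattice construct
#'
#' A finite ssDNA lattice of `length_nt` residues with optional 2-AP probe(s).
#' Positions are 1-based and counted from the 5' end.  Dimer probes must
#' occupy two adjacent positions.
#'
#' @param length_nt Lattice length in nucleotides.
#' @param probe_positions Integer vector of probe positions (1-based from the
#'   5' end); empty for an unlabeled control.
#' @param probe_kind One of `"monomer"`, `"dimer"`, `"none"`. Inferred from
#'   `probe_positions` when missing.
#' @param name Optional construct label, e.g. `"21T9"` or `"28T22,23"`.
#' @return An object of class `lattice_construct`.
#' @examples
#' lattice_construct(21, 9)
#' lattice_construct(28, c(22, 23))
#' @export
lattice_construct <- function(length_nt, probe_positions = integer(0),
                              probe_kind = NULL, name = NULL) {
  length_nt <- as.integer(length_nt)
  if (is.na(length_nt) || length_nt < 1L) {
    stop("'length_nt' must be a positive integer", call. = FALSE)
  }
  probe_positions <- as.integer(probe_positions)
  if (any(is.na(probe_positions)) ||
      any(probe_positions < 1L | probe_positions > length_nt)) {
    stop("probe positions must lie in [1, length_nt]", call. = FALSE)
  }
  probe_positions <- sort(probe_positions)
  if (is.null(probe_kind)) {
    probe_kind <- switch(as.character(length(probe_positions)),
      "0" = "none", "1" = "monomer", "2" = "dimer",
      stop("at most two probe positions are supported", call. = FALSE)
    )
  }
  probe_kind <- match.arg(probe_kind, c("monomer", "dimer", "none"))
  if (probe_kind == "dimer") {
    if (length(probe_positions) != 2L || diff(probe_positions) != 1L) {
      stop("a dimer probe must occupy two adjacent positions", call. = FALSE)
    }
  }
  if (probe_kind == "monomer" && length(probe_positions) != 1L) {
    stop("a monomer probe needs exactly one position", call. = FALSE)
  }
  if (is.null(name)) name <- construct_name(length_nt, probe_positions)
  structure(
    list(length_nt = length_nt, probe_positions = probe_positions,
         probe_kind = probe_kind, name = name),
    class = "lattice_construct"
  )
}

#' @export
print.lattice_construct <- function(x, ...) {
  pos <- if (length(x$probe_positions)) {
    paste(x$probe_positions, collapse = ",")
  } else "none"
  cat(sprintf("<lattice_construct> %s: %d nt, %s probe at %s\n",
              x$name, x$length_nt, x$probe_kind, pos))
  invisible(x)
}

#' Maximum number of nonoverlapping bound ligands
#'
#' The saturating capacity of a finite lattice, `floor(length_nt /
#' site_size_n)`.  A 21-mer binds at most 3 ligands of site size 7; a 28-mer
#' binds 4.
#'
#' @param length_nt Lattice length (nt), non-negative.
#' @param site_size_n Ligand site size (nt), positive.
#' @return Non-negative integer.
#' @examples
#' count_saturating_ligands(21, 7) # 3
#' count_saturating_ligands(28, 7) # 4
#' @export
count_saturating_ligands <- function(length_nt, site_size_n) {
  stopifnot_scalar_number(length_nt, "length_nt", lower = 0)
  stopifnot_scalar_number(site_size_n, "site_size_n", lower = 0, strict = TRUE)
  as.integer(length_nt %/% site_size_n)
}

#' Binding configuration
#'
#' One placement of nonoverlapping ligands, recorded by their 5' start
#' positions.  `m` is the ligand count and `j` the number of abutting
#' ligand-ligand interfaces (adjacent ligands with zero gap), the quantity
#' multiplying `log(omega)` in the configuration weight.
#'
#' @param start_positions Sorted 1-based 5' starts of the bound ligands.
#' @param site_size_n Ligand site size (nt).
#' @param length_nt Lattice length (nt).
#' @return An object of class `binding_configuration` with fields
#'   `start_positions`, `m`, `j`.
#' @export
binding_configuration <- function(start_positions, site_size_n, length_nt) {
  start_positions <- sort(as.integer(start_positions))
  site_size_n <- as.integer(site_size_n)
  length_nt <- as.integer(length_nt)
  if (length(start_positions)) {
    ends <- start_positions + site_size_n - 1L
    if (start_positions[1L] < 1L || ends[length(ends)] > length_nt) {
      stop("ligand intervals must fit within the lattice", call. = FALSE)
    }
    if (length(start_positions) > 1L &&
        any(diff(start_positions) < site_size_n)) {
      stop("ligand intervals must not overlap", call. = FALSE)
    }
  }
  m <- length(start_positions)
  j <- if (m > 1L) sum(diff(start_positions) == site_size_n) else 0L
  structure(
    list(start_positions = start_positions, m = m, j = j,
         site_size_n = site_size_n, length_nt = length_nt),
    class = "binding_configuration"
  )
}

#' Enumerate all binding configurations (brute-force oracle)
#'
#' Generates every valid placement of 0 to `floor(N/n)` nonoverlapping
#' ligands on the lattice.  The number of configurations with exactly m
#' ligands is `choose(N - m*n + m, m)`.  This is the independent oracle
#' against which the transfer recursion is validated; it is capped at small
#' lattices because the configuration count grows combinatorially.
#'
#' @param length_nt Lattice length (nt).
#' @param site_size_n Ligand site size (nt).
#' @param cap Maximum lattice length accepted (default 40).
#' @return List of [binding_configuration] objects (the empty configuration
#'   first).
#' @examples
#' length(enumerate_configurations(7, 7)) # 2
#' @export
enumerate_configurations <- function(length_nt, site_size_n, cap = 40L) {
  length_nt <- as.integer(length_nt)
  site_size_n <- as.integer(site_size_n)
  if (is.na(site_size_n) || site_size_n < 1L) {
    stop("'site_size_n' must be a positive integer", call. = FALSE)
  }
  if (length_nt > cap) {
    stop(sprintf("length_nt = %d exceeds the enumeration cap (%d)",
                 length_nt, cap), call. = FALSE)
  }
  res <- list()
  last_start <- length_nt - site_size_n + 1L
  recurse <- function(prefix, next_start) {
    res[[length(res) + 1L]] <<- prefix
    if (next_start > last_start) return(invisible(NULL))
    for (s in next_start:last_start) {
      recurse(c(prefix, s), s + site_size_n)
    }
  }
  recurse(integer(0), 1L)
  lapply(res, binding_configuration,
         site_size_n = site_size_n, length_nt = length_nt)
}

#' Statistical weight of a binding configuration
#'
#' Returns `(K_a * L)^m * omega^j` where `m` is the ligand count and `j` the
#' abutting-interface count; the empty lattice is the reference state with
#' weight 1.  The fully saturated 21-mer (m = 3, j = 2) therefore carries
#' weight `(K_a*L)^3 * omega^2`, the origin of the finite-lattice reduction
#' of the effective per-ligand cooperativity.
#'
#' @param config A [binding_configuration].
#' @param params A [ligand_params].
#' @param free_ligand Free ligand concentration L (M), non-negative.
#' @param log Return the log weight instead?
#' @return Non-negative weight (or its log).
#' @export
configuration_weight <- function(config, params, free_ligand, log = FALSE) {
  stopifnot(inherits(config, "binding_configuration"),
            inherits(params, "ligand_params"))
  stopifnot_scalar_number(free_ligand, "free_ligand", lower = 0)
  # 0 * log(0) terms are taken as 0 (absent factors), not NaN
  lw <- 0
  if (config$m > 0L) {
    lw <- lw + config$m * (base::log(params$K_a) + base::log(free_ligand))
  }
  if (config$j > 0L) lw <- lw + config$j * base::log(params$omega)
  if (log) lw else exp(lw)
}

# Two-state transfer recursion in the log domain.
# lzf[p + 1]: log partition function of the first p residues with residue p
#             uncovered; lzb[p + 1]: with a ligand ending exactly at p.
# lzf(p) = lzf(p-1) + lzb(p-1);  lzb(p) = K*L * (lzf(p-n) + omega*lzb(p-n)).
lattice_recursion <- function(length_nt, site_size_n, log_kl, log_omega) {
  N <- length_nt
  n <- site_size_n
  lzf <- numeric(N + 1L)
  lzb <- rep(-Inf, N + 1L)
  if (N >= 1L) {
    # logsumexp inlined: this loop dominates mass-balance solves
    for (p in seq_len(N)) {
      a <- lzf[p]
      b <- lzb[p]
      lzf[p + 1L] <- if (b == -Inf) a
        else if (a >= b) a + log1p(exp(b - a))
        else b + log1p(exp(a - b))
      if (p >= n) {
        a <- lzf[p - n + 1L]
        b <- log_omega + lzb[p - n + 1L]
        s <- if (b == -Inf) a
          else if (a >= b) a + log1p(exp(b - a))
          else b + log1p(exp(a - b))
        lzb[p + 1L] <- log_kl + s
      }
    }
  }
  list(lzf = lzf, lzb = lzb)
}

#' Finite-lattice partition function
#'
#' Computes `Z(N) = sum over configurations of (K_a*L)^m * omega^j` by the
#' two-state transfer recursion, carried in the log domain so that strongly
#' bound or highly cooperative regimes cannot overflow.  Within the
#' enumeration cap the result equals the brute-force sum of
#' [configuration_weight()] over [enumerate_configurations()].
#'
#' @param length_nt Lattice length (nt), non-negative.
#' @param params A [ligand_params].
#' @param free_ligand Free ligand concentration L (M).
#' @param log Return `log(Z)`?
#' @return `Z` (or `log(Z)`); `Z = 1` at `L = 0`.
#' @examples
#' p <- ligand_params(site_size_n = 7, K_a = 1e6, omega = 1)
#' partition_function(7, p, 1e-6) # 1 + K_a * L = 2
#' @export
partition_function <- function(length_nt, params, free_ligand, log = FALSE) {
  stopifnot(inherits(params, "ligand_params"))
  stopifnot_scalar_number(length_nt, "length_nt", lower = 0)
  stopifnot_scalar_number(free_ligand, "free_ligand", lower = 0)
  log_kl <- base::log(params$K_a) + base::log(free_ligand)
  st <- lattice_recursion(as.integer(length_nt), params$site_size_n,
                          log_kl, base::log(params$omega))
  N <- as.integer(length_nt)
  lz <- logsumexp2(st$lzf[N + 1L], st$lzb[N + 1L])
  if (log) lz else exp(lz)
}

# Log probability that a ligand starts at each admissible position s,
# P(start = s) = K*L * (Zf(s-1) + w*Zb(s-1)) * (Zf(r) + w*Zb(r)) / Z(N)
# with r = N - s - n + 1 the length of the 3' remainder.  The suffix factors
# reuse the forward recursion because the homogeneous model is reversal
# symmetric.
start_log_probs <- function(length_nt, params, free_ligand) {
  N <- as.integer(length_nt)
  n <- params$site_size_n
  if (N < n) return(numeric(0))
  log_kl <- base::log(params$K_a) + base::log(free_ligand)
  log_w <- base::log(params$omega)
  st <- lattice_recursion(N, n, log_kl, log_w)
  logZ <- logsumexp2(st$lzf[N + 1L], st$lzb[N + 1L])
  s <- seq_len(N - n + 1L)
  left <- logsumexp2(st$lzf[s], log_w + st$lzb[s])
  r <- N - s - n + 1L
  right <- logsumexp2(st$lzf[r + 1L], log_w + st$lzb[r + 1L])
  log_kl + left + right - logZ
}

#' Per-position coverage and mean occupancy
#'
#' Computes the occupancy profile at free ligand concentration L: the
#' probability `theta_p` that each lattice position is covered by a bound
#' ligand, the expected number of bound ligands `mean_bound`, and the
#' saturation fraction `mean_bound / floor(N/n)`.  Two routes are provided:
#' the transfer recursion (production, any N) and configuration enumeration
#' (oracle, N below the cap); they agree to relative 1e-9.
#'
#' @param length_nt Lattice length (nt).
#' @param params A [ligand_params].
#' @param free_ligand Free ligand concentration (M).
#' @param method `"recursion"` (default) or `"enumeration"`.
#' @param cap Enumeration cap (nt), only used by the enumeration route.
#' @return An object of class `occupancy_profile` with fields `coverage`
#'   (numeric length N), `mean_bound`, `saturation_fraction`, `length_nt`,
#'   `site_size_n`.
#' @examples
#' p <- ligand_params(K_a = 1e7, omega = 1e3)
#' mean_bound_and_coverage(21, p, 1e-7)
#' @export
mean_bound_and_coverage <- function(length_nt, params, free_ligand,
                                    method = c("recursion", "enumeration"),
                                    cap = 40L) {
  stopifnot(inherits(params, "ligand_params"))
  stopifnot_scalar_number(free_ligand, "free_ligand", lower = 0)
  method <- match.arg(method)
  N <- as.integer(length_nt)
  n <- params$site_size_n
  capacity <- N %/% n
  if (method == "recursion") {
    ps <- exp(start_log_probs(N, params, free_ligand))
    coverage <- numeric(N)
    if (length(ps)) {
      # theta_p = sum of start probabilities over starts covering p
      cs <- cumsum(c(0, ps))
      hi <- pmin(seq_len(N), N - n + 1L)
      lo <- pmax(seq_len(N) - n + 1L, 1L)
      cover <- hi >= lo
      coverage[cover] <- cs[hi[cover] + 1L] - cs[lo[cover]]
    }
    mean_bound <- sum(ps)
  } else {
    configs <- enumerate_configurations(N, n, cap = cap)
    lw <- vapply(configs, configuration_weight, numeric(1),
                 params = params, free_ligand = free_ligand, log = TRUE)
    lw <- lw - max(lw)
    w <- exp(lw)
    Z <- sum(w)
    mean_bound <- sum(w * vapply(configs, `[[`, numeric(1), "m")) / Z
    coverage <- numeric(N)
    for (i in seq_along(configs)) {
      for (s in configs[[i]]$start_positions) {
        idx <- s:(s + n - 1L)
        coverage[idx] <- coverage[idx] + w[i]
      }
    }
    coverage <- coverage / Z
  }
  # numerical guard: probabilities can overshoot [0, 1] by an ulp
  coverage <- clamp(coverage, 0, 1)
  if (capacity > 0) mean_bound <- clamp(mean_bound, 0, capacity)
  structure(
    list(coverage = coverage, mean_bound = mean_bound,
         saturation_fraction = if (capacity > 0) mean_bound / capacity else 0,
         length_nt = N, site_size_n = n),
    class = "occupancy_profile"
  )
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf(
    "<occupancy_profile> N = %d, n = %d, mean bound = %.4g (%.1f%% saturated)\n",
    x$length_nt, x$site_size_n, x$mean_bound, 100 * x$saturation_fraction
  ))
  invisible(x)
}

#' Effective cooperativity exponent at saturation
#'
#' For the unique fully saturated configuration of a lattice binding
#' `m = floor(N/n)` ligands there are `j = m - 1` abutting interfaces, so the
#' effective association constant per bound ligand is `K_a * omega^((m-1)/m)`.
#' This returns the exponent `(m - 1)/m`: 2/3 for a 21-mer with n = 7
#' (three ligands, two interfaces) and 3/4 for a 28-mer (four ligands,
#' three interfaces).
#'
#' @param length_nt Lattice length (nt).
#' @param site_size_n Ligand site size (nt).
#' @return Exponent in `[0, 1)`.
#' @examples
#' saturated_exponent(21, 7) # 2/3
#' saturated_exponent(28, 7) # 3/4
#' @export
saturated_exponent <- function(length_nt, site_size_n) {
  m <- count_saturating_ligands(length_nt, site_size_n)
  if (m < 1L) {
    stop("lattice shorter than one binding site has no saturated cluster",
         call. = FALSE)
  }
  (m - 1) / m
}

#' Solve the ligand mass balance
#'
#' Finds the free ligand concentration L such that
#' `total_ligand = L + lattice_conc * mean_bound(L)` by monotone bisection on
#' `[0, total_ligand]` (mean occupancy is strictly increasing in L, so the
#' root is unique).  Convergence requires the residual to drop below
#' `1e-10 * total_ligand`, with an absolute floor of 1e-18 M.
#'
#' @param total_ligand Total ligand concentration (M).
#' @param lattice_conc Lattice (construct) concentration (M).
#' @param length_nt Lattice length (nt).
#' @param params A [ligand_params].
#' @param max_iter Bisection iteration limit.
#' @return An object of class `solution_state`: `free_ligand`,
#'   `total_ligand`, `lattice_conc`, `profile` (the [occupancy_profile] at
#'   the root), `residual`, `iterations`.
#' @export
solve_mass_balance <- function(total_ligand, lattice_conc, length_nt, params,
                               max_iter = 200L) {
  stopifnot(inherits(params, "ligand_params"))
  stopifnot_scalar_number(total_ligand, "total_ligand", lower = 0)
  stopifnot_scalar_number(lattice_conc, "lattice_conc", lower = 0)
  tol <- max(1e-10 * total_ligand, 1e-18)
  # bisection only needs the mean bound count, not the full profile
  residual_at <- function(L) {
    L + lattice_conc * sum(exp(start_log_probs(length_nt, params, L))) -
      total_ligand
  }
  if (total_ligand == 0 || lattice_conc == 0) {
    prof <- mean_bound_and_coverage(length_nt, params, total_ligand)
    return(structure(
      list(free_ligand = total_ligand, total_ligand = total_ligand,
           lattice_conc = lattice_conc, profile = prof,
           residual = total_ligand + lattice_conc * prof$mean_bound -
             total_ligand,
           iterations = 0L),
      class = "solution_state"
    ))
  }
  lo <- 0
  hi <- total_ligand
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    res <- residual_at(mid)
    if (abs(res) < tol || (hi - lo) < .Machine$double.xmin) break
    if (res > 0) hi <- mid else lo <- mid
    if (it >= max_iter) {
      if (abs(res) >= tol) {
        stop(sprintf(
          "mass balance failed to converge: bracket [%.6g, %.6g], residual %.3g",
          lo, hi, res), call. = FALSE)
      }
      break
    }
  }
  structure(
    list(free_ligand = mid, total_ligand = total_ligand,
         lattice_conc = lattice_conc,
         profile = mean_bound_and_coverage(length_nt, params, mid),
         residual = res, iterations = it),
    class = "solution_state"
  )
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf(
    "<solution_state> free = %.4g M of %.4g M total; mean bound = %.4g\n",
    x$free_ligand, x$total_ligand, x$profile$mean_bound
  ))
  invisible(x)
}

#' Equilibrium titration curve over an added-ligand ratio grid
#'
#' For each added monomers-per-lattice ratio, solves the mass balance at
#' `total_ligand = ratio * lattice_conc` and records the occupancy profile.
#' In the strong-binding limit the probe coverage versus ratio approaches two
#' line segments intersecting at the capacity `floor(N/n)`.
#'
#' @param construct A [lattice_construct].
#' @param params A [ligand_params].
#' @param ratios Non-negative, sorted monomers-per-lattice ratios.
#' @param lattice_conc Lattice concentration (M).
#' @return A tidy `data.frame` with columns `construct`, `ratio`, `position`,
#'   `theta`, `mean_bound`, `free_ligand`; the list of occupancy profiles is
#'   attached as attribute `"profiles"`.
#' @export
titration_curve <- function(construct, params, ratios, lattice_conc) {
  stopifnot(inherits(construct, "lattice_construct"),
            inherits(params, "ligand_params"))
  if (is.unsorted(ratios) || any(ratios < 0)) {
    stop("'ratios' must be non-negative and sorted", call. = FALSE)
  }
  N <- construct$length_nt
  profiles <- vector("list", length(ratios))
  rows <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    sol <- solve_mass_balance(ratios[i] * lattice_conc, lattice_conc,
                              N, params)
    profiles[[i]] <- sol$profile
    rows[[i]] <- data.frame(
      construct = construct$name, ratio = ratios[i], position = seq_len(N),
      theta = sol$profile$coverage, mean_bound = sol$profile$mean_bound,
      free_ligand = sol$free_ligand
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

#' Coverage of a construct's probe
#'
#' Convenience accessor: coverage at a monomer probe position, or the mean
#' coverage of the two positions of a dimer probe.
#'
#' @param profile An [occupancy_profile].
#' @param construct A [lattice_construct] with at least one probe.
#' @return Scalar coverage in `[0, 1]`.
#' @export
probe_coverage <- function(profile, construct) {
  stopifnot(inherits(profile, "occupancy_profile"),
            inherits(construct, "lattice_construct"))
  if (!length(construct$probe_positions)) {
    stop("construct has no probe", call. = FALSE)
  }
  mean(profile$coverage[construct$probe_positions])
}
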