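#' Straight-line CSDA electron transport in a homogeneous medium
#'
#' A deliberately simplified transport model used as an internally
#' consistent validation oracle: electrons travel in straight lines from
#' the origin, losing energy continuously at the local linear total
#' stopping power (continuous slowing down approximation), with no
#' multiple scattering, bremsstrahlung escape, or secondary production.
#' Energy deposition is scored as point deposits at step midpoints; when
#' the energy falls below `cutoff` the remainder is deposited locally, so
#' energy is conserved exactly per electron (to floating-point error).
#' This is *not* a condensed-history Monte Carlo code and its kernels are
#' not evaluated reference kernels — its role is to provide matched
#' physics against which the EPA rescaling chain can be verified without
#' an external transport engine.
#'
#' @param es an `electron_spectrum`; source energies are drawn from the
#'   occupied bins (at bin centers) with probability proportional to weight.
#' @param medium a `material_table` whose grid covers the spectrum support
#'   and `cutoff`.
#' @param n number of source electrons (>= 1).
#' @param seed optional integer seed.
#' @param cutoff transport cutoff in keV (default 0.25, i.e. 250 eV, the
#'   conventional nanodosimetry production threshold); must be at or above
#'   the table's minimum grid energy.
#' @param max_step maximum step length in nm; per-step energy loss is also
#'   capped at 2% of the current energy.
#' @return A tibble of deposit events with columns `r_nm` (radial distance
#'   from the origin) and `e_dep_keV`, suitable for [kernel_from_deposits()].
#' @export
transport_homogeneous <- function(es, medium, n, seed = NULL, cutoff = 0.25,
                                  max_step = 5) {
  stopifnot(inherits(es, "electron_spectrum"), inherits(medium, "material_table"))
  if (n < 1) rlang::abort("`n` must be at least 1")
  .check_transport_grid(es, medium, cutoff)
  if (!is.null(seed)) set.seed(seed)
  e <- .sample_spectrum_energies(es, n)
  s <- rep(0, n)
  out_r <- vector("list", 0); out_e <- vector("list", 0)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    ea <- e[alive]; sa <- s[alive]
    stp <- linear_tsp(medium, ea)
    ds <- pmin(max_step, 0.02 * ea / stp)
    de <- stp * ds
    out_r <- c(out_r, list(sa + ds / 2)); out_e <- c(out_e, list(de))
    ea <- ea - de; sa <- sa + ds
    dead <- ea < cutoff
    if (any(dead)) {
      out_r <- c(out_r, list(sa[dead])); out_e <- c(out_e, list(ea[dead]))
    }
    e[alive] <- ea; s[alive] <- sa
    alive[alive] <- !dead
  }
  tibble::tibble(r_nm = unlist(out_r), e_dep_keV = unlist(out_e))
}

.check_transport_grid <- function(es, tab, cutoff) {
  occ <- es$weight > 0
  if (!any(occ)) rlang::abort("electron spectrum has no occupied bins")
  emax <- max(spectrum_centers(es)[occ])
  grid <- tab$energy_keV
  if (emax > max(grid) || cutoff < min(grid)) {
    rlang::abort("spectrum support / cutoff outside the material table grid")
  }
  if (cutoff <= 0) rlang::abort("`cutoff` must be positive")
}

.sample_spectrum_energies <- function(es, n) {
  occ <- which(es$weight > 0)
  centers <- spectrum_centers(es)
  centers[occ[sample.int(length(occ), n, replace = TRUE,
                         prob = es$weight[occ])]]
}

#' Ground-truth dose profile around an electron-emitting nanosphere
#'
#' Same straight-line CSDA physics as [transport_homogeneous()], with
#' source points sampled uniformly inside the sphere, gold stopping power
#' applied while the track is inside (a straight ray through a convex body
#' exits exactly once) and water outside. Deposits beyond the surface are
#' binned into uniform spherical shells and divided by shell mass (water
#' density) and source count — the matched-physics reference against which
#' [profile_sphere()] with a TSP factor can be scored.
#'
#' @inheritParams transport_homogeneous
#' @param s a `sphere`.
#' @param gold,water `material_table`s for particle and medium.
#' @param d_max profile extent from the surface in nm.
#' @param bin_width shell thickness in nm.
#' @return A `radial_dose_profile`; its `meta` attribute carries the energy
#'   ledger (`energy_emitted_keV`, `energy_inside_keV`,
#'   `energy_profile_keV`, `energy_beyond_keV`, all totals in keV).
#' @export
transport_sphere_source <- function(s, es, gold, water, n, seed = NULL,
                                    cutoff = 0.25, max_step = 5,
                                    d_max = 1000, bin_width = 1) {
  stopifnot(inherits(s, "sphere"), inherits(es, "electron_spectrum"))
  if (n < 1) rlang::abort("`n` must be at least 1")
  .check_transport_grid(es, gold, cutoff)
  .check_transport_grid(es, water, cutoff)
  if (!is.null(seed)) set.seed(seed)
  r0 <- s$radius
  n <- as.integer(n)
  n_bins <- ceiling(d_max / bin_width)

  p0 <- as.matrix(sample_in_sphere(s, n))
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  b <- rowSums(p0 * u)
  cc <- rowSums(p0^2) - r0^2
  t_exit <- -b + sqrt(pmax(b^2 - cc, 0))   # arc length at which the ray exits

  e <- .sample_spectrum_energies(es, n)
  e_emitted <- sum(e)
  sarc <- rep(0, n)
  hist_e <- rep(0, n_bins); hist_n <- rep(0L, n_bins)
  e_inside <- 0; e_beyond <- 0
  alive <- rep(TRUE, n)

  deposit <- function(dvals, evals) {
    outb <- dvals >= 0
    e_inside <<- e_inside + sum(evals[!outb])
    if (any(outb)) {
      di <- floor(dvals[outb] / bin_width) + 1
      ein <- evals[outb]
      far <- di > n_bins
      e_beyond <<- e_beyond + sum(ein[far])
      if (any(!far)) {
        acc <- rowsum(ein[!far], di[!far])
        ii <- as.integer(rownames(acc))
        hist_e[ii] <<- hist_e[ii] + acc[, 1]
        hist_n[ii] <<- hist_n[ii] + tabulate(di[!far], nbins = n_bins)[ii]
      }
    }
  }

  while (any(alive)) {
    ia <- which(alive)
    ea <- e[ia]; sa <- sarc[ia]
    rem <- t_exit[ia] - sa
    in_gold <- rem > 1e-9
    stp <- numeric(length(ia))
    if (any(in_gold)) stp[in_gold] <- linear_tsp(gold, ea[in_gold])
    if (any(!in_gold)) stp[!in_gold] <- linear_tsp(water, ea[!in_gold])
    ds <- pmin(max_step, 0.02 * ea / stp)
    ds[in_gold] <- pmin(ds[in_gold], rem[in_gold])
    de <- stp * ds
    smid <- sa + ds / 2
    pos <- p0[ia, , drop = FALSE] + u[ia, , drop = FALSE] * smid
    dmid <- sqrt(rowSums(pos^2)) - r0
    deposit(dmid, de)
    ea <- ea - de; sa <- sa + ds
    dead <- ea < cutoff
    if (any(dead)) {
      pe <- p0[ia[dead], , drop = FALSE] + u[ia[dead], , drop = FALSE] * sa[dead]
      deposit(sqrt(rowSums(pe^2)) - r0, ea[dead])
    }
    e[ia] <- ea; sarc[ia] <- sa
    alive[ia] <- !dead
  }

  edges_lo <- r0 + (seq_len(n_bins) - 1) * bin_width
  mass <- shell_mass(edges_lo, edges_lo + bin_width, material_density(water))
  radial_dose_profile(
    seq(0, n_bins * bin_width, by = bin_width),
    hist_e / mass / n, hist_n,
    meta = list(
      geometry = sprintf("sphere R0=%g nm", r0), method = "csda-oracle",
      seed = seed, n_electrons = n,
      energy_emitted_keV = e_emitted, energy_inside_keV = e_inside,
      energy_profile_keV = sum(hist_e), energy_beyond_keV = e_beyond
    )
  )
}
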