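#' Photon spectrum constructor
#'
#' A photon spectrum is a discrete set of emission lines, each an energy in
#' keV with a yield in photons per disintegration. It is stored as a tibble
#' with columns `energy_keV` and `yield`, sorted by increasing energy.
#'
#' @param lines data frame with columns `energy_keV` (> 0) and `yield` (>= 0).
#' @param name text label carried as an attribute.
#' @return A `photon_spectrum` tibble.
#' @export
#' @examples
#' photon_spectrum(data.frame(energy_keV = 100, yield = 0.5), "mono-100")
photon_spectrum <- function(lines, name = "spectrum") {
  stopifnot(is.data.frame(lines))
  if (!all(c("energy_keV", "yield") %in% names(lines))) {
    rlang::abort("`lines` must have columns energy_keV and yield")
  }
  out <- tibble::as_tibble(lines[, c("energy_keV", "yield")])
  out <- dplyr::arrange(out, .data$energy_keV)
  if (nrow(out) < 1L) rlang::abort("a photon spectrum needs at least one line")
  if (any(!is.finite(out$energy_keV)) || any(out$energy_keV <= 0)) {
    rlang::abort("all line energies must be finite and strictly positive")
  }
  if (any(diff(out$energy_keV) <= 0)) {
    rlang::abort("line energies must be distinct")
  }
  if (any(!is.finite(out$yield)) || any(out$yield < 0)) {
    rlang::abort("all yields must be finite and non-negative")
  }
  structure(out,
    name = name,
    class = c("photon_spectrum", class(out))
  )
}

# Yb-169 emission lines as printed in standard spectrum compilations:
# energies in MeV, yields in photons per disintegration (lines with yields
# above 0.1% only). Stored in MeV and converted to keV on load.
.yb169_lines_MeV <- data.frame(
  energy_MeV = c(
    0.04977, 0.05074, 0.05730, 0.05751, 0.05790, 0.05903, 0.05921, 0.06312,
    0.09362, 0.10978, 0.11819, 0.13052, 0.17721, 0.19796, 0.26108, 0.30774
  ),
  yield = c(
    0.532, 0.940, 0.0993, 0.192, 0.00379, 0.0647, 0.0172, 0.442,
    0.0261, 0.1747, 0.01869, 0.1131, 0.2216, 0.358, 0.01715, 0.1005
  )
)

#' Built-in Yb-169 photon spectrum
#'
#' The 16 principal emission lines of ytterbium-169 (yields above 0.1%),
#' a keV-energy photon emitter used in brachytherapy and a canonical source
#' for gold-nanoparticle radiosensitization studies. Energies are stored in
#' MeV as tabulated and converted to keV here.
#'
#' @return A `photon_spectrum` with 16 lines in ascending energy order.
#' @export
#' @examples
#' yb169_spectrum() |> total_yield() # 3.32083 photons per disintegration
yb169_spectrum <- function() {
  photon_spectrum(
    data.frame(
      energy_keV = .yb169_lines_MeV$energy_MeV * 1000,
      yield = .yb169_lines_MeV$yield
    ),
    name = "Yb-169"
  )
}

#' Total photon yield of a spectrum
#'
#' @param s a `photon_spectrum`.
#' @return Sum of line yields, in photons per disintegration.
#' @export
total_yield <- function(s) {
  stopifnot(inherits(s, "photon_spectrum"))
  sum(s$yield)
}

#' Binned secondary-electron spectrum constructor
#'
#' An electron spectrum is a histogram of secondary-electron kinetic
#' energies on uniform keV bins, with weights in electrons per incident
#' photon. Stored as a tibble with `bin_lo_keV`, `bin_hi_keV`, `weight`.
#'
#' @param bin_edges strictly increasing, uniformly spaced bin edges in keV.
#' @param weights one non-negative weight per bin.
#' @return An `electron_spectrum` tibble.
#' @export
electron_spectrum <- function(bin_edges, weights) {
  if (length(bin_edges) != length(weights) + 1L) {
    rlang::abort("need length(bin_edges) == length(weights) + 1")
  }
  d <- diff(bin_edges)
  if (any(d <= 0)) rlang::abort("bin edges must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(d)) {
    rlang::abort("bin edges must be uniformly spaced")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    rlang::abort("weights must be finite and non-negative")
  }
  out <- tibble::tibble(
    bin_lo_keV = bin_edges[-length(bin_edges)],
    bin_hi_keV = bin_edges[-1],
    weight = as.numeric(weights)
  )
  structure(out,
    bin_width = d[1],
    class = c("electron_spectrum", class(out))
  )
}

#' Bin centers of an electron spectrum
#' @param es an `electron_spectrum`.
#' @return Numeric vector of bin-center energies in keV.
#' @export
spectrum_centers <- function(es) {
  stopifnot(inherits(es, "electron_spectrum"))
  (es$bin_lo_keV + es$bin_hi_keV) / 2
}

#' Simplified secondary-electron spectrum from photoelectric absorption
#'
#' Monte-Carlo sampling model of the first photon interaction in gold:
#' each sampled photon line ejects a photoelectron of energy `E_gamma - B`
#' from an atomic shell with binding energy `B`, chosen among the
#' energetically allowed shells with the supplied relative probabilities.
#' Each vacancy may additionally emit fixed-energy Auger electrons with the
#' given yields per vacancy. Compton scattering and pair production are not
#' modelled; at the keV energies where gold nanoparticle dose enhancement
#' matters, photoelectric absorption dominates the gold cross-section. A
#' spectrum computed by an external transport code can be used anywhere an
#' `electron_spectrum` is accepted.
#'
#' @param s a `photon_spectrum`.
#' @param shells data frame with columns `binding_keV` and `prob`
#'   (relative photoionization probability; renormalized among the shells
#'   with `binding_keV` below the sampled photon energy).
#' @param auger optional data frame with columns `energy_keV` and
#'   `yield` (Auger electrons per vacancy at that fixed energy).
#' @param n_samples number of photon histories to sample (>= 1).
#' @param seed integer seed; the histogram is reproducible bit-for-bit.
#' @param bin_width histogram bin width in keV (default 0.1, the
#'   convention for keV brachytherapy sources; 1 keV suits MV spectra).
#' @return An `electron_spectrum` normalized to electrons per incident
#'   (interacting) photon.
#' @export
secondary_electron_spectrum <- function(s, shells, auger = NULL,
                                        n_samples = 1e5, seed = NULL,
                                        bin_width = 0.1) {
  stopifnot(inherits(s, "photon_spectrum"), is.data.frame(shells))
  if (!all(c("binding_keV", "prob") %in% names(shells))) {
    rlang::abort("`shells` must have columns binding_keV and prob")
  }
  if (bin_width <= 0) rlang::abort("`bin_width` must be positive")
  if (n_samples < 1) rlang::abort("`n_samples` must be at least 1")
  # a line is usable only if at least one shell lies below it
  usable <- vapply(s$energy_keV, function(e) any(shells$binding_keV < e), logical(1))
  if (!any(usable)) {
    rlang::abort("no photon line exceeds any shell binding energy")
  }
  lines <- s[usable, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  li <- sample.int(nrow(lines), n_samples, replace = TRUE, prob = lines$yield)
  e_gamma <- lines$energy_keV[li]
  # shell choice restricted to B < E_gamma, renormalized per event
  e_el <- vapply(e_gamma, function(eg) {
    ok <- shells$binding_keV < eg
    si <- sample.int(sum(ok), 1L, prob = shells$prob[ok])
    eg - shells$binding_keV[ok][si]
  }, numeric(1))

  e_max <- max(s$energy_keV)
  n_bins <- ceiling(e_max / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- pmin(findInterval(e_el, edges, left.open = FALSE), n_bins)
  w <- tabulate(idx, nbins = n_bins) / n_samples

  if (!is.null(auger) && nrow(auger) > 0) {
    stopifnot(all(c("energy_keV", "yield") %in% names(auger)))
    ai <- pmin(findInterval(auger$energy_keV, edges), n_bins)
    for (j in seq_along(ai)) w[ai[j]] <- w[ai[j]] + auger$yield[j]
  }
  electron_spectrum(edges, w)
}

#' Read / write spectra as two-column CSV
#'
#' Photon spectra are stored as `energy_keV,weight` CSV with a header row;
#' electron spectra as `bin_lo_keV,bin_hi_keV,weight`.
#'
#' @param path file path.
#' @param s,es the spectrum to write.
#' @name spectrum_io
NULL

#' @rdname spectrum_io
#' @export
read_photon_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_keV", "weight") %in% names(df))) {
    rlang::abort("photon spectrum CSV needs columns energy_keV,weight")
  }
  photon_spectrum(data.frame(energy_keV = df$energy_keV, yield = df$weight),
                  name = basename(path))
}

#' @rdname spectrum_io
#' @export
write_photon_spectrum <- function(s, path) {
  stopifnot(inherits(s, "photon_spectrum"))
  utils::write.csv(data.frame(energy_keV = s$energy_keV, weight = s$yield),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spectrum_io
#' @export
read_electron_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("bin_lo_keV", "bin_hi_keV", "weight")
  if (!all(need %in% names(df))) {
    rlang::abort("electron spectrum CSV needs columns bin_lo_keV,bin_hi_keV,weight")
  }
  electron_spectrum(c(df$bin_lo_keV, df$bin_hi_keV[nrow(df)]), df$weight)
}

#' @rdname spectrum_io
#' @export
write_electron_spectrum <- function(es, path) {
  stopifnot(inherits(es, "electron_spectrum"))
  utils::write.csv(as.data.frame(es), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default gold shell and Auger data
#'
#' Binding energies and fixed relative photoionization probabilities for the
#' principal gold shells, plus representative Auger lines, bundled as plain
#' CSV under `inst/extdata`. These are synthetic simplifications assembled
#' from standard X-ray data compilations (K-shell dominance above the
#' 80.7 keV edge; L3 > L2 > L1 below), intended as default inputs for
#' [secondary_electron_spectrum()].
#'
#' @return A data frame (`gold_shells()`: `binding_keV`, `prob`;
#'   `gold_auger()`: `energy_keV`, `yield`).
#' @export
gold_shells <- function() {
  utils::read.csv(system.file("extdata", "gold_shells_synthetic.csv",
                              package = "nanodpk"), comment.char = "#")
}

#' @rdname gold_shells
#' @export
gold_auger <- function() {
  utils::read.csv(system.file("extdata", "gold_auger_synthetic.csv",
                              package = "nanodpk"), comment.char = "#")
}
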