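#' Mass of a spherical shell
#'
#' @param r_in,r_out inner and outer shell radii in nm, `0 <= r_in < r_out`.
#' @param rho density in g/cm^3.
#' @return Shell mass in grams: `(4/3) * pi * (r_out^3 - r_in^3) * rho`,
#'   with the nm^3 to cm^3 conversion (1e-21) applied. Vectorized.
#' @export
#' @examples
#' shell_mass(0, 1, 1.0) # ~4.18879e-21 g
shell_mass <- function(r_in, r_out, rho) {
  if (any(rho <= 0)) rlang::abort("`rho` must be positive")
  if (any(r_in < 0) || any(r_in >= r_out)) {
    rlang::abort("need 0 <= r_in < r_out")
  }
  (4 / 3) * pi * (r_out^3 - r_in^3) * 1e-21 * rho
}

#' Dose point kernel constructor
#'
#' A dose point kernel (DPK) is the radial dose distribution around an
#' isotropic point source of electrons in an infinite homogeneous medium,
#' tabulated on uniform concentric shells starting at the origin. Doses are
#' in keV/g per source electron; multiply by the electrons-per-photon yield
#' of a secondary-electron spectrum to express a kernel per incident photon.
#'
#' @param dose non-negative dose per shell, keV/g per source electron.
#' @param bin_width shell thickness in nm (default 1).
#' @param medium text label.
#' @param n_source number of simulated source electrons behind the table.
#' @return A `dose_point_kernel` tibble with columns `r_lo_nm`, `r_hi_nm`,
#'   `dose_keV_per_g_per_src`.
#' @export
dose_point_kernel <- function(dose, bin_width = 1, medium = "water",
                              n_source = 1) {
  if (n_source < 1) rlang::abort("`n_source` must be at least 1")
  if (bin_width <= 0) rlang::abort("`bin_width` must be positive")
  if (any(!is.finite(dose)) || any(dose < 0)) {
    rlang::abort("kernel doses must be finite and non-negative")
  }
  n <- length(dose)
  out <- tibble::tibble(
    r_lo_nm = (seq_len(n) - 1) * bin_width,
    r_hi_nm = seq_len(n) * bin_width,
    dose_keV_per_g_per_src = as.numeric(dose)
  )
  structure(out,
    medium = medium, n_source = n_source, bin_width = bin_width,
    class = c("dose_point_kernel", class(out))
  )
}

#' Build a dose point kernel from energy-deposition events
#'
#' Histograms point energy deposits by radial distance into uniform shells
#' and divides each shell's energy by its mass and by the number of source
#' electrons. Events at or beyond `r_max` are dropped (their count is
#' reported with a message).
#'
#' @param events data frame with columns `r_nm` (>= 0) and `e_dep_keV`.
#' @param bin_width shell thickness in nm.
#' @param r_max kernel extent in nm (multiple of `bin_width` recommended).
#' @param rho medium density in g/cm^3.
#' @param n_source number of source electrons that produced `events` (>= 1).
#' @param medium text label for the kernel.
#' @return A `dose_point_kernel`.
#' @export
kernel_from_deposits <- function(events, bin_width, r_max, rho, n_source,
                                 medium = "water") {
  stopifnot(is.data.frame(events))
  if (!all(c("r_nm", "e_dep_keV") %in% names(events))) {
    rlang::abort("`events` must have columns r_nm and e_dep_keV")
  }
  if (n_source < 1) rlang::abort("`n_source` must be at least 1")
  if (any(events$r_nm < 0)) rlang::abort("event radii must be non-negative")
  n_bins <- ceiling(r_max / bin_width)
  idx <- floor(events$r_nm / bin_width) + 1
  drop <- idx > n_bins
  if (any(drop)) {
    message(sprintf("kernel_from_deposits: dropped %d events at r >= %g nm",
                    sum(drop), r_max))
  }
  e_hist <- rep(0, n_bins)
  if (any(!drop)) {
    acc <- rowsum(events$e_dep_keV[!drop], idx[!drop])
    e_hist[as.integer(rownames(acc))] <- acc[, 1]
  }
  edges_lo <- (seq_len(n_bins) - 1) * bin_width
  mass <- shell_mass(edges_lo, edges_lo + bin_width, rho)
  dose_point_kernel(e_hist / mass / n_source, bin_width = bin_width,
                    medium = medium, n_source = n_source)
}

#' Evaluate a dose point kernel at arbitrary radius
#'
#' Linear interpolation between shell-center values. Radii below the first
#' shell center return the first shell's dose; radii beyond the last shell
#' center return 0 (electrons have finite range, so the kernel has compact
#' support).
#'
#' @param k a `dose_point_kernel`.
#' @param r radius in nm, `r >= 0` (vectorized).
#' @return Dose in keV/g per source electron.
#' @export
kernel_value <- function(k, r) {
  stopifnot(inherits(k, "dose_point_kernel"))
  if (any(r < 0)) rlang::abort("`r` must be non-negative")
  centers <- (k$r_lo_nm + k$r_hi_nm) / 2
  d <- k$dose_keV_per_g_per_src
  if (nrow(k) == 1L) {
    return(ifelse(r <= centers[1], d[1], 0))
  }
  stats::approx(centers, d, xout = r, yleft = d[1], yright = 0)$y
}

#' Read / write dose point kernels as CSV
#'
#' Columns `r_lo_nm`, `r_hi_nm`, `dose_keV_per_g_per_src`; `medium` and
#' `n_source` as `# key=value` header comments. Round trips losslessly.
#'
#' @param path file path.
#' @param k a `dose_point_kernel`.
#' @export
read_kernel <- function(path) {
  meta <- .read_hash_meta(path)
  if (is.null(meta$medium) || is.null(meta$n_source)) {
    rlang::abort(sprintf("%s: missing '# medium=' or '# n_source=' header", path))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("r_lo_nm", "r_hi_nm", "dose_keV_per_g_per_src")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf("%s: kernel CSV needs columns %s",
                         path, paste(need, collapse = ",")))
  }
  w <- df$r_hi_nm - df$r_lo_nm
  bad <- which(abs(w - w[1]) > 1e-9 * w[1] |
                 abs(df$r_lo_nm - (seq_len(nrow(df)) - 1) * w[1]) > 1e-9 * w[1])
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s: non-uniform or non-contiguous shell edges at data row %d",
      path, bad[1]
    ))
  }
  dose_point_kernel(df$dose_keV_per_g_per_src, bin_width = w[1],
                    medium = meta$medium,
                    n_source = as.numeric(meta$n_source))
}

#' @rdname read_kernel
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "dose_point_kernel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# medium=%s", attr(k, "medium")), con)
  writeLines(sprintf("# n_source=%.10g", attr(k, "n_source")), con)
  utils::write.csv(as.data.frame(k), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
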