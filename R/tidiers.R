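#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for nanodosimetry objects
#'
#' `tidy()` returns a plain tibble representation of each result type;
#' `glance()` returns a one-row summary.
#'
#' @param x the object.
#' @param ... unused.
#' @name nanodpk-tidiers
NULL

#' @rdname nanodpk-tidiers
#' @export
tidy.radial_dose_profile <- function(x, ...) {
  tibble::tibble(
    d_mid_nm = (x$d_lo_nm + x$d_hi_nm) / 2,
    dose_keV_per_g_per_src = x$dose_keV_per_g_per_src,
    n_samples = x$n_samples
  )
}

#' @rdname nanodpk-tidiers
#' @export
glance.radial_dose_profile <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble::tibble(
    n_bins = nrow(x),
    d_max_nm = max(x$d_hi_nm),
    bin_width_nm = attr(x, "bin_width"),
    peak_dose = max(x$dose_keV_per_g_per_src),
    factor = meta$factor %||% NA_character_,
    alpha = as.numeric(meta$alpha %||% NA_real_)
  )
}

#' @rdname nanodpk-tidiers
#' @export
tidy.dose_point_kernel <- function(x, ...) {
  tibble::tibble(
    r_mid_nm = (x$r_lo_nm + x$r_hi_nm) / 2,
    dose_keV_per_g_per_src = x$dose_keV_per_g_per_src
  )
}

#' @rdname nanodpk-tidiers
#' @export
tidy.rescaling_factor <- function(x, ...) {
  tibble::tibble(name = x$name, alpha = x$alpha)
}

#' @rdname nanodpk-tidiers
#' @export
tidy.mape_result <- function(x, ...) {
  tibble::tibble(mape_pct = x$value, n_used = x$n_used,
                 n_excluded = x$n_excluded)
}

#' @rdname nanodpk-tidiers
#' @export
glance.mape_result <- tidy.mape_result

#' @rdname nanodpk-tidiers
#' @export
tidy.pixel_grid <- function(x, ...) {
  dm <- dim(x$labels)
  tibble::tibble(
    ix = rep(seq_len(dm[2]), each = dm[1]),
    iy = rep(seq_len(dm[1]), times = dm[2]),
    label = ifelse(as.vector(x$labels) == 1L, "gold", "water")
  )
}

#' @rdname nanodpk-tidiers
#' @export
glance.pixel_grid <- function(x, ...) {
  tibble::tibble(
    nx = ncol(x$labels), ny = nrow(x$labels),
    pixel_size_nm = x$pixel_size,
    n_gold = sum(x$labels == 1L), n_water = sum(x$labels == 0L),
    gold_fraction = gold_fraction(x)
  )
}

#' @rdname nanodpk-tidiers
#' @export
tidy.dose_map <- function(x, ...) {
  out <- tidy.pixel_grid(x$grid)
  out$dose <- as.vector(x$dose)
  out
}

#' @rdname nanodpk-tidiers
#' @export
glance.dose_map <- function(x, ...) {
  w <- x$grid$labels == 0L
  tibble::tibble(
    factor = x$factor, alpha = x$alpha, relative = x$relative,
    max_dose = max(x$dose[w]), mean_water_dose = mean(x$dose[w])
  )
}
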