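#' Mean absolute percentage error between dose series
#'
#' `MAPE = (100 / N) * sum(|G_i - S_i| / G_i)` over the `N` points where
#' the reference `G_i` is positive. Points with a zero reference are
#' excluded from the sum and reported in `n_excluded` (the definition
#' divides by `G_i`, which is undefined there).
#'
#' @param reference reference dose series `G` (e.g. a transport result).
#' @param test test dose series `S` (e.g. a rescaled-kernel estimate),
#'   aligned point-for-point with `reference`.
#' @return A `mape_result` with fields `value` (percent), `n_used`,
#'   `n_excluded`.
#' @export
#' @examples
#' mape(c(100, 100), c(90, 110)) # 10%
mape <- function(reference, test) {
  if (length(reference) != length(test)) {
    rlang::abort("`reference` and `test` must have equal length")
  }
  if (length(reference) < 1) rlang::abort("empty series")
  use <- reference > 0
  if (!any(use)) rlang::abort("all reference points are zero; MAPE undefined")
  value <- 100 * mean(abs(reference[use] - test[use]) / reference[use])
  structure(
    list(value = value, n_used = sum(use), n_excluded = sum(!use)),
    class = "mape_result"
  )
}

#' @export
print.mape_result <- function(x, ...) {
  cat(sprintf("MAPE: %.4g%% over %d points (%d zero-reference points excluded)\n",
              x$value, x$n_used, x$n_excluded))
  invisible(x)
}

#' Align two radial dose profiles on common distance bins
#'
#' Profiles are paired on exactly matching bin edges; an error is raised
#' when the binnings differ or the distance ranges are disjoint.
#'
#' @param a,b `radial_dose_profile`s.
#' @return A tibble with `d_lo_nm`, `d_hi_nm`, `dose_a`, `dose_b`.
#' @export
align_profiles <- function(a, b) {
  stopifnot(inherits(a, "radial_dose_profile"), inherits(b, "radial_dose_profile"))
  wa <- attr(a, "bin_width"); wb <- attr(b, "bin_width")
  if (abs(wa - wb) > 1e-9 * max(wa, wb)) {
    rlang::abort("profiles have different bin widths; rebin before comparing")
  }
  out <- dplyr::inner_join(
    tibble::tibble(d_lo_nm = a$d_lo_nm, d_hi_nm = a$d_hi_nm,
                   dose_a = a$dose_keV_per_g_per_src),
    tibble::tibble(d_lo_nm = b$d_lo_nm, d_hi_nm = b$d_hi_nm,
                   dose_b = b$dose_keV_per_g_per_src),
    by = c("d_lo_nm", "d_hi_nm")
  )
  if (nrow(out) == 0) rlang::abort("profiles share no common distance bins")
  out
}

#' MAPE between two profiles over a distance range
#'
#' Convenience wrapper: aligns the profiles, optionally restricts to
#' `d_lo_nm < d_max`, and scores profile `b` against reference `a`.
#'
#' @param a reference profile; `b` test profile.
#' @param d_max optional upper distance bound in nm.
#' @return A `mape_result`.
#' @export
mape_profiles <- function(a, b, d_max = Inf) {
  al <- align_profiles(a, b)
  al <- al[al$d_lo_nm < d_max, , drop = FALSE]
  if (nrow(al) == 0) rlang::abort("no bins below `d_max`")
  mape(al$dose_a, al$dose_b)
}
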