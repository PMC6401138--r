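#' Nanoparticle geometries
#'
#' A gold nanosphere is a sphere of radius `R0` centered at the origin; a
#' gold nanorod is a cylinder of radius `r` and half-length `h` with its
#' axis along z, centered at the origin. All coordinates are in nm.
#'
#' @param radius sphere or rod radius in nm (> 0).
#' @param half_length rod half-length in nm (> 0).
#' @return A `sphere` or `rod` object.
#' @export
sphere <- function(radius) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(radius = radius), class = "sphere")
}

#' @rdname sphere
#' @export
rod <- function(radius, half_length) {
  stopifnot(radius > 0, half_length > 0)
  structure(list(radius = radius, half_length = half_length), class = "rod")
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf("<sphere> radius %g nm\n", x$radius)); invisible(x)
}

#' @export
print.rod <- function(x, ...) {
  cat(sprintf("<rod> radius %g nm, half-length %g nm (axis z)\n",
              x$radius, x$half_length))
  invisible(x)
}

#' Uniform random points inside a nanoparticle
#'
#' Source points are sampled uniformly by volume: for the sphere, an
#' isotropic direction scaled by `R0 * U^(1/3)`; for the rod, uniform in
#' angle and axial position with radial coordinate `r * sqrt(U)`.
#'
#' @param s a `sphere`; `rd` a `rod`.
#' @param n number of points.
#' @param seed optional integer seed for reproducible streams.
#' @return A tibble of coordinates `x`, `y`, `z` in nm.
#' @export
sample_in_sphere <- function(s, n, seed = NULL) {
  stopifnot(inherits(s, "sphere"))
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rr <- s$radius * stats::runif(n)^(1 / 3)
  tibble::tibble(x = u[, 1] * rr, y = u[, 2] * rr, z = u[, 3] * rr)
}

#' @rdname sample_in_sphere
#' @export
sample_in_rod <- function(rd, n, seed = NULL) {
  stopifnot(inherits(rd, "rod"))
  if (!is.null(seed)) set.seed(seed)
  rho <- rd$radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  zz <- stats::runif(n, -rd$half_length, rd$half_length)
  tibble::tibble(x = rho * cos(phi), y = rho * sin(phi), z = zz)
}

.xyz <- function(p) {
  stopifnot(is.data.frame(p), all(c("x", "y", "z") %in% names(p)))
  cbind(p$x, p$y, p$z)
}

#' Geometric path length between source and tally points
#'
#' @param ps,pt data frames with columns `x`, `y`, `z` (paired row-wise).
#' @return Euclidean distances in nm.
#' @export
gpl <- function(ps, pt) {
  a <- .xyz(ps); b <- .xyz(pt)
  stopifnot(nrow(a) == nrow(b))
  sqrt(rowSums((a - b)^2))
}

#' Distance traversed inside a nanosphere
#'
#' For a source point inside the sphere and tally point outside, the
#' segment from source to tally crosses the surface at a unique point
#' `P_R`. Writing any point on the segment parametrically as
#' `p(lambda) = ps * (1 - lambda) + pt * lambda`, substituting into
#' `x^2 + y^2 + z^2 = R0^2` gives a quadratic in `lambda`; the root in
#' `[0, 1]` locates the exit point, and the distance traversed inside (DTI)
#' is `|ps - P_R|`.
#'
#' @param ps source points inside the sphere (`|ps| <= R0`).
#' @param pt tally points outside the sphere (`|pt| > R0`).
#' @param s a `sphere`.
#' @return DTI in nm, one value per row pair.
#' @export
dti_sphere <- function(ps, pt, s) {
  stopifnot(inherits(s, "sphere"))
  a <- .xyz(ps); b <- .xyz(pt)
  stopifnot(nrow(a) == nrow(b))
  r0 <- s$radius
  if (any(rowSums(a^2) > r0^2 * (1 + 1e-12))) {
    rlang::abort("dti_sphere: all source points must lie inside the sphere")
  }
  if (any(rowSums(b^2) <= r0^2)) {
    rlang::abort("dti_sphere: all tally points must lie outside the sphere")
  }
  d <- b - a
  qa <- rowSums(d^2)
  qb <- 2 * rowSums(a * d)
  qc <- rowSums(a^2) - r0^2            # <= 0 since ps is inside
  lam <- (-qb + sqrt(pmax(qb^2 - 4 * qa * qc, 0))) / (2 * qa)
  lam * sqrt(qa)
}

#' Classify an exterior point into a nanorod axis region
#'
#' With the rod axis along z, half-length `h`, radius `r`, define the
#' long-axis opening angle `tan(omega) = r / h` and the short-axis angle
#' `tan(theta) = h / r`. An exterior point with cylindrical radius
#' `rho = sqrt(x^2 + y^2)` is in the long-axis region when
#' `rho / |z| < tan(omega)` and `|z| > h` (electrons cross the flat cap, a
#' planar boundary), in the short-axis region when `|z| / rho < tan(theta)`
#' and `rho > r` (electrons cross the curved side), and otherwise in
#' neither. The inequalities are strict, so cone-boundary points classify
#' as "neither"; dose profiles score only the two named regions.
#'
#' @param p data frame of exterior points (`x`, `y`, `z`).
#' @param rd a `rod`.
#' @return Character vector in `c("long_axis", "short_axis", "neither")`.
#' @export
classify_rod_region <- function(p, rd) {
  stopifnot(inherits(rd, "rod"))
  m <- .xyz(p)
  rho <- sqrt(m[, 1]^2 + m[, 2]^2)
  az <- abs(m[, 3])
  inside <- rho <= rd$radius & az <= rd$half_length
  if (any(inside)) {
    rlang::abort("classify_rod_region: points must lie outside the rod")
  }
  # comparisons multiplied through to avoid 0/0 on the axes
  long <- (rho * rd$half_length < rd$radius * az) & (az > rd$half_length)
  short <- (az * rd$radius < rd$half_length * rho) & (rho > rd$radius)
  out <- rep("neither", nrow(m))
  out[long] <- "long_axis"
  out[short] <- "short_axis"
  out
}

#' Distance traversed inside a nanorod
#'
#' First crossing of the rod boundary along the segment from a source point
#' inside to a tally point outside, via the same parametric form as
#' [dti_sphere()]. Cap crossings solve the linear condition
#' `z(lambda) = +/- h` (valid when the lateral coordinate stays within the
#' radius); side crossings solve the two-dimensional quadratic
#' `x(lambda)^2 + y(lambda)^2 = r^2` (valid when `|z(lambda)| <= h`). The
#' smallest valid `lambda` is the exit; this handles segments that exit
#' through a cap even when the tally point lies in the short-axis region.
#'
#' @param ps source points inside the rod.
#' @param pt tally points outside the rod.
#' @param rd a `rod`.
#' @return DTI in nm, one value per row pair.
#' @export
dti_rod <- function(ps, pt, rd) {
  stopifnot(inherits(rd, "rod"))
  a <- .xyz(ps); b <- .xyz(pt)
  stopifnot(nrow(a) == nrow(b))
  r <- rd$radius; h <- rd$half_length
  tol <- 1 + 1e-12
  rho_s <- sqrt(a[, 1]^2 + a[, 2]^2)
  if (any(rho_s > r * tol | abs(a[, 3]) > h * tol)) {
    rlang::abort("dti_rod: all source points must lie inside the rod")
  }
  rho_t2 <- b[, 1]^2 + b[, 2]^2
  if (any(rho_t2 <= r^2 & abs(b[, 3]) <= h)) {
    rlang::abort("dti_rod: all tally points must lie outside the rod")
  }
  d <- b - a
  n <- nrow(a)
  lam <- matrix(NA_real_, n, 4)

  # cap planes z = +h and z = -h
  dz <- d[, 3]
  for (j in 1:2) {
    zcap <- if (j == 1) h else -h
    lj <- ifelse(abs(dz) > 0, (zcap - a[, 3]) / dz, NA_real_)
    xl <- a[, 1] + d[, 1] * lj
    yl <- a[, 2] + d[, 2] * lj
    ok <- !is.na(lj) & lj >= 0 & lj <= 1 & (xl^2 + yl^2) <= r^2 * tol
    lam[, j] <- ifelse(ok, lj, NA_real_)
  }

  # lateral surface x^2 + y^2 = r^2
  qa <- d[, 1]^2 + d[, 2]^2
  qb <- 2 * (a[, 1] * d[, 1] + a[, 2] * d[, 2])
  qc <- a[, 1]^2 + a[, 2]^2 - r^2
  disc <- qb^2 - 4 * qa * qc
  has <- qa > 0 & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  for (j in 1:2) {
    lj <- ifelse(has, (-qb + (if (j == 1) sq else -sq)) / (2 * qa), NA_real_)
    zl <- a[, 3] + dz * lj
    ok <- !is.na(lj) & lj >= 0 & lj <= 1 & abs(zl) <= h * tol
    lam[, j + 2] <- ifelse(ok, lj, NA_real_)
  }

  lmin <- suppressWarnings(apply(lam, 1, min, na.rm = TRUE))
  if (any(!is.finite(lmin))) {
    rlang::abort("dti_rod: no boundary crossing found for some pair (degenerate input)")
  }
  lmin * sqrt(rowSums(d^2))
}

#' Modified path length under an EPA rescaling factor
#'
#' `MPL = GPL + (alpha - 1) * DTI`: the path segment inside the particle is
#' stretched by `alpha`, converting the heterogeneous path into an
#' equivalent water path at which the homogeneous kernel is evaluated.
#'
#' @param gpl geometric path lengths in nm.
#' @param dti distances traversed inside the particle, `0 <= dti <= gpl`.
#' @param f a `rescaling_factor`.
#' @return MPL in nm.
#' @export
#' @examples
#' mpl(100, 10, factor_unity()) # 100
mpl <- function(gpl, dti, f) {
  stopifnot(inherits(f, "rescaling_factor"))
  if (any(dti < 0)) rlang::abort("`dti` must be non-negative")
  if (any(dti > gpl * (1 + 1e-9))) {
    rlang::abort("`dti` cannot exceed `gpl`")
  }
  gpl + (f$alpha - 1) * dti
}

#' Nanorod scoring-volume geometry
#'
#' Long-axis dose bins are scored in two symmetric frustums of the cone
#' with apex at the origin and half-angle `omega` (`tan(omega) = r/h`),
#' cut between the axial planes `|z| = h + d` and `|z| = h + d + t`:
#' `V = (2*pi*tan(omega)^2 / 3) * ((h+d+t)^3 - (h+d)^3)`.
#' Short-axis bins are scored in the hollow cylinder-minus-frustums solid
#' between lateral radii `r + d` and `r + d + t`, bounded by the cones
#' `|z| < s * h / r`: `V = (4*pi*h / (3*r)) * ((r+d+t)^3 - (r+d)^3)`.
#'
#' @param d distance from the particle surface in nm (>= 0, vectorized).
#' @param rd a `rod`.
#' @param t shell thickness in nm (default 1).
#' @return Volume in nm^3.
#' @export
scoring_volume_long <- function(d, rd, t = 1) {
  stopifnot(inherits(rd, "rod"), t > 0)
  if (any(d < 0)) rlang::abort("`d` must be non-negative")
  tw <- rd$radius / rd$half_length
  h <- rd$half_length
  (2 * pi * tw^2 / 3) * ((h + d + t)^3 - (h + d)^3)
}

#' @rdname scoring_volume_long
#' @export
scoring_volume_short <- function(d, rd, t = 1) {
  stopifnot(inherits(rd, "rod"), t > 0)
  if (any(d < 0)) rlang::abort("`d` must be non-negative")
  r <- rd$radius; h <- rd$half_length
  (4 * pi * h / (3 * r)) * ((r + d + t)^3 - (r + d)^3)
}

#' Path decomposition for source-tally pairs
#'
#' Convenience wrapper returning the (GPL, DTI, MPL) triple for paired
#' source and tally points around a sphere or rod.
#'
#' @param ps,pt paired coordinate data frames.
#' @param shape a `sphere` or `rod`.
#' @param f a `rescaling_factor`.
#' @return A tibble with columns `gpl_nm`, `dti_nm`, `mpl_nm`.
#' @export
decompose_paths <- function(ps, pt, shape, f = factor_unity()) {
  g <- gpl(ps, pt)
  dti <- if (inherits(shape, "sphere")) {
    dti_sphere(ps, pt, shape)
  } else if (inherits(shape, "rod")) {
    dti_rod(ps, pt, shape)
  } else {
    rlang::abort("`shape` must be a sphere or a rod")
  }
  tibble::tibble(gpl_nm = g, dti_nm = dti, mpl_nm = mpl(g, pmin(dti, g), f))
}
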