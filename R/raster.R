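#' Pixel grid of a segmented nanoparticle cluster
#'
#' A two-dimensional raster of square pixels labelled gold or water,
#' typically segmented from an electron-microscopy image of nanoparticle
#' clusters inside a cell. Stored as an integer matrix (1 = gold,
#' 0 = water) with `ny` rows and `nx` columns plus the physical pixel
#' size; 50 nm is the conventional default for TEM-derived grids.
#'
#' @param labels integer matrix of 0 (water) / 1 (gold), rows = y.
#' @param pixel_size pixel edge length in nm (> 0, default 50).
#' @return A `pixel_grid`.
#' @export
pixel_grid <- function(labels, pixel_size = 50) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  if (!all(labels %in% c(0L, 1L))) {
    rlang::abort("`labels` must contain only 0 (water) and 1 (gold)")
  }
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         pixel_size = pixel_size),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d pixels at %g nm (%d gold, %d water)\n",
              ncol(x$labels), nrow(x$labels), x$pixel_size,
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Grid dimensions and composition
#' @param g a `pixel_grid`.
#' @return `grid_dim()`: named vector `nx`, `ny`; `n_pixels()`: total pixel
#'   count; `gold_fraction()`: fraction of gold pixels.
#' @export
grid_dim <- function(g) c(nx = ncol(g$labels), ny = nrow(g$labels))

#' @rdname grid_dim
#' @export
n_pixels <- function(g) length(g$labels)

#' @rdname grid_dim
#' @export
gold_fraction <- function(g) mean(g$labels == 1L)

#' Segment an RGB raster into gold and water pixels
#'
#' Global threshold on the mean RGB value: a pixel whose mean channel
#' intensity (normalized to `[0, 1]`) falls below `threshold` is gold
#' (nanoparticles image dark in bright-field TEM), otherwise water.
#'
#' @param img numeric array `ny x nx x 3` (or `x 4`; alpha is ignored)
#'   with values in `[0, 1]`, as returned by [png::readPNG()].
#' @param pixel_size pixel edge length in nm.
#' @param threshold gold/water threshold on the mean RGB, in (0, 1);
#'   default 0.4.
#' @return A `pixel_grid`.
#' @export
grid_from_image <- function(img, pixel_size = 50, threshold = 0.4) {
  if (threshold <= 0 || threshold >= 1) rlang::abort("`threshold` must be in (0, 1)")
  if (!is.array(img) || length(dim(img)) != 3 || !dim(img)[3] %in% c(3L, 4L)) {
    rlang::abort("`img` must be an RGB(A) array of dimension ny x nx x 3|4")
  }
  if (dim(img)[1] < 1 || dim(img)[2] < 1) rlang::abort("empty image")
  mean_rgb <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  pixel_grid((mean_rgb < threshold) * 1L, pixel_size)
}

#' Read a pixel grid from an image or label file
#'
#' Accepts PNG (via the png package), ASCII PGM (P2/P5 grayscale, treated
#' as equal RGB channels), or a CSV label grid of 0/1 values with an
#' optional JSON sidecar (`<path>.json` with field `pixel_size_nm`).
#'
#' @param path file path (`.png`, `.pgm`, or `.csv`).
#' @inheritParams grid_from_image
#' @export
read_pixel_grid <- function(path, pixel_size = 50, threshold = 0.4) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) {
      rlang::abort(sprintf("%s: grayscale PNG is not RGB input", path))
    }
    grid_from_image(img, pixel_size, threshold)
  } else if (ext == "pgm") {
    gray <- .read_pgm(path)
    img <- array(rep(gray, 3), dim = c(nrow(gray), ncol(gray), 3))
    grid_from_image(img, pixel_size, threshold)
  } else if (ext == "csv") {
    lab <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side)
      if (!is.null(meta$pixel_size_nm)) pixel_size <- as.numeric(meta$pixel_size_nm)
    }
    pixel_grid(matrix(as.integer(lab), nrow(lab), ncol(lab)), pixel_size)
  } else {
    rlang::abort(sprintf("unsupported pixel grid format: .%s", ext))
  }
}

#' Write a pixel grid as a CSV label file with JSON sidecar
#' @param g a `pixel_grid`.
#' @param path output `.csv` path; `<path>.json` records the pixel size.
#' @export
write_pixel_grid <- function(g, path) {
  stopifnot(inherits(g, "pixel_grid"))
  utils::write.table(g$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_size_nm = g$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# minimal ASCII/binary PGM reader (P2 / P5), values normalized to [0, 1]
.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  while (length(toks) < 4) {
    ln <- readLines(con, n = 1)
    ln <- sub("#.*$", "", ln)
    toks <- c(toks, strsplit(trimws(ln), "\\s+")[[1]])
    toks <- toks[nzchar(toks)]
  }
  magic <- toks[1]
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxv <- as.integer(toks[4])
  if (!magic %in% c("P2", "P5")) rlang::abort(sprintf("%s: not a PGM file", path))
  npx <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = npx, quiet = TRUE)
  } else {
    as.integer(readBin(con, "raw", n = npx))
  }
  if (length(vals) != npx) rlang::abort(sprintf("%s: truncated PGM data", path))
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

#' Synthetic nanoparticle cluster grid
#'
#' Random disc-shaped gold regions on a water background, emulating an
#' endosome-like cluster of internalized nanoparticles. A stand-in for
#' segmented microscopy images (the reference TEM segmentations used in
#' the field are rarely deposited); clearly synthetic, for testing and
#' method exploration.
#'
#' @param nx,ny grid dimensions in pixels.
#' @param n_blobs number of discs (>= 1).
#' @param blob_radius_px inclusive integer range of disc radii in pixels.
#' @param pixel_size pixel edge length in nm.
#' @param seed optional integer seed (fixed seed gives identical grids).
#' @return A `pixel_grid`.
#' @export
synth_cluster <- function(nx, ny, n_blobs, blob_radius_px = c(2, 5),
                          pixel_size = 50, seed = NULL) {
  if (n_blobs < 1) rlang::abort("`n_blobs` must be at least 1")
  rmax <- max(blob_radius_px)
  if (2 * rmax + 1 > min(nx, ny)) {
    rlang::abort("blobs cannot fit: 2*max(blob_radius_px)+1 exceeds the grid")
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- matrix(0L, ny, nx)
  cx <- seq_len(nx); cy <- seq_len(ny)
  for (i in seq_len(n_blobs)) {
    r <- sample(seq(min(blob_radius_px), rmax), 1)
    x0 <- sample(seq(1 + r, nx - r), 1)
    y0 <- sample(seq(1 + r, ny - r), 1)
    d2 <- outer((cy - y0)^2, (cx - x0)^2, `+`)
    lab[d2 <= r^2] <- 1L
  }
  pixel_grid(lab, pixel_size)
}

#' Bresenham line between two pixels
#'
#' Integer raster traversal from `p0` to `p1`, inclusive of both
#' endpoints, using the classic midpoint rule along the major axis.
#'
#' @param p0,p1 integer pixel indices `c(ix, iy)`, 1-based.
#' @param g optional `pixel_grid`; when supplied, indices outside the grid
#'   raise an error.
#' @return An integer matrix with columns `ix`, `iy`, one row per pixel.
#' @export
#' @examples
#' traverse(c(1, 1), c(4, 4)) # the main diagonal
traverse <- function(p0, p1, g = NULL) {
  p0 <- as.integer(p0); p1 <- as.integer(p1)
  if (!is.null(g)) {
    dm <- grid_dim(g)
    pts <- rbind(p0, p1)
    if (any(pts[, 1] < 1 | pts[, 1] > dm["nx"] | pts[, 2] < 1 | pts[, 2] > dm["ny"])) {
      rlang::abort("traverse: pixel index outside the grid")
    }
  }
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  adx <- abs(dx); ady <- abs(dy)
  if (adx == 0L && ady == 0L) {
    return(cbind(ix = p0[1], iy = p0[2]))
  }
  if (adx >= ady) {
    i <- 0:adx
    x <- p0[1] + i * sign(dx)
    y <- p0[2] + sign(dy) * ((2L * i * ady + adx) %/% (2L * adx))
  } else {
    i <- 0:ady
    y <- p0[2] + i * sign(dy)
    x <- p0[1] + sign(dx) * ((2L * i * adx + ady) %/% (2L * ady))
  }
  cbind(ix = as.integer(x), iy = as.integer(y))
}

#' Gold path length between pixels on a Bresenham line
#'
#' Counts the gold pixels strictly between a gold source pixel and a water
#' tally pixel on the Bresenham line joining them (both endpoints
#' excluded) and multiplies by the pixel size — the raster analogue of the
#' distance traversed inside for the modified path length.
#'
#' @param g a `pixel_grid`.
#' @param sp gold source pixel `c(ix, iy)`.
#' @param tp water tally pixel `c(ix, iy)`.
#' @return DTI in nm.
#' @export
dti_pixels <- function(g, sp, tp) {
  stopifnot(inherits(g, "pixel_grid"))
  if (g$labels[sp[2], sp[1]] != 1L) rlang::abort("`sp` must be a gold pixel")
  if (g$labels[tp[2], tp[1]] != 0L) rlang::abort("`tp` must be a water pixel")
  line <- traverse(sp, tp, g)
  if (nrow(line) <= 2) return(0)
  mid <- line[-c(1, nrow(line)), , drop = FALSE]
  sum(g$labels[cbind(mid[, 2], mid[, 1])] == 1L) * g$pixel_size
}

#' Superposed dose map of a pixelated nanoparticle cluster
#'
#' Every gold pixel is an isotropic electron point source at its center;
#' for every water pixel the dose is the single-kernel superposition over
#' all sources, each evaluated at the modified path length
#' `MPL = GPL + (alpha - 1) * DTI`, with GPL the center-to-center distance
#' and DTI the Bresenham gold path of [dti_pixels()]. Gold pixels score no
#' dose (the map is the dose to water). The double loop is deterministic;
#' with the unity factor the Bresenham stage is skipped since
#' `(alpha - 1) * DTI = 0`.
#'
#' @param g a `pixel_grid` with at least one gold and one water pixel.
#' @param k a `dose_point_kernel` in water.
#' @param f a `rescaling_factor`.
#' @param source_weights optional per-gold-pixel source strength (electrons
#'   per pixel, in grid order); default 1 per gold pixel.
#' @return A `dose_map`: the grid, a dose matrix in keV/g per source
#'   electron per gold pixel (0 on gold pixels), and a `relative` flag.
#' @export
dose_map <- function(g, k, f = factor_unity(), source_weights = NULL) {
  stopifnot(inherits(g, "pixel_grid"), inherits(k, "dose_point_kernel"),
            inherits(f, "rescaling_factor"))
  gold <- which(g$labels == 1L, arr.ind = TRUE)   # (row=iy, col=ix)
  water <- which(g$labels == 0L, arr.ind = TRUE)
  if (nrow(gold) == 0 || nrow(water) == 0) {
    rlang::abort("dose_map needs at least one gold and one water pixel")
  }
  wts <- if (is.null(source_weights)) rep(1, nrow(gold)) else {
    stopifnot(length(source_weights) == nrow(gold))
    source_weights
  }
  ps <- g$pixel_size
  dose <- rep(0, nrow(water))
  for (i in seq_len(nrow(gold))) {
    dx <- (water[, 2] - gold[i, 2]) * ps
    dy <- (water[, 1] - gold[i, 1]) * ps
    dist <- sqrt(dx^2 + dy^2)
    if (f$alpha == 1) {
      dose <- dose + wts[i] * kernel_value(k, dist)
    } else {
      sp <- c(gold[i, 2], gold[i, 1])
      dti <- vapply(seq_len(nrow(water)), function(j) {
        dti_pixels(g, sp, c(water[j, 2], water[j, 1]))
      }, numeric(1))
      dose <- dose + wts[i] * kernel_value(k, mpl(dist, pmin(dti, dist), f))
    }
  }
  m <- matrix(0, nrow(g$labels), ncol(g$labels))
  m[water] <- dose
  structure(list(grid = g, dose = m, relative = FALSE,
                 factor = f$name, alpha = f$alpha),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d pixels, factor %s (alpha=%.4g), %s\n",
              ncol(x$dose), nrow(x$dose), x$factor, x$alpha,
              if (x$relative) "relative (max = 1)" else "keV/g per source electron"))
  invisible(x)
}

#' Normalize a dose map to its maximum
#'
#' Divides every water-pixel dose by the maximum water-pixel dose, giving
#' the relative dose distribution conventionally used to display cluster
#' dosimetry. Idempotent; errors on an all-zero map.
#'
#' @param m a `dose_map`.
#' @return The relative `dose_map` (max over water pixels = 1).
#' @export
normalize_relative <- function(m) {
  stopifnot(inherits(m, "dose_map"))
  mx <- max(m$dose[m$grid$labels == 0L])
  if (mx <= 0) rlang::abort("cannot normalize an all-zero dose map")
  m$dose <- m$dose / mx
  m$relative <- TRUE
  m
}

#' Write a dose map as CSV matrix plus JSON metadata
#' @param m a `dose_map`.
#' @param path output `.csv` path; `<path>.json` records pixel size,
#'   factor, and normalization.
#' @export
write_dose_map <- function(m, path) {
  stopifnot(inherits(m, "dose_map"))
  utils::write.table(m$dose, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_nm = m$grid$pixel_size, factor = m$factor,
         alpha = m$alpha, relative = m$relative),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}
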