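test_that("image thresholding separates gold from water on the mean RGB", {
  white <- array(1, dim = c(4, 5, 3))
  black <- array(0, dim = c(4, 5, 3))
  expect_equal(sum(grid_from_image(white)$labels), 0)
  expect_equal(sum(grid_from_image(black)$labels), 20)
  # one dark pixel
  img <- white
  img[2, 3, ] <- 0.1
  g <- grid_from_image(img, threshold = 0.4)
  expect_equal(which(g$labels == 1L), 4 * 2 + 2) # column-major index (2,3)
  expect_error(grid_from_image(matrix(1, 4, 5)), "RGB")
  expect_error(grid_from_image(white, threshold = 1.5), "threshold")
})

test_that("a 6400 x 3650 nm field at 50 nm pixels has 9344 pixels", {
  nx <- 6400 / 50
  ny <- 3650 / 50
  g <- pixel_grid(matrix(0L, ny, nx), pixel_size = 50)
  expect_equal(unname(grid_dim(g)), c(128, 73))
  expect_equal(n_pixels(g), 9344)
})

test_that("synthetic clusters are reproducible partitions of the grid", {
  g <- synth_cluster(40, 30, 5, c(2, 4), seed = 81)
  g2 <- synth_cluster(40, 30, 5, c(2, 4), seed = 81)
  expect_identical(g$labels, g2$labels)
  expect_equal(sum(g$labels == 1L) + sum(g$labels == 0L), 40 * 30)
  expect_gt(gold_fraction(g), 0)
  expect_error(synth_cluster(5, 5, 1, c(4, 4)), "cannot fit")
  # single 1-px blob: a handful of pixels
  g1 <- synth_cluster(20, 20, 1, c(1, 1), seed = 82)
  expect_true(sum(g1$labels) >= 1 && sum(g1$labels) <= 5)
})

test_that("Bresenham traversal covers the canonical lines", {
  h <- traverse(c(1, 1), c(4, 1))
  expect_equal(h[, "ix"], 1:4, ignore_attr = TRUE)
  expect_equal(h[, "iy"], rep(1, 4), ignore_attr = TRUE)
  d <- traverse(c(1, 1), c(4, 4))
  expect_equal(d[, "ix"], 1:4, ignore_attr = TRUE)
  expect_equal(d[, "iy"], 1:4, ignore_attr = TRUE)
  expect_equal(nrow(traverse(c(3, 3), c(3, 3))), 1)
  # steep and reversed lines still connect endpoints contiguously
  for (pts in list(list(c(1, 1), c(2, 7)), list(c(6, 2), c(1, 4)))) {
    ln <- traverse(pts[[1]], pts[[2]])
    expect_equal(unname(ln[1, ]), pts[[1]])
    expect_equal(unname(ln[nrow(ln), ]), pts[[2]])
    expect_true(all(abs(diff(ln[, 1])) <= 1 & abs(diff(ln[, 2])) <= 1))
  }
  g <- pixel_grid(matrix(0L, 5, 5))
  expect_error(traverse(c(0, 1), c(3, 3), g), "outside")
})

test_that("dti_pixels counts strictly intermediate gold pixels", {
  lab <- matrix(0L, 1, 6)
  lab[1, c(1, 3, 4)] <- 1L # gold at columns 1, 3, 4
  g <- pixel_grid(lab, pixel_size = 50)
  expect_equal(dti_pixels(g, c(1, 1), c(6, 1)), 2 * 50)
  expect_equal(dti_pixels(g, c(1, 1), c(2, 1)), 0)
  expect_error(dti_pixels(g, c(2, 1), c(6, 1)), "gold")
  expect_error(dti_pixels(g, c(1, 1), c(3, 1)), "water")
})

test_that("pixel DTI never exceeds the center-to-center distance", {
  set.seed(83)
  g <- synth_cluster(25, 25, 6, c(2, 4), seed = 83)
  gold <- which(g$labels == 1L, arr.ind = TRUE)
  water <- which(g$labels == 0L, arr.ind = TRUE)
  for (i in 1:100) {
    a <- gold[sample(nrow(gold), 1), ]
    b <- water[sample(nrow(water), 1), ]
    dti <- dti_pixels(g, c(a[2], a[1]), c(b[2], b[1]))
    gplc <- g$pixel_size * sqrt(sum((a - b)^2))
    expect_lte(dti, gplc)
  }
})

test_that("a single source reproduces the kernel and is radially symmetric", {
  lab <- matrix(0L, 11, 11); lab[6, 6] <- 1L
  g <- pixel_grid(lab, pixel_size = 50)
  k <- smooth_kernel()
  m <- dose_map(g, k, factor_unity())
  iy <- rep(1:11, 11); ix <- rep(1:11, each = 11)
  dist <- 50 * sqrt((ix - 6)^2 + (iy - 6)^2)
  expected <- kernel_value(k, dist)
  expected[dist == 0] <- 0 # the source pixel scores no dose
  expect_equal(as.vector(m$dose), expected)
  # symmetry: the four axial neighbours at equal distance get equal dose
  expect_equal(m$dose[6, 5], m$dose[6, 7])
  expect_equal(m$dose[5, 6], m$dose[7, 6])
  expect_equal(m$dose[4, 4], m$dose[8, 8])
})

test_that("dose maps superpose linearly over disjoint gold sets", {
  k <- smooth_kernel()
  labA <- matrix(0L, 9, 9); labA[2, 2] <- 1L
  labB <- matrix(0L, 9, 9); labB[8, 7] <- 1L
  labU <- labA | labB
  mA <- dose_map(pixel_grid(labA), k)
  mB <- dose_map(pixel_grid(labB), k)
  mU <- dose_map(pixel_grid(labU * 1L), k)
  water <- labU == 0
  expect_equal(mU$dose[water], (mA$dose + mB$dose)[water], tolerance = 1e-12)
})

test_that("rescaling with alpha > 1 never increases the dose", {
  k <- smooth_kernel()
  g <- synth_cluster(15, 15, 3, c(1, 2), seed = 84)
  m1 <- dose_map(g, k, factor_unity())
  m2 <- dose_map(g, k, factor_pdr(9.6, 1))
  w <- g$labels == 0L
  expect_true(all(m2$dose[w] <= m1$dose[w] + 1e-12))
  expect_true(any(m2$dose[w] < m1$dose[w])) # some rays do cross gold
})

test_that("relative normalization scales the maximum to one and is idempotent", {
  k <- smooth_kernel()
  g <- synth_cluster(12, 12, 2, c(1, 2), seed = 85)
  m <- dose_map(g, k)
  r1 <- normalize_relative(m)
  expect_equal(max(r1$dose[g$labels == 0L]), 1)
  r2 <- normalize_relative(r1)
  expect_equal(r2$dose, r1$dose)
  # ratios preserved
  w <- which(g$labels == 0L & m$dose > 0)
  expect_equal(m$dose[w] / max(m$dose[g$labels == 0L]), r1$dose[w])
  zero <- dose_map(g, dose_point_kernel(rep(0, 10)))
  expect_error(normalize_relative(zero), "all-zero")
})

test_that("pixel grids and dose maps round-trip through CSV/PNG/PGM inputs", {
  g <- synth_cluster(10, 8, 2, c(1, 2), seed = 86)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pixel_grid(g, tmp)
  g2 <- read_pixel_grid(tmp)
  expect_identical(g2$labels, g$labels)
  expect_equal(g2$pixel_size, 50)

  # PNG: dark pixels become gold
  png_path <- withr::local_tempfile(fileext = ".png")
  img <- array(1, dim = c(6, 7, 3))
  img[3, 4, ] <- 0
  png::writePNG(img, png_path)
  g3 <- read_pixel_grid(png_path)
  expect_equal(sum(g3$labels), 1)
  expect_equal(which(g3$labels == 1L, arr.ind = TRUE)[1, ],
               c(row = 3, col = 4))

  # ASCII PGM
  pgm_path <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "3 2", "255",
               "255 0 255", "255 255 255"), pgm_path)
  g4 <- read_pixel_grid(pgm_path)
  expect_equal(sum(g4$labels), 1)
  expect_equal(unname(grid_dim(g4)), c(3, 2))

  m <- dose_map(g, smooth_kernel())
  out <- withr::local_tempfile(fileext = ".csv")
  write_dose_map(m, out)
  expect_true(file.exists(paste0(out, ".json")))
  meta <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(meta$pixel_size_nm, 50)
})
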