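test_that("sphere sampling is uniform by volume and reproducible", {
  s <- sphere(10)
  p <- sample_in_sphere(s, 1e5, seed = 11)
  r3 <- (p$x^2 + p$y^2 + p$z^2)^(3 / 2) / s$radius^3
  expect_true(all(r3 <= 1 + 1e-12))
  # |p|^3 / R^3 ~ U(0,1): mean 0.5 within 3 sigma of the sample mean
  expect_lt(abs(mean(r3) - 0.5), 3 * sqrt(1 / 12 / 1e5))
  expect_identical(p, sample_in_sphere(s, 1e5, seed = 11))
})

test_that("rod sampling stays inside the cylinder with symmetric z", {
  rd <- rod(3, 12)
  p <- sample_in_rod(rd, 1e5, seed = 12)
  expect_true(all(p$x^2 + p$y^2 <= rd$radius^2 + 1e-12))
  expect_true(all(abs(p$z) <= rd$half_length))
  expect_lt(abs(mean(p$z)), 3 * rd$half_length / sqrt(3) / sqrt(1e5))
  expect_identical(p, sample_in_rod(rd, 1e5, seed = 12))
})

test_that("gpl is the symmetric Euclidean distance", {
  a <- tibble::tibble(x = 0, y = 0, z = 0)
  b <- tibble::tibble(x = 3, y = 4, z = 0)
  expect_equal(gpl(a, b), 5)
  expect_equal(gpl(b, a), 5)
  expect_equal(gpl(a, a), 0)
})

test_that("dti_sphere handles radial chords exactly", {
  s <- sphere(7)
  center <- tibble::tibble(x = 0, y = 0, z = 0)
  out <- tibble::tibble(x = 0, y = 0, z = 30)
  expect_equal(dti_sphere(center, out, s), 7)
  surf <- tibble::tibble(x = 0, y = 0, z = 7)
  expect_equal(dti_sphere(surf, out, s), 0, tolerance = 1e-9)
  expect_error(dti_sphere(out, center, s), "inside")
  expect_error(dti_sphere(center, surf, s), "outside")
})

test_that("dti_sphere matches the fine-step sampling oracle", {
  s <- sphere(20)
  set.seed(21)
  for (i in 1:50) {
    pr <- random_pair_sphere(s)
    g <- gpl(pr$sp, pr$tp)
    expect_lt(abs(dti_sphere(pr$sp, pr$tp, s) -
                    dti_oracle(pr$sp, pr$tp, inside_sphere(s), 1e4)),
              g / 1e4 + 1e-9)
  }
})

test_that("rod region classification follows the angular conditions", {
  rd <- rod(2, 10)
  expect_equal(classify_rod_region(tibble::tibble(x = 0, y = 0, z = 20), rd),
               "long_axis")
  expect_equal(classify_rod_region(tibble::tibble(x = 4, y = 0, z = 0), rd),
               "short_axis")
  # point exactly on the cone boundary: strict inequalities give neither
  expect_equal(classify_rod_region(tibble::tibble(x = 3, y = 0, z = 15), rd),
               "neither")
  expect_error(classify_rod_region(tibble::tibble(x = 0, y = 0, z = 0), rd),
               "outside")
})

test_that("region labels partition exterior points with no overlap", {
  rd <- rod(3, 9)
  set.seed(31)
  p <- purrr::map_dfr(1:500, function(i) random_point_outside_rod(rd))
  lab <- classify_rod_region(p, rd)
  expect_true(all(lab %in% c("long_axis", "short_axis", "neither")))
  rho <- sqrt(p$x^2 + p$y^2); az <- abs(p$z)
  long <- rho * rd$half_length < rd$radius * az & az > rd$half_length
  short <- az * rd$radius < rd$half_length * rho & rho > rd$radius
  expect_false(any(long & short)) # the two cones cannot both hold
  expect_equal(lab == "long_axis", long, ignore_attr = TRUE)
  expect_equal(lab == "short_axis", short, ignore_attr = TRUE)
})

test_that("dti_rod resolves axial and radial exits exactly", {
  rd <- rod(4, 10)
  o <- tibble::tibble(x = 0, y = 0, z = 0)
  expect_equal(dti_rod(o, tibble::tibble(x = 0, y = 0, z = 30), rd), 10)
  expect_equal(dti_rod(o, tibble::tibble(x = 12, y = 0, z = 0), rd), 4)
  expect_error(dti_rod(tibble::tibble(x = 20, y = 0, z = 0), o, rd), "inside")
  expect_error(dti_rod(o, tibble::tibble(x = 1, y = 0, z = 1), rd), "outside")
})

test_that("dti_rod matches the sampling oracle on oblique corner crossings", {
  rd <- rod(3, 8)
  set.seed(22)
  for (i in 1:50) {
    sp <- sample_in_rod(rd, 1)
    tp <- random_point_outside_rod(rd)
    g <- gpl(sp, tp)
    expect_lt(abs(dti_rod(sp, tp, rd) -
                    dti_oracle(sp, tp, inside_rod(rd), 1e4)),
              2 * g / 1e4 + 1e-9)
  }
})

test_that("DTI never exceeds GPL or the body diameter", {
  s <- sphere(15); rd <- rod(4, 12)
  set.seed(23)
  for (i in 1:200) {
    pr <- random_pair_sphere(s)
    d <- dti_sphere(pr$sp, pr$tp, s)
    expect_true(d >= 0 && d <= gpl(pr$sp, pr$tp) + 1e-9 && d <= 2 * s$radius + 1e-9)
    sp <- sample_in_rod(rd, 1); tp <- random_point_outside_rod(rd)
    dr <- dti_rod(sp, tp, rd)
    expect_true(dr >= 0 && dr <= gpl(sp, tp) + 1e-9 &&
                  dr <= 2 * sqrt(rd$radius^2 + rd$half_length^2) + 1e-9)
  }
})

test_that("mpl applies the rescaling identity", {
  expect_equal(mpl(100, 10, factor_unity()), 100)
  expect_equal(mpl(100, 0, factor_pdr(19.3, 1)), 100)
  f96 <- factor_pdr(9.6, 1)
  expect_equal(mpl(100, 10, f96), 186)
  expect_error(mpl(100, 110, f96), "exceed")
  # monotone non-decreasing in alpha; equality iff alpha = 1 or dti = 0
  expect_gt(mpl(100, 10, factor_pdr(2, 1)), mpl(100, 10, factor_unity()))
})

test_that("rod scoring volumes match the rejection-sampling oracle", {
  rd <- rod(3, 9)
  set.seed(24)
  n <- 2e5
  for (d in c(0, 5)) {
    t <- 2
    # long axis: box around the two frustums
    zmax <- rd$half_length + d + t
    rmax <- zmax * rd$radius / rd$half_length
    x <- runif(n, -rmax, rmax); y <- runif(n, -rmax, rmax); z <- runif(n, -zmax, zmax)
    rho <- sqrt(x^2 + y^2); az <- abs(z)
    inl <- az >= rd$half_length + d & az <= zmax & rho < az * rd$radius / rd$half_length
    vbox <- (2 * rmax)^2 * (2 * zmax)
    est <- mean(inl) * vbox
    se <- vbox * sd(inl) / sqrt(n)
    expect_lt(abs(scoring_volume_long(d, rd, t) - est), 3 * se)

    # short axis: box around the hollow-cylinder solid
    smax <- rd$radius + d + t
    zm <- smax * rd$half_length / rd$radius
    x <- runif(n, -smax, smax); y <- runif(n, -smax, smax); z <- runif(n, -zm, zm)
    rho <- sqrt(x^2 + y^2); az <- abs(z)
    ins <- rho >= rd$radius + d & rho <= smax & az < rho * rd$half_length / rd$radius
    vbox <- (2 * smax)^2 * (2 * zm)
    est <- mean(ins) * vbox
    se <- vbox * sd(ins) / sqrt(n)
    expect_lt(abs(scoring_volume_short(d, rd, t) - est), 3 * se)
  }
})

test_that("scoring volumes obey their thin-shell limits and monotonicity", {
  rd <- rod(2, 7)
  t <- 1e-6
  d <- 3
  expect_equal(scoring_volume_long(d, rd, t) / t,
               2 * pi * (rd$radius / rd$half_length)^2 * (rd$half_length + d)^2,
               tolerance = 1e-5)
  expect_equal(scoring_volume_short(d, rd, t) / t,
               4 * pi * rd$half_length * (rd$radius + d)^2 / rd$radius,
               tolerance = 1e-5)
  dd <- 0:10
  expect_true(all(diff(scoring_volume_long(dd, rd)) > 0))
  expect_true(all(scoring_volume_short(dd, rd) > 0))
})

test_that("decompose_paths returns consistent GPL/DTI/MPL triples", {
  s <- sphere(10)
  sp <- sample_in_sphere(s, 100, seed = 33)
  u <- matrix(rnorm(300), ncol = 3); u <- u / sqrt(rowSums(u^2))
  rt <- 10 + runif(100, 0.1, 50)
  tp <- tibble::tibble(x = u[, 1] * rt, y = u[, 2] * rt, z = u[, 3] * rt)
  pd <- decompose_paths(sp, tp, s, factor_pdr(19.3, 1))
  expect_true(all(pd$dti_nm <= pd$gpl_nm + 1e-9))
  expect_true(all(pd$mpl_nm >= pd$gpl_nm - 1e-12))
  expect_equal(pd$mpl_nm, pd$gpl_nm + 18.3 * pmin(pd$dti_nm, pd$gpl_nm))
})
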