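# Shared fixtures: analytic toy materials, small spectra, smooth kernels,
# and the fine-step segment-sampling oracle for DTI checks.

toy_pair <- function() toy_material_tables()

# flat four-bin spectrum at 8-12 keV: toy-water range ~1.2-2 um
toy_spectrum <- function() electron_spectrum(8:12, rep(1, 4))

# smooth analytic kernel: exponential decay over `range_nm`
smooth_kernel <- function(range_nm = 2000, bin_width = 1, scale = 1e15) {
  centers <- seq(bin_width / 2, range_nm - bin_width / 2, by = bin_width)
  dose_point_kernel(scale * exp(-centers / (range_nm / 6)),
                    bin_width = bin_width, medium = "test")
}

# fine-step sampling oracle for the distance traversed inside a convex body:
# probe `n_steps` midpoints along the segment and sum the in-body fraction.
dti_oracle <- function(ps, pt, inside, n_steps = 1e5) {
  lam <- (seq_len(n_steps) - 0.5) / n_steps
  dx <- pt$x - ps$x; dy <- pt$y - ps$y; dz <- pt$z - ps$z
  g <- sqrt(dx^2 + dy^2 + dz^2)
  inb <- inside(ps$x + lam * dx, ps$y + lam * dy, ps$z + lam * dz)
  mean(inb) * g
}

inside_sphere <- function(s) function(x, y, z) x^2 + y^2 + z^2 <= s$radius^2

inside_rod <- function(rd) function(x, y, z) {
  x^2 + y^2 <= rd$radius^2 & abs(z) <= rd$half_length
}

# random interior/exterior point pair generators (plain data frames)
random_pair_sphere <- function(s, d_max = 200) {
  sp <- sample_in_sphere(s, 1)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  rt <- s$radius + stats::runif(1, 1e-3, d_max)
  list(sp = sp, tp = tibble::tibble(x = u[1] * rt, y = u[2] * rt, z = u[3] * rt))
}

random_point_outside_rod <- function(rd, spread = 5) {
  repeat {
    p <- tibble::tibble(
      x = stats::runif(1, -spread * rd$radius, spread * rd$radius),
      y = stats::runif(1, -spread * rd$radius, spread * rd$radius),
      z = stats::runif(1, -spread * rd$half_length, spread * rd$half_length)
    )
    if (p$x^2 + p$y^2 > rd$radius^2 || abs(p$z) > rd$half_length) return(p)
  }
}
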