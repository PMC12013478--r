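test_that("vesselness parameters are validated", {
  expect_error(vesselness_params(scales = numeric(0)), "scales")
  expect_error(vesselness_params(scales = c(2, 1)), "scales")
  expect_error(vesselness_params(alpha = 0), "alpha")
  expect_error(vesselness_params(c = -1), "adaptive")
  p <- vesselness_params()
  expect_length(p$scales, 10)
  expect_equal(range(p$scales), c(1, 3.5))
})

test_that("the Hessian vanishes on constants and is exact on quadratics", {
  flat <- image_volume(array(3, c(12, 12, 12)))
  h <- suppressWarnings(hessian_at_scale(flat, 1.5))
  for (cmp in c("xx", "yy", "zz", "xy", "xz", "yz"))
    expect_equal(max(abs(h[[cmp]])), 0, tolerance = 1e-12)

  # f = x^2 on a 1 mm grid: d2f/dx2 = 2, gamma-normalized by sigma^2
  g <- seq(0, 19)
  vol <- image_volume(array(rep(g^2, 400), c(20, 20, 20)))
  h2 <- suppressWarnings(hessian_at_scale(vol, 1.5, gamma = 2))
  expect_equal(h2$xx[10, 10, 10], 2 * 1.5^2, tolerance = 1e-10)
  expect_equal(h2$yy[10, 10, 10], 0, tolerance = 1e-10)
  expect_equal(max(abs(h2$xy[5:15, 5:15, 5:15])), 0, tolerance = 1e-10)

  # mixed partial of f = x * y
  volxy <- image_volume(array(outer(g, g), c(20, 20, 20)))
  h3 <- suppressWarnings(hessian_at_scale(volxy, 1.5, gamma = 2))
  expect_equal(h3$xy[10, 10, 10], 1.5^2, tolerance = 1e-10)
})

test_that("Hessian components agree with finite differences of the smoothed volume", {
  # smooth analytic input: full quadratic form with cross terms
  n <- 15
  idx <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  f <- with(idx, 2 * x^2 + 3 * y^2 + z^2 + x * y - 2 * y * z + 5 * x + 1)
  vol <- image_volume(array(f, c(n, n, n)))
  sig <- 1.2
  h <- suppressWarnings(hessian_at_scale(vol, sig, gamma = 2))

  sm <- brute_force_smooth(vol$data, rep(sig, 3))
  cd2 <- function(a, sh) { # central second difference along axis sh
    d <- dim(a); out <- array(NA_real_, d)
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    if (sh == 1) out[i, j, k] <- a[i + 1, j, k] - 2 * a[i, j, k] + a[i - 1, j, k]
    if (sh == 2) out[i, j, k] <- a[i, j + 1, k] - 2 * a[i, j, k] + a[i, j - 1, k]
    out
  }
  cdxy <- function(a) {
    d <- dim(a); out <- array(NA_real_, d)
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    out[i, j, k] <- (a[i + 1, j + 1, k] - a[i + 1, j - 1, k] -
                       a[i - 1, j + 1, k] + a[i - 1, j - 1, k]) / 4
    out
  }
  core <- 7:9 # deep interior, clear of both kernel and difference borders
  expect_equal(h$xx[core, core, core],
               sig^2 * cd2(sm, 1)[core, core, core], tolerance = 1e-6)
  expect_equal(h$yy[core, core, core],
               sig^2 * cd2(sm, 2)[core, core, core], tolerance = 1e-6)
  expect_equal(h$xy[core, core, core],
               sig^2 * cdxy(sm)[core, core, core], tolerance = 1e-6)
})

test_that("eigenvalues are sorted by absolute value and match a dense solver", {
  # diagonal case: diag(-3, 1, -2) sorts to (1, -2, -3)
  ef <- eigenvalues_sorted(structure(
    list(xx = array(-3, c(1, 1, 1)), yy = array(1, c(1, 1, 1)),
         zz = array(-2, c(1, 1, 1)), xy = array(0, c(1, 1, 1)),
         xz = array(0, c(1, 1, 1)), yz = array(0, c(1, 1, 1)),
         spacing = c(1, 1, 1), sigma_voxels = 1, sigma_mm = 1, gamma = 2),
    class = "hessian_field"))
  expect_equal(c(ef$l1[1], ef$l2[1], ef$l3[1]), c(1, -2, -3))

  set.seed(42)
  n <- 8^3
  comp <- lapply(1:6, function(i) array(rnorm(n), c(8, 8, 8)))
  hf <- structure(list(xx = comp[[1]], yy = comp[[2]], zz = comp[[3]],
                       xy = comp[[4]], xz = comp[[5]], yz = comp[[6]],
                       spacing = c(1, 1, 1), sigma_voxels = 1, sigma_mm = 1,
                       gamma = 2), class = "hessian_field")
  ef2 <- eigenvalues_sorted(hf)
  worst <- 0
  for (i in seq_len(n)) {
    M <- matrix(c(comp[[1]][i], comp[[4]][i], comp[[5]][i],
                  comp[[4]][i], comp[[2]][i], comp[[6]][i],
                  comp[[5]][i], comp[[6]][i], comp[[3]][i]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev))]
    worst <- max(worst, abs(ev - c(ef2$l1[i], ef2$l2[i], ef2$l3[i])))
  }
  expect_lt(worst, 1e-10)
  # ordering invariant holds everywhere
  expect_true(all(abs(ef2$l1) <= abs(ef2$l2) + 1e-14))
  expect_true(all(abs(ef2$l2) <= abs(ef2$l3) + 1e-14))
})

test_that("single-scale response matches closed forms and the sign gate", {
  p <- vesselness_params(c = 1)
  # ideal bright tube (0, -L, -L): Ra = 1, Rb = 0, S-term -> 1 at L >> c
  v <- frangi_response_single_scale(const_eigen_field(0, -1e4, -1e4), p)
  expect_equal(v$data[1], 1 - exp(-2), tolerance = 1e-8)
  # dark tube under bright polarity is gated to zero
  expect_equal(frangi_response_single_scale(const_eigen_field(0, 1e4, 1e4),
                                            p)$data[1], 0)
  # flat structure: S = 0 kills the response
  expect_equal(frangi_response_single_scale(const_eigen_field(0, 0, 0),
                                            p)$data[1], 0)
})

test_that("the response peaks at the matching scale for a Gaussian cylinder", {
  vol <- gaussian_cylinder(n = 41, nz = 21, s = 1.5)
  scales <- seq(1, 3.5, length.out = 10)
  resp <- vapply(scales, function(s) {
    e <- eigenvalues_sorted(suppressWarnings(hessian_at_scale(vol, s)))
    frangi_response_single_scale(e, vesselness_params(c = 0.5))$data[21, 21, 11]
  }, numeric(1))
  # gamma = 2 scale selection: argmax within one scale step of the tube std
  expect_lte(abs(scales[which.max(resp)] - 1.5), diff(scales)[1] + 1e-12)
})

test_that("the response of a tube is invariant under axis permutation on iso grids", {
  volz <- gaussian_cylinder(n = 41, nz = 21, s = 1.5)
  volx <- image_volume(aperm(volz$data, c(3, 1, 2)))
  e1 <- eigenvalues_sorted(suppressWarnings(hessian_at_scale(volz, 1.5)))
  e2 <- eigenvalues_sorted(suppressWarnings(hessian_at_scale(volx, 1.5)))
  vz <- frangi_response_single_scale(e1, vesselness_params(c = 0.5))$data[21, 21, 11]
  vx <- frangi_response_single_scale(e2, vesselness_params(c = 0.5))$data[11, 21, 21]
  expect_lt(abs(vz - vx) / vz, 0.05)
})

test_that("the multi-scale map is ROI-masked, bounded, and scale-monotone", {
  ph <- recovery_phantom(shape = c(40, 40, 40), n_tubes = 2, seed = 3)
  roi <- ph$nawm_mask
  norm <- normalize_histogram(ph$image)

  flat_map <- suppressWarnings(
    frangi_vesselness(image_volume(array(0, dim(norm$data))), roi))
  expect_equal(max(flat_map$data), 0)

  p_few <- vesselness_params(scales = c(1, 2))
  p_more <- vesselness_params(scales = c(1, 1.5, 2, 3))
  m1 <- suppressWarnings(frangi_vesselness(norm, roi, p_few))
  m2 <- suppressWarnings(frangi_vesselness(norm, roi, p_more))
  expect_true(all(m2$data >= m1$data - 1e-12)) # max over a superset of scales
  expect_true(all(m1$data >= 0 & m1$data <= 1))
  expect_equal(max(m1$data[!roi$data]), 0)
  expect_error(suppressWarnings(
    frangi_vesselness(norm, binary_mask(array(FALSE, dim(norm$data))))),
    "empty ROI")
})

test_that("with adaptive c the map is invariant to intensity scaling", {
  ph <- recovery_phantom(shape = c(40, 40, 40), n_tubes = 2, seed = 3)
  roi <- ph$nawm_mask
  v <- image_volume(ph$image$data / max(ph$image$data))
  p <- vesselness_params(scales = c(1.5, 2.5))
  base <- suppressWarnings(frangi_vesselness(v, roi, p))
  for (a in c(0.02, 7)) {
    scaled <- image_volume(a * v$data)
    expect_equal(suppressWarnings(frangi_vesselness(scaled, roi, p))$data,
                 base$data, tolerance = 1e-8)
  }
})
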