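test_that("closed-form estimator matches dense quadrature on random polygons", {
  set.seed(11)
  for (i in 1:10) {
    xy <- random_star_polygon(150 + 10 * i)
    est <- efd_estimate(xy, 10)$coef
    orc <- efd_quadrature_oracle(xy, 10)
    expect_lt(max(abs(est - orc)), 1e-6)
  }
})

test_that("translation moves only the dc terms", {
  set.seed(12)
  xy <- random_star_polygon(200)
  e0 <- efd_estimate(xy, 8)
  e1 <- efd_estimate(cbind(xy[, 1] + 13.7, xy[, 2] - 4.2), 8)
  expect_equal(e0$coef, e1$coef, tolerance = 1e-12)
  expect_equal(e1$dc - e0$dc, c(13.7, -4.2), tolerance = 1e-9)
})

test_that("a circle estimates to a first-harmonic circle of the same radius", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  R <- 37.5
  e <- efd_normalize(efd_estimate(cbind(R * cos(th), R * sin(th)), 5))
  expect_equal(unname(e$coef[1, "d"]), 1, tolerance = 1e-6)
  expect_equal(unname(e$scale_px), R, tolerance = R * 1e-3)
  expect_lt(max(abs(e$coef[2:5, ])), 1e-6)
})

test_that("normalized coefficients are invariant to similarity transforms and start vertex", {
  set.seed(13)
  shapes <- list(make_template(0.5, 0.2), make_template(0.35, 0.1),
                 random_star_polygon(180))
  for (xy in shapes) {
    base <- flatten_coeffs(efd_normalize(efd_estimate(xy, 10)))
    for (i in 1:8) {
      tr <- spermshape:::transform_contour(
        xy, rotation = runif(1, 0, 2 * pi), scale = runif(1, 0.2, 8),
        shift = runif(2, -100, 100))
      k <- sample.int(nrow(tr), 1)
      tr <- tr[c(k:nrow(tr), seq_len(k - 1)), ]
      v <- flatten_coeffs(efd_normalize(efd_estimate(tr, 10)))
      expect_lt(max(abs(v - base)), 1e-9)
    }
  }
})

test_that("mirror-image contours normalize to mirrored coefficients with d1 unchanged", {
  xy <- make_template(0.5, 0.2)
  v <- flatten_coeffs(efd_normalize(efd_estimate(xy, 10)))
  vm <- flatten_coeffs(efd_normalize(efd_estimate(
    ensure_ccw(cbind(xy[, 1], -xy[, 2])), 10)))
  expect_equal(vm[["d1"]], v[["d1"]], tolerance = 1e-9)
})

test_that("reconstruction error is non-increasing in the harmonic count", {
  xy <- make_template(0.45, 0.15, 512)
  e <- efd_estimate(xy, 20)
  nearest_rms <- function(rec) {
    d <- sqrt(outer(rec[, 1], xy[, 1], "-")^2 + outer(rec[, 2], xy[, 2], "-")^2)
    sqrt(mean(apply(d, 1, min)^2))
  }
  errs <- vapply(c(1, 2, 5, 10, 20), function(N) {
    nearest_rms(efd_reconstruct(e, n_harmonics = N, n_points = 256))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  # at N = 20 the approximation is tight relative to the perimeter
  expect_lt(errs[5], 0.01 * polygon_perimeter(xy))
})

test_that("flattening gives 4N - 3 free parameters and inverts exactly", {
  e <- efd_normalize(efd_estimate(make_template(0.5, 0.15), 20))
  v <- flatten_coeffs(e)
  expect_length(v, 77)
  expect_identical(names(v)[1:5], c("d1", "a2", "b2", "c2", "d2"))
  e1 <- efd_normalize(efd_estimate(make_template(0.5, 0.15), 1))
  expect_length(flatten_coeffs(e1), 1)

  back <- unflatten_coeffs(v, scale_px = e$scale_px)
  expect_equal(flatten_coeffs(back), v, tolerance = 1e-15)
  expect_equal(back$coef[1, c("a", "b", "c")], c(a = 1, b = 0, c = 0))

  raw <- efd_estimate(make_template(0.5, 0.15), 5)
  expect_error(flatten_coeffs(raw), "normalized")
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(efd_estimate(cbind(c(0, 1), c(0, 0)), 5), "at least 3")
  line <- cbind(c(0, 1, 2, 1), c(0, 0, 0, 0))
  expect_error(efd_estimate(line, 5), "collinear|zero-perimeter")
  e <- efd_normalize(efd_estimate(make_template(0.5, 0), 5))
  expect_error(efd_reconstruct(e, n_harmonics = 0), ">= 1")
  expect_error(efd_reconstruct(e, n_harmonics = 9), "exceeds")
})
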