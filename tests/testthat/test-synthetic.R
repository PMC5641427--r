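test_that("template parameters are validated by name", {
  expect_error(make_template(0, 0), "aspect")
  expect_error(make_template(1.2, 0), "aspect")
  expect_error(make_template(0.5, 0.4), "hook_strength")
  expect_error(make_template(0.5, 0, n_points = 16), "n_points")
})

test_that("templates hit the requested first-harmonic aspect ratio exactly", {
  circ <- make_template(1, 0, 256)
  expect_equal(measured_d1(circ, 1), 1, tolerance = 1e-9)
  for (a in c(0.3, 0.5, 0.8)) {
    for (h in c(0, 0.3)) {
      expect_equal(measured_d1(make_template(a, h, 256)), a, tolerance = 1e-8)
    }
  }
})

test_that("the hook is a genuine higher-harmonic asymmetric deformation", {
  xy <- make_template(0.5, 0.2, 256)
  expect_true(is_simple_polygon(xy))
  co <- efd_normalize(efd_estimate(xy, 10))$coef
  expect_gt(max(abs(co[2:10, ])), 0.01)
  # hookless templates are up-down symmetric up to the fixed bend; the hook
  # breaks that symmetry at odd y-harmonics
  co0 <- efd_normalize(efd_estimate(make_template(0.5, 0, 256), 10))$coef
  expect_gt(abs(co[3, "c"] - co0[3, "c"]), 1e-3)
})

test_that("population sampling respects the requested d1 distribution", {
  # zero variance: every specimen carries the population mean
  recs <- sample_population(population_spec(20, cv_aspect = 0, rng_seed = 3))
  expect_true(all(ground_truth(recs)$true_aspect == 0.5))

  # sample mean within 3 SE of the target
  recs <- sample_population(population_spec(200, mean_aspect = 0.5,
                                            cv_aspect = 0.05, rng_seed = 7))
  se <- 0.5 * 0.05 / sqrt(200)
  expect_lt(abs(mean(ground_truth(recs)$true_aspect) - 0.5), 3 * se)

  # exact abnormal count
  recs <- sample_population(population_spec(100, abnormal_fraction = 0.1,
                                            rng_seed = 5))
  expect_identical(sum(ground_truth(recs)$is_abnormal), 10L)
})

test_that("identical spec and seed give identical populations", {
  s <- population_spec(25, abnormal_fraction = 0.08, rng_seed = 42)
  expect_identical(sample_population(s), sample_population(s))
})

test_that("infeasible truncation is reported as an error", {
  expect_error(sample_population(population_spec(10, mean_aspect = 0.9,
                                                 cv_aspect = 2, rng_seed = 1)),
               "infeasible")
})

test_that("specimen contours are simple and measured d1 equals ground truth", {
  recs <- sample_population(population_spec(30, abnormal_fraction = 0.1,
                                            rng_seed = 9))
  gt <- ground_truth(recs)
  for (i in seq_along(recs)) {
    expect_true(is_simple_polygon(recs[[i]]$contour))
    expect_equal(measured_d1(recs[[i]]$contour), gt$true_aspect[i],
                 tolerance = 1e-7)
  }
})

test_that("rasterization follows the center-in-or-on-polygon convention", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  img <- rasterize_specimen(sq, image_px = 14)
  expect_identical(sum(img > 0), 100L)

  expect_error(rasterize_specimen(sq, image_px = 10), "at least")

  # clean rendering of any specimen segments to a single component
  rec <- sample_population(population_spec(1, rng_seed = 2))[[1]]
  img <- rasterize_specimen(rec)
  lab <- label_components(img > 0)
  expect_identical(max(lab), 1L)
})

test_that("imaging round trip recovers d1 within 0.01 under blur and noise", {
  xy <- make_template(0.5, 0.12, 256) * 105
  set.seed(31)
  img <- rasterize_specimen(xy, psf_sd = 1, noise_sd = 5)
  ot <- otsu_threshold(img)
  chains <- extract_contours(ot$mask, min_area = 200)
  expect_length(chains, 1)
  d1 <- measured_d1(chain_to_contour(chains[[1]]))
  expect_lt(abs(d1 - 0.5), 0.01)
})

test_that("full pipeline mean d1 matches mean_aspect for noiseless populations", {
  recs <- sample_population(population_spec(
    20, mean_aspect = 0.52, cv_aspect = 0, hook_strength = 0,
    coef_noise_sd = 0, rng_seed = 4))
  d1 <- efd_table(recs, 20)$matrix[, "d1"]
  expect_lt(abs(mean(d1) - 0.52), 1e-3)
})
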