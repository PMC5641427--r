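# Frozen reference p-values for 20 seeded two-sample datasets, computed once
# with an independent implementation (SciPy 1.17: ttest_ind pooled two- and
# one-sided, the F variance-ratio test against the F distribution, the
# two-sample Kolmogorov-Smirnov statistic referred to the asymptotic
# Kolmogorov distribution, and shapiro on the first sample). Columns:
# set, t_two, t_greater, f_var, ks_two, shapiro_x.
REFERENCE_P <- matrix(byrow = TRUE, ncol = 6, data = c(
  1, 0.47076828317, 0.235384141585, 0.925681802003, 0.721037012368, 0.102212770013,
  2, 0.847970819788, 0.423985409894, 0.103551935526, 0.259056448678, 0.123265919178,
  3, 0.032346762622, 0.016173381311, 0.540496293148, 0.0561018936456, 0.953027403883,
  4, 0.105942983958, 0.0529714919788, 0.0565733726553, 0.0172912508167, 0.131833849554,
  5, 0.556483430166, 0.278241715083, 0.368162157543, 0.564137458196, 0.575890080623,
  6, 0.00170726859035, 0.000853634295176, 0.874699676624, 0.00132180430021, 0.0451224978772,
  7, 0.0106687464742, 0.0053343732371, 0.012382382705, 0.135091895875, 0.281066266977,
  8, 0.00801294545725, 0.00400647272862, 0.131747116684, 0.00430278110703, 0.427197673788,
  9, 0.0377684227173, 0.0188842113587, 0.0280163069597, 0.0319983400785, 0.500425497219,
  10, 0.00346372232894, 0.00173186116447, 0.653828707063, 0.00365780064229, 0.844688992279,
  11, 0.0212229148947, 0.0106114574473, 0.039322988583, 0.0145234440203, 0.43049832658,
  12, 0.00960149414396, 0.00480074707198, 0.00453432151528, 0.0379863785899, 0.0695020690829,
  13, 0.0302798606829, 0.0151399303415, 0.0003189971195, 0.00225168059585, 0.353506414681,
  14, 0.0110057620297, 0.00550288101487, 0.0236085215694, 0.0102436694581, 0.95787783149,
  15, 0.0140769410319, 0.00703847051597, 0.0834517408428, 0.00162855211293, 0.993478377118,
  16, 0.00172476778276, 0.000862383891378, 0.00130264733951, 0.00282017768727, 0.511060015815,
  17, 1.75782925362e-05, 8.78914626812e-06, 0.000201548686876, 0.000310004381491, 0.656569174195,
  18, 0.0104495397645, 0.00522476988226, 0.0111709171514, 0.00538972180944, 0.64357760236,
  19, 1.49142081411e-06, 7.45710407054e-07, 0.000100725295205, 1.38775635272e-05, 0.492113937645,
  20, 1.31614369327e-05, 6.58071846634e-06, 0.000145982184465, 0.000441549614818, 0.339429380468))

# regenerate the exact datasets the reference values were computed on
reference_datasets <- function() {
  set.seed(20260923)
  lapply(1:20, function(i) {
    n1 <- sample(8:40, 1); n2 <- sample(8:40, 1)
    list(x = round(rnorm(n1, 10 + i / 7, 1 + i / 10), 6),
         y = round(rnorm(n2, 10, 1.3), 6))
  })
}

test_that("classic test p-values agree with the independent reference", {
  sets <- reference_datasets()
  for (i in 1:20) {
    x <- sets[[i]]$x; y <- sets[[i]]$y
    expect_equal(classic_test(x, y, "t_two")$p_value, REFERENCE_P[i, 2],
                 tolerance = 1e-6)
    expect_equal(classic_test(x, y, "t_one", tail = "greater")$p_value,
                 REFERENCE_P[i, 3], tolerance = 1e-6)
    expect_equal(classic_test(x, y, "f_var")$p_value, REFERENCE_P[i, 4],
                 tolerance = 1e-6)
    expect_equal(classic_test(x, y, "ks_two")$p_value, REFERENCE_P[i, 5],
                 tolerance = 1e-6)
    expect_equal(classic_test(x, kind = "shapiro")$p_value, REFERENCE_P[i, 6],
                 tolerance = 1e-6)
  }
})

test_that("degenerate and invalid samples are handled explicitly", {
  r <- classic_test(c(1, 2, 3), c(1, 2, 3), "t_two")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(71)
  x <- rnorm(12)
  expect_equal(classic_test(x, x + 5, "f_var")$statistic, 1, tolerance = 1e-9)
  expect_error(classic_test(1, c(1, 2), "t_two"), "n >= 2")
  expect_error(classic_test(rep(1, 5), kind = "shapiro"), "constant")
  expect_error(classic_test(c(1, 2), kind = "shapiro"), "3 <= n")
})

test_that("significance labels follow the stated convention", {
  expect_identical(significance_label(c(0.2, 0.05, 0.049, 0.01, 0.0099, 0.0009)),
                   c("n.s.", "n.s.", "*", "*", "**", "***"))
  expect_error(significance_label(1.2), "\\[0, 1\\]")
})

test_that("steel-dwass gives p near 1 for identical groups and needs k >= 3", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5), c = c(1, 2, 3, 4, 5))
  expect_true(all(steel_dwass(g)$p_value > 0.999))
  expect_error(steel_dwass(g[1:2]), "rank-sum")
  expect_error(steel_dwass(list(a = 1, b = c(1, 2), c = c(1, 2))), "n >= 2")
})

test_that("steel-dwass p-values are invariant to group relabeling", {
  set.seed(72)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2), d = rnorm(8))
  p1 <- sort(steel_dwass(g)$p_value)
  p2 <- sort(steel_dwass(g[c(3, 1, 4, 2)])$p_value)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("steel-dwass agrees with the familywise permutation null on small groups", {
  set.seed(73)
  g <- list(a = c(3, 5, 6, 7, 8), b = c(1, 2, 4, 4, 6), c = c(6, 7, 8, 9, 11))
  p_asym <- steel_dwass(g)$p_value
  p_perm <- permutation_steel_dwass(g, n_perm = 2e4)
  expect_lt(max(abs(p_asym - p_perm)), 0.02)
})

test_that("familywise type-I error stays controlled under the null", {
  set.seed(74)
  rej <- 0; B <- 2000
  for (b in seq_len(B)) {
    g <- split(rnorm(80), rep(1:4, each = 20))
    if (any(steel_dwass(g)$p_value < 0.05)) rej <- rej + 1
  }
  expect_lte(rej / B, 0.07)
})

test_that("percent difference uses the reference-group convention", {
  expect_equal(percent_difference(0.5, 0.4715), 5.7, tolerance = 1e-9)
  expect_equal(percent_difference(3.14, 3.14), 0)
  expect_equal(percent_difference(0.5, 0.515), -3, tolerance = 1e-9)
  expect_error(percent_difference(0, 1), "positive")
})
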