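# build a coefficient matrix whose first column is named d1, embedding a
# low-dimensional configuration in a wider zero-padded space
embed_matrix <- function(xy, p = 9) {
  m <- matrix(0, nrow(xy), p)
  m[, 1:2] <- xy
  colnames(m) <- c("d1", paste0(c("a", "b", "c", "d"), rep(2:3, each = 4)))[1:p]
  rownames(m) <- paste0("s", seq_len(nrow(xy)))
  m
}

test_that("contribution rates match the closed-form planar eigenvalues", {
  # 4 points (+-1, 0), (0, +-0.5): covariance diag(2/3, 1/6) with divisor n-1
  m <- embed_matrix(rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5)))
  fit <- efd_pca(m)
  expect_equal(fit$eigenvalues[1:2], c(2/3, 1/6), tolerance = 1e-12)
  expect_equal(fit$contribution_rates[1:2], c(0.8, 0.2), tolerance = 1e-12)
})

test_that("contribution rates always sum to one and survive row duplication", {
  set.seed(51)
  m <- matrix(rnorm(20 * 9), 20, 9,
              dimnames = list(NULL, colnames(embed_matrix(cbind(0, 0)))))
  fit <- efd_pca(m)
  expect_equal(sum(fit$contribution_rates), 1, tolerance = 1e-12)
  fit2 <- efd_pca(rbind(m, m))
  expect_equal(abs(fit2$eigenvectors[, 1]), abs(fit$eigenvectors[, 1]),
               tolerance = 1e-9)
  expect_equal(fit2$contribution_rates[1:8], fit$contribution_rates[1:8],
               tolerance = 1e-9)
})

test_that("scores are centered with diagonal covariance equal to the eigenvalues", {
  set.seed(52)
  m <- matrix(rnorm(30 * 9), 30, 9,
              dimnames = list(NULL, colnames(embed_matrix(cbind(0, 0)))))
  fit <- efd_pca(m)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-9)
  cv <- cov(fit$scores)
  expect_lt(max(abs(cv - diag(fit$eigenvalues))), 1e-9)
})

test_that("the sign convention pins PC1 to non-negative d1 and other PCs to a positive peak", {
  set.seed(53)
  recs <- sample_population(population_spec(60, rng_seed = 53))
  fit <- efd_pca(efd_table(recs, 10)$matrix)
  expect_gte(fit$eigenvectors["d1", 1], 0)
  for (k in 2:5) {
    expect_gt(fit$eigenvectors[which.max(abs(fit$eigenvectors[, k])), k], 0)
  }
})

test_that("NaN rows are rejected naming the specimens", {
  m <- embed_matrix(rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5)))
  m["s3", 2] <- NaN
  expect_error(efd_pca(m), "s3")
})

test_that("factor loadings are correlations with the scores", {
  set.seed(54)
  m <- matrix(rnorm(40 * 9), 40, 9,
              dimnames = list(NULL, colnames(embed_matrix(cbind(0, 0)))))
  fit <- efd_pca(m)
  L <- factor_loadings(fit, m, n_pcs = 3)
  for (j in 1:9) {
    for (k in 1:3) {
      expect_equal(L[j, k + 1], cor(m[, j], fit$scores[, k]), tolerance = 1e-9)
    }
  }
  expect_true(all(abs(as.matrix(L[, 2:4])) <= 1 + 1e-12))

  # a variable equal to a score correlates perfectly with it
  m2 <- cbind(m, proxy = fit$scores[, 1])
  fit2 <- efd_pca(m2)
  L2 <- factor_loadings(fit2, m2)
  expect_gt(abs(L2$PC1[L2$variable == "proxy"]), 0.999)

  # zero-variance variable: loading zero with a warning
  m3 <- m; m3[, "b2"] <- 5
  fit3 <- efd_pca(m3)
  expect_warning(L3 <- factor_loadings(fit3, m3), "zero-variance")
  expect_identical(L3$PC1[L3$variable == "b2"], 0)
})

test_that("reconstruction along a PC is linear in the score multiple", {
  recs <- sample_population(population_spec(50, rng_seed = 55))
  tab <- efd_table(recs, 10)
  fit <- efd_pca(tab$matrix)

  mean_contour <- reconstruct_along_pc(fit, 1, 0)
  expect_equal(mean_contour,
               efd_reconstruct(unflatten_coeffs(fit$mean_vector)),
               tolerance = 1e-12)

  # +-2 SD coefficient vectors sit symmetrically about the mean vector
  vplus <- fit$mean_vector + 2 * sqrt(fit$eigenvalues[1]) * fit$eigenvectors[, 1]
  vminus <- fit$mean_vector - 2 * sqrt(fit$eigenvalues[1]) * fit$eigenvectors[, 1]
  expect_equal((vplus + vminus) / 2, fit$mean_vector, tolerance = 1e-12)

  # d1 of the +-2 SD shapes differs by 4 sqrt(lambda_1) e_d1 (linear algebra)
  d1p <- vplus[["d1"]]; d1m <- vminus[["d1"]]
  expect_equal(d1p - d1m, 4 * sqrt(fit$eigenvalues[1]) * fit$eigenvectors["d1", 1],
               tolerance = 1e-12)

  expect_error(reconstruct_along_pc(fit, 1, 4), "<= 3")
})

test_that("the abnormality filter excludes planted outliers and nothing else", {
  recs <- sample_population(population_spec(120, abnormal_fraction = 0.1,
                                            rng_seed = 56))
  gt <- ground_truth(recs)
  flt <- filter_abnormal(efd_table(recs, 20)$matrix, threshold = 0.55)
  expect_setequal(flt$abnormal_ids, gt$specimen_id[gt$is_abnormal])

  # homogeneous population: no exclusions at the default threshold
  recs0 <- sample_population(population_spec(120, rng_seed = 57))
  flt0 <- filter_abnormal(efd_table(recs0, 20)$matrix, threshold = 0.55)
  expect_length(flt0$abnormal_ids, 0)

  # infinite threshold: a no-op filter
  fltInf <- filter_abnormal(efd_table(recs, 20)$matrix, threshold = Inf)
  expect_identical(nrow(fltInf$normal), length(recs))
})

test_that("the pass-2 mean shape has the mean d1 of the retained set", {
  recs <- sample_population(population_spec(80, abnormal_fraction = 0.1,
                                            rng_seed = 58))
  flt <- filter_abnormal(efd_table(recs, 20)$matrix, threshold = 0.55)
  expect_equal(flt$pass2$mean_vector[["d1"]], mean(flt$normal[, "d1"]),
               tolerance = 1e-6)
})
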