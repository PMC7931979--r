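test_that("pca handles rank-1 data, missing features and orthonormality", {
  # sample vectors s, 2s, 3s: all variation along one direction
  s <- c(1, 2, 5, 9, 3)
  m <- cbind(a = s, b = 2 * s, c = 3 * s)
  ds <- make_dataset(m)
  pr <- pca(ds, scale = FALSE, n_components = 2)
  expect_equal(pr$variance_explained[1], 1.0, tolerance = 1e-12)

  # loadings columns are orthonormal
  set.seed(31)
  m2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m2[7, 2] <- NA
  ds2 <- make_dataset(m2)
  pr2 <- pca(ds2, n_components = 3)
  expect_equal(pr2$n_features_used, 49L)  # complete-case rule
  expect_equal(crossprod(pr2$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading element is positive
  for (j in seq_len(ncol(pr2$loadings)))
    expect_gt(pr2$loadings[which.max(abs(pr2$loadings[, j])), j], 0)
  # variance fractions are non-increasing and bounded by one
  expect_true(all(diff(pr2$variance_explained) <= 1e-12))
  expect_lte(sum(pr2$variance_explained), 1 + 1e-12)
})

test_that("pca errors and warnings follow the missing-value policy", {
  m <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("s1", "s2")))
  m[, 1][1:4] <- NA
  expect_error(pca(make_dataset(m)), "complete feature")

  m2 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("s", 1:3)))
  m2[3, ] <- 7  # zero variance
  expect_warning(pr <- pca(make_dataset(m2)), "zero-variance")
  expect_equal(pr$n_features_used, 9L)

  # k distinct sample profiles give at most k-1 nonzero components
  base <- rnorm(20)
  m3 <- cbind(s1 = base, s2 = base + rnorm(20), s3 = base, s4 = base + 1)
  m3 <- cbind(m3, s5 = m3[, "s2"])  # duplicate profile
  pr3 <- pca(make_dataset(m3), scale = FALSE, n_components = 4)
  expect_lte(sum(pr3$variance_explained > 1e-10), 3)
})

test_that("UPGMA dendrogram reproduces hand-computed merges", {
  # 1-D samples at 0, 1, 10: d(A,B)=1, d(A,C)=10, d(B,C)=9
  m <- matrix(c(0, 1, 10), 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  tr <- sample_dendrogram(make_dataset(m))
  expect_equal(tr$height, c(1, 9.5))
  expect_equal(tr$labels, c("A", "B", "C"))

  # identical samples merge at height zero
  m2 <- matrix(c(1, 2, 1, 2, 5, 9), 2, 3,
               dimnames = list(NULL, c("x", "y", "z")))
  tr2 <- sample_dendrogram(make_dataset(m2))
  expect_equal(min(tr2$height), 0)

  expect_error(sample_dendrogram(make_dataset(matrix(1:3, 3, 1,
    dimnames = list(NULL, "only")))), "two samples")
})

test_that("dendrogram heights are non-decreasing and match naive UPGMA", {
  set.seed(41)
  for (i in 1:100) {
    ns <- sample(3:9, 1)
    m <- matrix(rnorm(ns * 12), 12, ns,
                dimnames = list(NULL, paste0("s", seq_len(ns))))
    tr <- sample_dendrogram(make_dataset(m))
    expect_true(all(diff(tr$height) >= -1e-10))
    expect_equal(tr$height, oracle_upgma_heights(m), tolerance = 1e-9)
  }
})

test_that("sample summaries use type-7 quantiles and flag degenerate samples", {
  m <- cbind(s1 = c(1, 2, 3, 4), s2 = c(5, 5, 5, 5), s3 = c(NA, 1, NA, 2))
  ss <- sample_summaries(make_dataset(m))
  t1 <- ss$table[ss$table$sample == "s1", ]
  expect_equal(t1$median, 2.5)
  expect_equal(t1$q1, 1.75)
  expect_equal(t1$q3, 3.25)
  t2 <- ss$table[ss$table$sample == "s2", ]
  expect_equal(t2$sd, 0)
  expect_true(t2$degenerate)
  t3 <- ss$table[ss$table$sample == "s3", ]
  expect_equal(t3$n_observed, 2L)
  expect_equal(t3$n_missing, 2L)

  # all-missing sample: summaries missing, flagged
  m2 <- cbind(s1 = c(1, 2, 3), s2 = c(NA_real_, NA, NA))
  ss2 <- sample_summaries(make_dataset(m2))
  row <- ss2$table[ss2$table$sample == "s2", ]
  expect_true(row$all_missing)
  expect_true(is.na(row$mean))

  # quantiles agree with brute-force sorting definitions on random vectors
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1))
    ssr <- sample_summaries(make_dataset(cbind(s1 = x, s2 = x)))
    r1 <- ssr$table[1, ]
    xs <- sort(x); n <- length(xs)
    bf_q <- function(prob) {
      h <- (n - 1) * prob + 1
      xs[floor(h)] + (h - floor(h)) * (xs[min(floor(h) + 1, n)] - xs[floor(h)])
    }
    expect_equal(r1$median, bf_q(0.5), tolerance = 1e-12)
    expect_equal(r1$q1, bf_q(0.25), tolerance = 1e-12)
    expect_equal(r1$q3, bf_q(0.75), tolerance = 1e-12)
  }
})

test_that("feature_profile summarises groups and suggests near matches", {
  m <- matrix(c(1, 1, 1, 2, 2, 2), 1, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  ds <- make_dataset(m, groups = rep(c("ctrl", "trt"), each = 3))
  fp <- feature_profile(ds, "g1", "group")
  expect_equal(fp$summary$mean[fp$summary$group == "ctrl"], 1)
  expect_equal(fp$summary$mean[fp$summary$group == "trt"], 2)
  expect_equal(sum(fp$summary$n), 6L)  # group ns sum to sample count

  # single-sample group: quartiles collapse onto the value
  ds2 <- make_dataset(matrix(c(3, 7, 7), 1, 3), groups = c("a", "b", "b"))
  fp2 <- feature_profile(ds2, "g1", "group")
  a <- fp2$summary[fp2$summary$group == "a", ]
  expect_equal(c(a$q1, a$median, a$q3), c(3, 3, 3))

  # missing values excluded per group, n_missing reported
  ds3 <- make_dataset(matrix(c(1, NA, 5, 6), 1, 4),
                      groups = c("a", "a", "b", "b"))
  fp3 <- feature_profile(ds3, "g1", "group")
  aa <- fp3$summary[fp3$summary$group == "a", ]
  expect_equal(aa$mean, 1)
  expect_equal(aa$n_missing, 1L)

  expect_error(feature_profile(ds, "g1_typo", "group"), "did you mean")
})
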