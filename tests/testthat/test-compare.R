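test_that("is_significant uses strict inequalities and a missing-means-not policy", {
  t <- thresholds(0.05, "fdr", 1)
  st <- make_stats(p = c(.001, .01, .001, .001),
                   fdr = c(.01, .05, .01, .01),
                   lfc = c(2, 2, 1, NA))
  expect_identical(is_significant(st, t), c(TRUE, FALSE, FALSE, FALSE))
  # fdr = 0.05 exactly and |lfc| = 1 exactly both fail; missing lfc fails

  tp <- thresholds(0.05, "p", 0)
  stp <- make_stats(p = c(.01, NA), fdr = c(.5, NA), lfc = c(0.1, 0.1))
  expect_identical(is_significant(stp, tp), c(TRUE, FALSE))

  expect_error(thresholds(1.5), "alpha")
  expect_error(thresholds(0.05, "fdr", -1), "lfc_min")
})

test_that("classify_features matches its definition on the worked examples", {
  t <- thresholds(0.05, "fdr", 1)
  m <- identity_pair(c("f1", "f2", "f3", "f4"))
  sa <- make_stats(p = rep(.001, 4), fdr = c(.01, .01, .01, .5),
                   lfc = c(2, 2, 2, 0.1))
  sb <- make_stats(p = rep(.001, 4), fdr = c(.01, .02, .2, .6),
                   lfc = c(1.5, -1.2, 2, -0.1))
  cls <- classify_features(m, sa, sb, t)
  expect_equal(cls$category, c("both_same", "both_contra", "a_only",
                               "neither"))
  expect_equal(cls$dir_b, c("up", "down", "up", "down"))
})

test_that("classification categories partition all sign/significance combos", {
  # all combinations of strong/weak fdr and lfc in {-1, 0, +1} on both sides
  t <- thresholds(0.05, "fdr", 0)
  grid <- expand.grid(fdr_a = c(.01, .5), lfc_a = c(-1, 0, 1),
                      fdr_b = c(.01, .5), lfc_b = c(-1, 0, 1))
  m <- identity_pair(sprintf("f%02d", seq_len(nrow(grid))))
  sa <- make_stats(p = grid$fdr_a / 2, fdr = grid$fdr_a, lfc = grid$lfc_a)
  sb <- make_stats(p = grid$fdr_b / 2, fdr = grid$fdr_b, lfc = grid$lfc_b)
  cls <- classify_features(m, sa, sb, t)
  expected <- mapply(function(fa, la, fb, lb) {
    sig_a <- fa < 0.05 & abs(la) > 0
    sig_b <- fb < 0.05 & abs(lb) > 0
    oracle_category(sig_a, sig_b, sign(la), sign(lb))
  }, grid$fdr_a, grid$lfc_a, grid$fdr_b, grid$lfc_b)
  expect_equal(cls$category, unname(expected))
  # categories partition: every feature gets exactly one category
  expect_true(all(cls$category %in% c("both_same", "both_contra", "a_only",
                                      "b_only", "neither")))
})

test_that("volcano and MA tables conserve features and clip p = 0", {
  st <- make_stats(p = c(0.01, 1, NA, 0), lfc = c(2, 1, 1, 3),
                   ave = c(10, 9, 8, NA))
  v <- volcano_table(st, ids = paste0("f", 1:4))
  expect_equal(v$y[v$id == "f1"], 2)
  expect_equal(v$y[v$id == "f2"], 0)
  expect_false("f3" %in% v$id)
  expect_equal(attr(v, "n_excluded"), 1L)
  expect_equal(nrow(v) + attr(v, "n_excluded"), 4L)
  # p = 0 lands 5% above the largest finite point and is flagged
  expect_true(v$clipped[v$id == "f4"])
  expect_equal(v$y[v$id == "f4"], 2 * 1.05)

  ma <- ma_table(st, ids = paste0("f", 1:4))
  expect_equal(ma$x[ma$id == "f1"], 10)
  expect_equal(ma$y[ma$id == "f1"], 2)
  expect_equal(attr(ma, "n_excluded"), 1L)  # f4 has missing ave

  empty <- make_stats(p = rep(NA_real_, 3), lfc = rep(NA_real_, 3))
  expect_equal(nrow(ma_table(empty)), 0L)
  expect_equal(attr(ma_table(empty), "n_excluded"), 3L)
})

test_that("p-value histogram bins are equal-width with right-closed last bin", {
  st <- make_stats(p = c(0.01, 0.02, 0.99), lfc = c(1, 1, 1))
  h <- pvalue_histogram(st, n_bins = 2)
  expect_equal(h$count, c(2L, 1L))
  # p = 1 belongs to the last bin; missing p is excluded and tallied
  st2 <- make_stats(p = c(1, 0.5, NA), lfc = c(1, 1, 1))
  h2 <- pvalue_histogram(st2, n_bins = 2)
  expect_equal(h2$count, c(0L, 2L))
  expect_equal(attr(h2, "n_excluded"), 1L)

  set.seed(51)
  u <- make_stats(p = runif(10000), lfc = rnorm(10000))
  hu <- pvalue_histogram(u, 20)
  expect_equal(sum(hu$count), 10000L)
  sd_bin <- sqrt(10000 * (1 / 20) * (19 / 20))
  expect_true(all(abs(hu$count - 500) < 5 * sd_bin))

  he <- pvalue_histogram(make_stats(numeric(0), numeric(0)), 5)
  expect_equal(he$count, rep(0L, 5))
})

test_that("select_features implements closed-rectangle and id-list modes", {
  tab <- data.frame(id = c("g1", "g2"), x = c(2, -1), y = c(3, 0.5),
                    stringsAsFactors = FALSE)
  expect_equal(select_features(tab, xlim = c(0, 3), ylim = c(1, 4)), "g1")
  expect_equal(select_features(tab, xlim = c(-2, 3), ylim = c(0, 4)),
               c("g1", "g2"))
  expect_equal(select_features(tab, xlim = c(5, 6), ylim = c(5, 6)),
               character(0))
  # boundary points are inside (closed rectangle)
  expect_equal(select_features(tab, xlim = c(2, 3), ylim = c(3, 4)), "g1")
  # id mode passes through ids present in the table, preserving table order
  expect_equal(select_features(tab, ids = c("g2", "g1", "gX")),
               c("g1", "g2"))
})

test_that("concordance profile counts directions per max-p bin", {
  m <- identity_pair(paste0("f", 1:4))
  sa <- make_stats(p = rep(0.02, 4), lfc = c(1, 2, 1, -1))
  sb <- make_stats(p = rep(0.02, 4), lfc = c(2, 1, -2, -3))
  cp <- concordance_profile(m, sa, sb, bin_edges = c(0, 0.05, 1))
  expect_equal(cp$n_features, c(4L, 0L))
  expect_equal(cp$fraction_same[1], 0.75)
  expect_true(is.na(cp$fraction_same[2]))

  # max-p rule: low in one comparison only is not "low p"
  m1 <- identity_pair("f1")
  cp2 <- concordance_profile(m1, make_stats(0.001, 1), make_stats(0.2, 1),
                             bin_edges = c(0, 0.05, 1))
  expect_equal(cp2$n_features, c(0L, 1L))

  # zero-lfc features count in n_features but never in n_same_direction
  cp3 <- concordance_profile(m1, make_stats(0.01, 0), make_stats(0.01, 0),
                             bin_edges = c(0, 0.05, 1))
  expect_equal(cp3$n_features[1], 1L)
  expect_equal(cp3$n_same_direction[1], 0L)

  expect_error(concordance_profile(m1, make_stats(0.5, 1), make_stats(0.5, 1),
                                   bin_edges = c(0, 0.5, 0.2, 1)),
               "ascending")

  # conservation: bins account for every feature with both p-values
  set.seed(61)
  n <- 500
  sa2 <- make_stats(p = ifelse(runif(n) < .1, NA, runif(n)), lfc = rnorm(n))
  sb2 <- make_stats(p = ifelse(runif(n) < .1, NA, runif(n)), lfc = rnorm(n))
  mp <- identity_pair(sprintf("f%03d", 1:n))
  cpn <- concordance_profile(mp, sa2, sb2)
  expect_equal(sum(cpn$n_features), sum(!is.na(sa2$p) & !is.na(sb2$p)))
  ok <- !is.na(cpn$fraction_same)
  expect_true(all(cpn$fraction_same[ok] >= 0 & cpn$fraction_same[ok] <= 1))
})

test_that("concordance is higher in low-p bins for true shared effects than for null", {
  # shared strong effects across two layers drive the low-p bin towards 1
  sim <- simulate_multiomics(multiomics_design(
    n_features = 600, n_samples = 30, target_rho = 0, n_same = 200,
    effect_size = 2, seed = 71))
  m <- merge_on_id(sim$layer1, sim$layer2)
  sa <- align_stats(two_group_stats(sim$layer1, "group", "g1", "g2"), m, "a")
  sb <- align_stats(two_group_stats(sim$layer2, "group", "g1", "g2"), m, "b")
  cp_eff <- concordance_profile(m, sa, sb, bin_edges = c(0, 0.05, 1))

  # matched-size independent null, large enough that the low bin is filled
  set.seed(72)
  n <- 20000
  cp_null <- concordance_profile(
    identity_pair(sprintf("f%05d", 1:n)),
    make_stats(p = runif(n), lfc = rnorm(n)),
    make_stats(p = runif(n), lfc = rnorm(n)),
    bin_edges = c(0, 0.05, 1))
  expect_gt(cp_null$n_features[1], 20)
  expect_gt(cp_eff$fraction_same[1], cp_null$fraction_same[1] + 0.2)
})
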