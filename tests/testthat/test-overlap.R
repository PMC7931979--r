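test_that("exclusive intersections enumerate membership patterns", {
  # A = {1,2,3}, B = {2,3,4}, C = {3}
  mm <- membership_matrix(cbind(A = c(TRUE, TRUE, TRUE, FALSE),
                                B = c(FALSE, TRUE, TRUE, TRUE),
                                C = c(FALSE, FALSE, TRUE, FALSE)),
                          ids = paste0("f", 1:4))
  ic <- exclusive_intersections(mm)
  got <- stats::setNames(ic$count, ic$key)
  expect_equal(got[["A"]], 1L)
  expect_equal(got[["B"]], 1L)
  expect_equal(got[["A&B"]], 1L)
  expect_equal(got[["A&B&C"]], 1L)
  expect_equal(sum(ic$count), 4L)  # conservation over the union

  # disjoint sets
  mm2 <- membership_matrix(cbind(A = c(TRUE, TRUE, FALSE),
                                 B = c(FALSE, FALSE, TRUE)),
                           ids = paste0("f", 1:3))
  ic2 <- exclusive_intersections(mm2)
  expect_equal(stats::setNames(ic2$count, ic2$key),
               c(A = 2L, B = 1L))

  # deterministic ordering: count desc, then degree, then key
  expect_equal(ic2$key, c("A", "B"))
  # all-false rows stay out of intersections but are tallied
  mm3 <- membership_matrix(cbind(A = c(TRUE, FALSE), B = c(FALSE, FALSE)),
                           ids = c("f1", "f2"))
  ic3 <- exclusive_intersections(mm3)
  expect_equal(attr(ic3, "n_none"), 1L)
})

test_that("venn counts are the two-set special case", {
  mm <- membership_matrix(cbind(A = c(TRUE, TRUE), B = c(FALSE, TRUE)),
                          ids = c("f1", "f2"))
  expect_equal(venn_counts(mm), c(only_a = 1L, only_b = 0L, both = 1L))
  mmAB <- membership_matrix(cbind(A = c(TRUE, TRUE), B = c(TRUE, TRUE)),
                            ids = c("f1", "f2"))
  expect_equal(venn_counts(mmAB), c(only_a = 0L, only_b = 0L, both = 2L))
  mmA <- membership_matrix(cbind(A = c(TRUE, TRUE), B = c(FALSE, FALSE)),
                           ids = c("f1", "f2"))
  expect_equal(venn_counts(mmA), c(only_a = 2L, only_b = 0L, both = 0L))
  mm3 <- membership_matrix(cbind(A = TRUE, B = TRUE, C = TRUE), ids = "f1")
  expect_error(venn_counts(mm3), "two sets")
})

test_that("significance membership flags features per spec and keeps the universe", {
  t <- thresholds(0.05, "fdr", 0)
  ids <- paste0("f", 1:3)
  sa <- make_stats(p = c(.001, .001, .5), fdr = c(.01, .01, .9),
                   lfc = c(1, 1, 1))
  sb <- make_stats(p = c(.001, NA, .5), fdr = c(.01, NA, .9),
                   lfc = c(1, 1, 1))
  mm <- significance_membership(list(A = list(stats = sa, t = t),
                                     B = list(stats = sb, t = t)), ids)
  expect_equal(mm$membership[1, ], c(A = TRUE, B = TRUE))
  expect_equal(mm$membership[2, ], c(A = TRUE, B = FALSE))  # missing stats
  expect_equal(mm$membership[3, ], c(A = FALSE, B = FALSE))
  ic <- exclusive_intersections(mm)
  expect_equal(sum(ic$count), 2L)
  expect_equal(attr(ic, "n_none"), 1L)
})

test_that("direction splitting separates up/down and exposes contra patterns", {
  t <- thresholds(0.05, "fdr", 0)
  ids <- paste0("f", 1:3)
  # f1: up in A, down in B (the contra pattern); f2: up in both; f3: zero lfc
  sa <- make_stats(p = rep(.001, 3), fdr = rep(.01, 3), lfc = c(2, 1, 0))
  sb <- make_stats(p = rep(.001, 3), fdr = rep(.01, 3), lfc = c(-2, 1, 1))
  mm <- direction_split_membership(list(A = list(stats = sa, t = t),
                                        B = list(stats = sb, t = t)), ids)
  expect_equal(colnames(mm$membership),
               c("A_up", "A_down", "B_up", "B_down"))
  ic <- exclusive_intersections(mm)
  got <- stats::setNames(ic$count, ic$key)
  expect_equal(got[["A_up&B_down"]], 1L)  # contra: up in one, down in other
  expect_equal(got[["A_up&B_up"]], 1L)
  # f3 has zero lfc in A: it fails the strict |lfc| > 0 cutoff there and
  # joins neither A-set, appearing only as B_up
  expect_equal(got[["B_up"]], 1L)

  # union invariant: up/down per spec partition the significant nonzero-lfc set
  set.seed(81)
  n <- 300
  sr <- make_stats(p = runif(n),
                   lfc = sample(c(-2, -1, 0, 1, 2), n, TRUE))
  mmr <- direction_split_membership(list(S = list(stats = sr, t = t)),
                                    sprintf("f%03d", 1:n))
  sig <- is_significant(sr, t)
  expect_equal(sum(mmr$membership[, "S_up"] | mmr$membership[, "S_down"]),
               sum(sig & sr$log2fc != 0))
  expect_equal(sum(mmr$membership[, "S_up"] & mmr$membership[, "S_down"]), 0L)
})

test_that("presence membership applies the min_obs rule", {
  m_a <- rbind(c(1, NA, NA), c(NA, NA, NA), c(1, 2, NA))
  m_b <- rbind(c(1, 1, 1), c(2, NA, NA), c(NA, NA, NA))
  ids <- paste0("f", 1:3)
  mm <- presence_membership(list(A = m_a, B = m_b), ids)
  # observed in 1 of 3 samples counts as present (not missing in all)
  expect_equal(unname(mm$membership[, "A"]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(mm$membership[, "B"]), c(TRUE, TRUE, FALSE))
  # stricter min_obs: 2 observations fail min_obs = 3
  mm3 <- presence_membership(list(A = m_a), ids, min_obs = 3)
  expect_equal(unname(mm3$membership[, "A"]), c(FALSE, FALSE, FALSE))
})

test_that("subset export returns exactly the features of one pattern", {
  mm <- membership_matrix(cbind(A = c(TRUE, TRUE, TRUE, FALSE),
                                B = c(FALSE, TRUE, TRUE, TRUE),
                                C = c(FALSE, FALSE, TRUE, FALSE)),
                          ids = paste0("f", 1:4))
  ann <- data.frame(gene = paste0("G", 1:4), stringsAsFactors = FALSE)
  out <- subset_export(mm, c("A", "B"), ann)
  expect_equal(out$id, "f2")
  expect_equal(out$gene, "G2")
  # string key form and count consistency with exclusive_intersections
  ic <- exclusive_intersections(mm)
  for (k in ic$key)
    expect_equal(nrow(subset_export(mm, k)),
                 ic$count[ic$key == k])
  expect_equal(nrow(subset_export(mm, c("B", "C"))), 0L)
  expect_error(subset_export(mm, "Z"), "unknown set")
})

test_that("set analytics match brute-force enumeration on random memberships", {
  set.seed(91)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    n <- sample(5:80, 1)
    mmx <- matrix(runif(n * k) < runif(1, 0.2, 0.8), n, k,
                  dimnames = list(NULL, LETTERS[seq_len(k)]))
    mm <- membership_matrix(mmx, ids = sprintf("f%03d", seq_len(n)))
    ic <- exclusive_intersections(mm)
    bf <- oracle_exclusive(mmx)
    expect_equal(ic$count[order(ic$key)], bf$count)
    expect_equal(sort(ic$key), bf$key)
    expect_equal(sum(ic$count) + attr(ic, "n_none"), n)
    if (k == 2) {
      vc <- venn_counts(mm)
      expect_equal(unname(vc["both"]),
                   sum(mmx[, 1] & mmx[, 2]))
      expect_equal(sum(vc), sum(ic$count))
    }
  }
})
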