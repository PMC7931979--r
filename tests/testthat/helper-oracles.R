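# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition (double loops, exhaustive enumeration) and
# share no code with the implementation under test.

# BH step-up by the literal double-loop definition: for the i-th smallest of
# the m non-missing p-values, q_(i) = min over j >= i of p_(j) * m / j.
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out[ok[o]] <- q
  out
}

# Naive O(n^3) UPGMA over a sample matrix (samples in columns): greedily
# merge the pair of clusters with the smallest mean pairwise leaf distance,
# recording merge heights.
oracle_upgma_heights <- function(m) {
  D <- as.matrix(stats::dist(t(m)))
  clusters <- as.list(seq_len(ncol(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Exclusive intersections by per-feature pattern enumeration.
oracle_exclusive <- function(mm) {
  sets <- colnames(mm)
  keys <- character(0); counts <- integer(0)
  for (r in seq_len(nrow(mm))) {
    v <- mm[r, ]
    if (!any(v)) next
    k <- paste(sets[v], collapse = "&")
    i <- match(k, keys)
    if (is.na(i)) { keys <- c(keys, k); counts <- c(counts, 1L) }
    else counts[i] <- counts[i] + 1L
  }
  o <- order(keys)
  data.frame(key = keys[o], count = counts[o], stringsAsFactors = FALSE)
}

# Cross-comparison category truth table, one feature at a time.
oracle_category <- function(sig_a, sig_b, dir_a, dir_b) {
  if ((sig_a && dir_a == 0) || (sig_b && dir_b == 0)) return("neither")
  if (sig_a && sig_b) {
    if (dir_a == dir_b) return("both_same") else return("both_contra")
  }
  if (sig_a) return("a_only")
  if (sig_b) return("b_only")
  "neither"
}

# Direct-formula Pearson and midrank Spearman.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# --- small fixture builders -------------------------------------------------

make_dataset <- function(m, groups = NULL, ids = NULL, name = "test") {
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(m)))
  design <- data.frame(sample = colnames(m), stringsAsFactors = FALSE)
  if (!is.null(groups)) design$group <- groups
  omic_dataset(m, data.frame(feature_id = ids, stringsAsFactors = FALSE),
               design, id_column = "feature_id", name = name)
}

# merged_pair where both sides are the same universe, in order
identity_pair <- function(ids) {
  structure(list(id_column = "feature_id", shared_ids = ids,
                 rows_a = seq_along(ids), rows_b = seq_along(ids),
                 dropped_duplicates_a = list(count = 0L, examples = character(0)),
                 dropped_duplicates_b = list(count = 0L, examples = character(0)),
                 name_a = "a", name_b = "b"),
            class = "merged_pair")
}

make_stats <- function(p, lfc, fdr = NULL, ave = NULL, name = "c") {
  if (is.null(fdr)) fdr <- pmin(p * 2, 1)
  contrast_stats(name, p = p, fdr = fdr, log2fc = lfc, ave = ave)
}

write_fixture_files <- function(dir, matrix_lines, design_lines,
                                prefix = "fx") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  dp <- file.path(dir, paste0(prefix, "_design.tsv"))
  writeLines(matrix_lines, mp)
  writeLines(design_lines, dp)
  c(matrix = mp, design = dp)
}
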