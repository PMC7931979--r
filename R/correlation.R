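#' Per-feature correlation between two data layers
#'
#' For two datasets measured on the same biological samples (multiomics, or
#' the same data processed by two pipelines), computes for each shared
#' feature the Pearson and Spearman correlation of its values across the
#' paired samples. Pairs with a missing value on either side are dropped
#' per feature (pairwise-complete deletion); Spearman is Pearson on
#' average-ranked values (ties get midranks). A correlation is reported
#' only when at least `min_pairs` complete pairs remain and both sides have
#' nonzero variance — two points always correlate perfectly, which carries
#' no information.
#'
#' @param m a `merged_pair` from [merge_on_id()].
#' @param a,b the two [omic_dataset]s that were merged.
#' @param sample_map two-column data.frame (or matrix) pairing sample names
#'   of `a` with sample names of `b`; defaults to the samples shared by
#'   name.
#' @param min_pairs minimum complete pairs for a reported correlation.
#' @return data.frame of class `correlation_result`: `id`, `pearson_r`,
#'   `spearman_r`, `n_pairs`, `reason` (why r is missing: `""`,
#'   `"too_few_pairs"` or `"zero_variance"`).
#' @export
feature_correlations <- function(m, a, b, sample_map = NULL, min_pairs = 3) {
  stopifnot(inherits(m, "merged_pair"), inherits(a, "omic_dataset"),
            inherits(b, "omic_dataset"))
  if (is.null(sample_map)) {
    shared <- intersect(colnames(a$matrix), colnames(b$matrix))
    sample_map <- data.frame(sample_a = shared, sample_b = shared,
                             stringsAsFactors = FALSE)
  }
  sample_map <- as.data.frame(sample_map, stringsAsFactors = FALSE)
  if (nrow(sample_map) == 0L)
    stop("sample_map is empty: no paired samples", call. = FALSE)
  bad_a <- setdiff(sample_map[[1]], colnames(a$matrix))
  bad_b <- setdiff(sample_map[[2]], colnames(b$matrix))
  if (length(bad_a) || length(bad_b))
    stop(sprintf("sample_map names missing from the datasets: %s",
                 paste(c(bad_a, bad_b), collapse = ", ")), call. = FALSE)

  X <- a$matrix[m$rows_a, sample_map[[1]], drop = FALSE]
  Y <- b$matrix[m$rows_b, sample_map[[2]], drop = FALSE]
  n <- nrow(X)
  pearson <- spearman <- rep(NA_real_, n)
  n_pairs <- integer(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    x <- X[i, ]; y <- Y[i, ]
    ok <- !is.na(x) & !is.na(y)
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] < min_pairs) { reason[i] <- "too_few_pairs"; next }
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason[i] <- "zero_variance"; next
    }
    pearson[i] <- stats::cor(x, y, method = "pearson")
    spearman[i] <- stats::cor(rank(x), rank(y), method = "pearson")
  }
  structure(data.frame(id = m$shared_ids, pearson_r = pearson,
                       spearman_r = spearman, n_pairs = n_pairs,
                       reason = reason, stringsAsFactors = FALSE),
            class = c("correlation_result", "data.frame"))
}

#' Summarise a correlation distribution
#'
#' Median, quartiles, fraction negative, and histogram counts over
#' `[-1, 1]` for each correlation method, computed over the features with a
#' reported correlation.
#'
#' @param cr a [feature_correlations()] result.
#' @param n_bins number of equal-width histogram bins over `[-1, 1]`.
#' @return list of class `correlation_summary` with one element per method
#'   (`pearson`, `spearman`), each a list `n`, `median`, `q1`, `q3`,
#'   `fraction_negative`, `histogram` (data.frame `bin_lo`, `bin_hi`,
#'   `count`), `empty` flag.
#' @export
correlation_summary <- function(cr, n_bins = 40) {
  stopifnot(inherits(cr, "correlation_result"), n_bins >= 1)
  one <- function(r) {
    r <- r[!is.na(r)]
    edges <- seq(-1, 1, length.out = n_bins + 1)
    if (length(r) == 0L)
      return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                  fraction_negative = NA_real_,
                  histogram = data.frame(bin_lo = edges[-length(edges)],
                                         bin_hi = edges[-1],
                                         count = integer(n_bins)),
                  empty = TRUE))
    idx <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bins)
    q <- stats::quantile(r, c(.25, .5, .75), names = FALSE)
    list(n = length(r), median = q[2], q1 = q[1], q3 = q[3],
         fraction_negative = mean(r < 0),
         histogram = data.frame(bin_lo = edges[-length(edges)],
                                bin_hi = edges[-1],
                                count = tabulate(idx, nbins = n_bins)),
         empty = FALSE)
  }
  structure(list(pearson = one(cr$pearson_r), spearman = one(cr$spearman_r)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  for (method in names(x)) {
    s <- x[[method]]
    if (s$empty) cat(sprintf("%s: no correlations\n", method))
    else cat(sprintf(
      "%s: n=%d, median=%.3f [q1=%.3f, q3=%.3f], %.1f%% negative\n",
      method, s$n, s$median, s$q1, s$q3, 100 * s$fraction_negative))
  }
  invisible(x)
}
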