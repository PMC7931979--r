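#' Significance thresholds for a contrast
#'
#' A feature counts as significant when its chosen statistic (FDR by
#' default, raw p optionally) is strictly below `alpha` AND its absolute
#' log2 fold change is strictly above `lfc_min`. Strict inequalities follow
#' the usual reporting convention ("FDR < 0.05, log2 fold change > 1"):
#' boundary values fail.
#'
#' @param alpha significance cutoff in `(0, 1]`.
#' @param stat_column `"fdr"` or `"p"`.
#' @param lfc_min non-negative log2 fold cutoff.
#' @return a `thresholds` object.
#' @export
thresholds <- function(alpha = 0.05, stat_column = c("fdr", "p"),
                       lfc_min = 0) {
  stat_column <- match.arg(stat_column)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(lfc_min) || length(lfc_min) != 1L || lfc_min < 0)
    stop("`lfc_min` must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, stat_column = stat_column,
                 lfc_min = lfc_min), class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("thresholds: %s < %g & |log2fc| > %g\n",
              x$stat_column, x$alpha, x$lfc_min))
  invisible(x)
}

#' Per-feature significance flags
#'
#' @param stats a [contrast_stats].
#' @param t a [thresholds()]. Features with a missing statistic or missing
#'   log2 fold change are never significant.
#' @return logical vector, one flag per feature.
#' @export
is_significant <- function(stats, t = thresholds()) {
  stopifnot(inherits(stats, "contrast_stats"), inherits(t, "thresholds"))
  stat <- if (t$stat_column == "fdr") stats$fdr else stats$p
  flag <- !is.na(stat) & stat < t$alpha &
    !is.na(stats$log2fc) & abs(stats$log2fc) > t$lfc_min
  flag
}

.dir3 <- function(lfc)  # "up" / "down" / "zero"; NA lfc -> "zero"
  ifelse(is.na(lfc) | lfc == 0, "zero", ifelse(lfc > 0, "up", "down"))

#' Classify shared features across two contrasts
#'
#' Assigns each shared feature to one of five cross-comparison categories:
#' `both_same` (significant in both contrasts with the same nonzero fold
#' direction), `both_contra` (significant in both with opposite directions —
#' the "contra" features), `a_only` / `b_only` (significant in exactly one)
#' and `neither`. Both contrasts must orient their fold changes with the
#' same group ordering; the function never flips signs.
#'
#' @param m a `merged_pair` from [merge_on_id()].
#' @param stats_a,stats_b [contrast_stats] aligned to the merged rows (see
#'   [align_stats()]), one entry per shared ID.
#' @param t a [thresholds()], applied to both contrasts.
#' @return a data.frame (one row per shared ID): `id`, `category`, `sig_a`,
#'   `sig_b`, `dir_a`, `dir_b`, `lfc_a`, `lfc_b`, `p_a`, `p_b`, `fdr_a`,
#'   `fdr_b`.
#' @export
classify_features <- function(m, stats_a, stats_b, t = thresholds()) {
  stopifnot(inherits(m, "merged_pair"))
  n <- length(m$shared_ids)
  if (length(stats_a) != n || length(stats_b) != n)
    stop("stats must be aligned to the merged pair (one entry per shared ID)",
         call. = FALSE)
  sig_a <- is_significant(stats_a, t)
  sig_b <- is_significant(stats_b, t)
  dir_a <- .dir3(stats_a$log2fc)
  dir_b <- .dir3(stats_b$log2fc)

  zero_sig <- (sig_a & dir_a == "zero") | (sig_b & dir_b == "zero")
  if (any(zero_sig))
    warning(sprintf(
      "%d feature(s) significant with log2fc exactly 0: direction undefined, classified as 'neither'",
      sum(zero_sig)), call. = FALSE)

  category <- rep("neither", n)
  both <- sig_a & sig_b & dir_a != "zero" & dir_b != "zero"
  category[both & dir_a == dir_b] <- "both_same"
  category[both & dir_a != dir_b] <- "both_contra"
  only <- !zero_sig & xor(sig_a, sig_b)
  category[only & sig_a] <- "a_only"
  category[only & sig_b] <- "b_only"

  data.frame(id = m$shared_ids, category = category,
             sig_a = sig_a, sig_b = sig_b, dir_a = dir_a, dir_b = dir_b,
             lfc_a = stats_a$log2fc, lfc_b = stats_b$log2fc,
             p_a = stats_a$p, p_b = stats_b$p,
             fdr_a = stats_a$fdr, fdr_b = stats_b$fdr,
             stringsAsFactors = FALSE)
}

#' Volcano plot coordinates
#'
#' Returns the per-feature coordinates of a volcano plot: x = log2 fold
#' change, y = -log10(p). Features missing either value are excluded from
#' the table but counted in the `n_excluded` attribute, so excluded +
#' plotted always equals the feature total. Zero p-values cannot be drawn on
#' a log axis; they are clipped to 1.05 times the largest finite -log10(p)
#' in the table and flagged in the `clipped` column (the underlying
#' statistics are untouched).
#'
#' @param stats a [contrast_stats].
#' @param ids optional feature IDs (recycled into the `id` column).
#' @return data.frame `id`, `x`, `y`, `clipped`; attribute `n_excluded`.
#' @export
volcano_table <- function(stats, ids = NULL) {
  stopifnot(inherits(stats, "contrast_stats"))
  n <- length(stats)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(n))
  keep <- !is.na(stats$p) & !is.na(stats$log2fc)
  p <- stats$p[keep]
  y <- -log10(p)
  clipped <- p == 0
  if (any(clipped)) {
    ymax <- if (any(!clipped)) max(y[!clipped]) else 0
    y[clipped] <- ymax * 1.05
  }
  out <- data.frame(id = ids[keep], x = stats$log2fc[keep], y = y,
                    clipped = clipped, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n - sum(keep)
  out
}

#' MA plot coordinates
#'
#' x = average level, y = log2 fold change; features missing either are
#' excluded and tallied in the `n_excluded` attribute.
#'
#' @inheritParams volcano_table
#' @return data.frame `id`, `x`, `y`; attribute `n_excluded`.
#' @export
ma_table <- function(stats, ids = NULL) {
  stopifnot(inherits(stats, "contrast_stats"))
  n <- length(stats)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(n))
  keep <- !is.na(stats$ave) & !is.na(stats$log2fc)
  out <- data.frame(id = ids[keep], x = stats$ave[keep],
                    y = stats$log2fc[keep], stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n - sum(keep)
  out
}

#' P-value histogram counts
#'
#' Equal-width bins over `[0, 1]`; each bin is left-closed, the last bin
#' also right-closed, so every non-missing p-value lands in exactly one bin.
#'
#' @param stats a [contrast_stats].
#' @param n_bins number of bins (>= 1).
#' @return data.frame `bin_lo`, `bin_hi`, `count`; attribute `n_excluded`
#'   (missing p-values).
#' @export
pvalue_histogram <- function(stats, n_bins = 20) {
  stopifnot(inherits(stats, "contrast_stats"), n_bins >= 1)
  p <- stats$p[!is.na(stats$p)]
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(floor(p * n_bins) + 1L, n_bins)  # p = 1 into the last bin
  counts <- tabulate(idx, nbins = n_bins)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = counts)
  attr(out, "n_excluded") <- length(stats) - length(p)
  out
}

#' Select features from a plot table
#'
#' The headless counterpart of dragging a box in an interactive scatter
#' plot: returns the IDs whose coordinates fall inside a closed rectangle,
#' in table order. The returned ID list can be re-applied as a highlight set
#' on any other comparison's table (`ids` mode), which passes through the
#' IDs present in that table, preserving the table's order.
#'
#' @param table a data.frame with columns `id`, `x`, `y` (as produced by
#'   [volcano_table()] or [ma_table()]).
#' @param xlim,ylim closed ranges `c(lo, hi)` of the selection rectangle.
#' @param ids alternative to the rectangle: a feature ID list to filter by.
#' @return character vector of selected feature IDs (possibly empty).
#' @export
select_features <- function(table, xlim = NULL, ylim = NULL, ids = NULL) {
  stopifnot(is.data.frame(table), all(c("id") %in% names(table)))
  if (!is.null(ids))
    return(table$id[table$id %in% ids])
  stopifnot(!is.null(xlim), !is.null(ylim),
            all(c("x", "y") %in% names(table)))
  inside <- table$x >= xlim[1] & table$x <= xlim[2] &
    table$y >= ylim[1] & table$y <= ylim[2]
  table$id[which(inside)]
}

#' Direction-concordance profile over p-value bins
#'
#' For features shared between two contrasts, the fraction whose fold
#' changes point the same way is a reliability read-out: genuine shared
#' biology drives that fraction towards 1 among low p-values, while under
#' independent noise it hovers around 0.5. This profile stratifies the
#' agreement by p-value bin.
#'
#' With `bin_statistic = "max_p"` (default) a feature is assigned to the bin
#' containing `max(p_a, p_b)` — it only counts as "low p" when low in both
#' comparisons. With `"per_comparison"` each feature contributes twice, once
#' at `p_a` and once at `p_b`. Bins are left-closed, the last bin
#' right-closed. Features with a zero or missing fold change on either side
#' count in `n_features` but never in `n_same_direction`.
#'
#' @param m a `merged_pair`.
#' @param stats_a,stats_b [contrast_stats] aligned to the merged rows.
#' @param bin_edges ascending numeric vector from 0 to 1.
#' @param bin_statistic `"max_p"` or `"per_comparison"`.
#' @return data.frame `bin_lo`, `bin_hi`, `n_features`, `n_same_direction`,
#'   `fraction_same` (NA for empty bins).
#' @export
concordance_profile <- function(m, stats_a, stats_b,
                                bin_edges = c(0, 0.001, 0.01, 0.05,
                                              0.1, 0.5, 1),
                                bin_statistic = c("max_p",
                                                  "per_comparison")) {
  stopifnot(inherits(m, "merged_pair"))
  bin_statistic <- match.arg(bin_statistic)
  if (length(bin_edges) < 2 || bin_edges[1] != 0 ||
      bin_edges[length(bin_edges)] != 1 || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly ascending from 0 to 1", call. = FALSE)
  n <- length(m$shared_ids)
  if (length(stats_a) != n || length(stats_b) != n)
    stop("stats must be aligned to the merged pair", call. = FALSE)

  ok <- !is.na(stats_a$p) & !is.na(stats_b$p)
  same <- !is.na(stats_a$log2fc) & !is.na(stats_b$log2fc) &
    sign(stats_a$log2fc) == sign(stats_b$log2fc) & stats_a$log2fc != 0

  assign_bin <- function(p) {
    # left-closed bins; p = 1 belongs to the last bin
    idx <- findInterval(p, bin_edges, rightmost.closed = TRUE)
    pmin(idx, length(bin_edges) - 1L)
  }
  if (bin_statistic == "max_p") {
    bins <- assign_bin(pmax(stats_a$p[ok], stats_b$p[ok]))
    sm <- same[ok]
  } else {
    bins <- c(assign_bin(stats_a$p[ok]), assign_bin(stats_b$p[ok]))
    sm <- rep(same[ok], 2)
  }
  nb <- length(bin_edges) - 1L
  n_feat <- tabulate(bins, nbins = nb)
  n_same <- tabulate(bins[sm], nbins = nb)
  data.frame(bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1],
             n_features = n_feat, n_same_direction = n_same,
             fraction_same = ifelse(n_feat > 0, n_same / n_feat, NA_real_))
}
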