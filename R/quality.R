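# Complete-case feature filtering shared by pca() and sample_dendrogram():
# keep features with no missing value among the selected samples.
.complete_features <- function(ds, samples = NULL) {
  m <- ds$matrix
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop(sprintf("unknown sample(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    m <- m[, samples, drop = FALSE]
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Principal component analysis of samples
#'
#' PCA over the sample profiles of an expression dataset for quality
#' control. Features with any missing value among the selected samples are
#' removed (complete-case filtering, no imputation); the remaining features
#' are centred and, by default, scaled to unit variance. Zero-variance
#' features cannot be scaled and are dropped with a warning. Component signs
#' are arbitrary in PCA; each loading vector is oriented so its
#' largest-magnitude element is positive, which makes results reproducible.
#'
#' @param ds an [omic_dataset].
#' @param samples optional character vector restricting the samples.
#' @param n_components number of components to return (capped at the rank).
#' @param scale divide each feature by its standard deviation.
#' @return list of class `pca_result`: `scores` (sample x component),
#'   `loadings` (feature x component, orthonormal columns),
#'   `variance_explained` (fractions, non-increasing), `n_features_used`.
#' @export
pca <- function(ds, samples = NULL, n_components = 2, scale = TRUE) {
  stopifnot(inherits(ds, "omic_dataset"))
  m <- .complete_features(ds, samples)
  if (ncol(m) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  if (scale) {
    sds <- apply(m, 1, stats::sd)
    zv <- sds == 0
    if (any(zv)) {
      warning(sprintf("%d zero-variance feature(s) dropped before scaling",
                      sum(zv)), call. = FALSE)
      m <- m[!zv, , drop = FALSE]
    }
  }
  if (nrow(m) < 2L)
    stop(sprintf(
      "only %d complete feature(s) after missing-value filtering; PCA needs at least 2",
      nrow(m)), call. = FALSE)

  # samples are the observations: transpose so prcomp sees sample rows
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, `*`)
  loadings <- sweep(loadings, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(k)],
                 n_features_used = nrow(m)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components over %d features\n",
              nrow(x$scores), ncol(x$scores), x$n_features_used))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Average-linkage (UPGMA) sample dendrogram
#'
#' Hierarchical clustering of samples for quality control, using the
#' average distance between clusters (UPGMA linkage), which makes merge
#' heights non-decreasing. Features with missing values are filtered out
#' first, as for [pca()]. Distances are euclidean between sample profiles
#' by default; `"correlation"` uses 1 - Pearson correlation.
#'
#' @param ds an [omic_dataset].
#' @param distance `"euclidean"` or `"correlation"`.
#' @param samples optional sample subset.
#' @return list of class `tree_result`: `merge` (hclust-style merge
#'   matrix), `height` (non-decreasing merge heights), `labels` (sample
#'   names), `hclust` (the underlying [stats::hclust] object for plotting),
#'   `n_features_used`.
#' @export
sample_dendrogram <- function(ds, distance = c("euclidean", "correlation"),
                              samples = NULL) {
  stopifnot(inherits(ds, "omic_dataset"))
  distance <- match.arg(distance)
  m <- .complete_features(ds, samples)
  if (ncol(m) < 2L)
    stop("dendrogram needs at least two samples", call. = FALSE)
  if (nrow(m) < 1L)
    stop("no complete features left after missing-value filtering",
         call. = FALSE)
  d <- if (distance == "euclidean") stats::dist(t(m))
       else stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc, distance = distance, n_features_used = nrow(m)),
            class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat(sprintf("tree_result: %d samples, %s distance, average linkage\n",
              length(x$labels), x$distance))
  invisible(x)
}

#' Per-sample distribution summaries
#'
#' Summaries used by boxplots and density plots: counts of observed and
#' missing values, five-number summary (type-7 linear-interpolation
#' quantiles), mean and standard deviation per sample, plus a shared
#' kernel-density grid (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth, 512 points spanning the pooled data plus three bandwidths) so
#' all samples' densities are comparable on one axis. Samples with all
#' values missing, or with zero spread (degenerate density), are flagged.
#'
#' @param ds an [omic_dataset].
#' @return list of class `sample_summary`: `table` (one row per sample:
#'   `sample`, `n_observed`, `n_missing`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`, `sd`, `all_missing`, `degenerate`), `density_grid`
#'   (shared x grid) and `densities` (grid x sample matrix, NA columns for
#'   flagged samples).
#' @export
sample_summaries <- function(ds) {
  stopifnot(inherits(ds, "omic_dataset"))
  m <- ds$matrix
  qs <- function(x) stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE,
                                    type = 7)
  rows <- lapply(colnames(m), function(s) {
    x <- m[, s]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(sample = s, n_observed = 0L,
                        n_missing = nrow(m), min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_,
                        mean = NA_real_, sd = NA_real_, all_missing = TRUE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    q <- qs(x)
    data.frame(sample = s, n_observed = length(x),
               n_missing = nrow(m) - length(x),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
               all_missing = FALSE,
               degenerate = length(unique(x)) < 2L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  pooled <- as.vector(m[!is.na(m)])
  usable <- !tab$all_missing & !tab$degenerate
  if (length(pooled) >= 2L && any(usable)) {
    bws <- vapply(which(usable), function(i)
      stats::bw.nrd0(m[, tab$sample[i]][!is.na(m[, tab$sample[i]])]), 1)
    bw_max <- max(bws)
    grid <- seq(min(pooled) - 3 * bw_max, max(pooled) + 3 * bw_max,
                length.out = 512)
    dens <- matrix(NA_real_, 512, ncol(m),
                   dimnames = list(NULL, colnames(m)))
    for (i in which(usable)) {
      x <- m[, tab$sample[i]]
      x <- x[!is.na(x)]
      d <- stats::density(x, bw = "nrd0", kernel = "gaussian",
                          from = grid[1], to = grid[512], n = 512)
      dens[, tab$sample[i]] <- d$y
    }
  } else {
    grid <- numeric(0)
    dens <- matrix(NA_real_, 0, ncol(m), dimnames = list(NULL, colnames(m)))
  }
  structure(list(table = tab, density_grid = grid, densities = dens),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary: %d samples\n", nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Inspect one feature across sample conditions
#'
#' The per-feature view: how a single feature's abundance values distribute
#' over the levels of any design column, as raw points plus per-group
#' summary statistics (the headless counterpart of box/violin plots of one
#' feature).
#'
#' @param ds an [omic_dataset].
#' @param feature_id an ID present in the dataset's ID column; for
#'   duplicated IDs the first listed row is used.
#' @param group_column design column defining the groups.
#' @return list of class `feature_profile`: `feature_id`, `group_column`,
#'   `summary` (per group: `group`, `n`, `n_missing`, `mean`, `median`,
#'   `q1`, `q3`), `points` (per sample: `sample`, `group`, `value`).
#' @export
feature_profile <- function(ds, feature_id, group_column) {
  stopifnot(inherits(ds, "omic_dataset"))
  if (!group_column %in% names(ds$design))
    stop(sprintf("group column '%s' not in design; available: %s",
                 group_column, paste(names(ds$design), collapse = ", ")),
         call. = FALSE)
  ids <- feature_ids(ds)
  row <- match(feature_id, ids)
  if (is.na(row)) {
    uniq <- unique(ids)
    near <- uniq[order(utils::adist(feature_id, uniq,
                                    ignore.case = TRUE))][1:min(3,
                                                                length(uniq))]
    stop(sprintf("feature '%s' not found; did you mean: %s", feature_id,
                 paste(near, collapse = ", ")), call. = FALSE)
  }
  samp <- as.character(ds$design[[ds$sample_column]])
  grp <- as.character(ds$design[[group_column]])
  keep <- samp %in% colnames(ds$matrix)
  samp <- samp[keep]; grp <- grp[keep]
  vals <- ds$matrix[row, samp]
  pts <- data.frame(sample = samp, group = grp, value = as.double(vals),
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(pts, pts$group), function(g) {
    x <- g$value[!is.na(g$value)]
    q <- if (length(x)) stats::quantile(x, c(.25, .5, .75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(group = g$group[1], n = nrow(g), n_missing = sum(is.na(g$value)),
               mean = if (length(x)) mean(x) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(feature_id = feature_id, group_column = group_column,
                 summary = summ, points = pts),
            class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  cat(sprintf("feature_profile '%s' by '%s':\n", x$feature_id,
              x$group_column))
  print(x$summary)
  invisible(x)
}
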