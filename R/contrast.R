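#' Per-feature statistics for one contrast
#'
#' A contrast is a named two-group comparison summarised per feature by a
#' p-value, a Benjamini-Hochberg adjusted p-value (FDR), a log2 fold change
#' (difference of group means on the log2 scale) and an average level. These
#' are produced upstream (limma, DESeq2, ...) or by [two_group_stats()];
#' missing values are allowed in every column and simply propagate.
#'
#' @param contrast_name label for the comparison.
#' @param p,fdr numeric vectors in `[0, 1]` (NA allowed).
#' @param log2fc numeric vector, log2 units.
#' @param ave numeric vector, same units as the expression matrix.
#' @return object of class `contrast_stats`.
#' @export
contrast_stats <- function(contrast_name, p, fdr, log2fc, ave = NULL) {
  n <- length(p)
  if (is.null(ave)) ave <- rep(NA_real_, n)
  lens <- c(length(fdr), length(log2fc), length(ave))
  if (any(lens != n))
    stop("p, fdr, log2fc and ave must have equal length", call. = FALSE)
  p <- as.double(p); fdr <- as.double(fdr)
  for (v in list(p = p, fdr = fdr)) {
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad))
      stop("p and fdr values must lie in [0, 1]", call. = FALSE)
  }
  both <- !is.na(p) & !is.na(fdr)
  if (any(fdr[both] < p[both] - 1e-9))
    warning("some FDR values are smaller than their p-values; ",
            "check the upstream adjustment", call. = FALSE)
  structure(list(contrast_name = contrast_name, p = p, fdr = fdr,
                 log2fc = as.double(log2fc), ave = as.double(ave)),
            class = "contrast_stats")
}

#' @export
print.contrast_stats <- function(x, ...) {
  cat(sprintf("contrast_stats '%s': %d features (%d with p, %d with log2fc)\n",
              x$contrast_name, length(x$p), sum(!is.na(x$p)),
              sum(!is.na(x$log2fc))))
  invisible(x)
}

#' @export
length.contrast_stats <- function(x) length(x$p)

# Column naming convention used when contrast statistics travel inside the
# feature annotation table: <stat>_<contrast>, e.g. "P.Value_trt_vs_ctrl".
.stat_cols <- function(contrast_name)
  paste(c("P.Value", "FDR", "log2FC", "AveExpr"), contrast_name, sep = "_")

#' Extract a contrast's statistics columns from a dataset's annotations
#'
#' Looks for the columns `P.Value_<name>`, `FDR_<name>`, `log2FC_<name>` and
#' `AveExpr_<name>` appended to the feature table by upstream tools or by
#' [attach_contrast()].
#'
#' @param ds an [omic_dataset].
#' @param contrast_name the contrast label.
#' @return a [contrast_stats].
#' @export
extract_contrast <- function(ds, contrast_name) {
  stopifnot(inherits(ds, "omic_dataset"))
  cols <- .stat_cols(contrast_name)
  missing <- setdiff(cols[1:3], names(ds$annotations))
  if (length(missing)) {
    have <- grep("^P\\.Value_", names(ds$annotations), value = TRUE)
    stop(sprintf(
      "contrast '%s' not found in dataset '%s' (missing columns: %s)%s",
      contrast_name, ds$name, paste(missing, collapse = ", "),
      if (length(have)) paste0("; available contrasts: ",
                               paste(sub("^P\\.Value_", "", have),
                                     collapse = ", "))
      else ""), call. = FALSE)
  }
  getcol <- function(cn)
    if (cn %in% names(ds$annotations)) .parse_numeric(ds$annotations[[cn]])
    else rep(NA_real_, nrow(ds$annotations))
  contrast_stats(contrast_name, p = getcol(cols[1]), fdr = getcol(cols[2]),
                 log2fc = getcol(cols[3]), ave = getcol(cols[4]))
}

#' Append a contrast's statistics to a dataset's annotation table
#'
#' @param ds an [omic_dataset].
#' @param stats a [contrast_stats] with one value per dataset feature.
#' @return the dataset with four new annotation columns.
#' @export
attach_contrast <- function(ds, stats) {
  stopifnot(inherits(ds, "omic_dataset"), inherits(stats, "contrast_stats"))
  if (length(stats) != nrow(ds$matrix))
    stop("stats length does not match the dataset's feature count",
         call. = FALSE)
  cols <- .stat_cols(stats$contrast_name)
  ds$annotations[[cols[1]]] <- stats$p
  ds$annotations[[cols[2]]] <- stats$fdr
  ds$annotations[[cols[3]]] <- stats$log2fc
  ds$annotations[[cols[4]]] <- stats$ave
  ds
}

#' Align contrast statistics to a merged pair
#'
#' Subsets a per-feature statistics object to the rows of one side of a
#' [merge_on_id()] result, in shared-ID order.
#'
#' @param stats a [contrast_stats] covering a full dataset.
#' @param m a `merged_pair`.
#' @param side `"a"` or `"b"`: which dataset the stats belong to.
#' @return a [contrast_stats] with one entry per shared ID.
#' @export
align_stats <- function(stats, m, side = c("a", "b")) {
  stopifnot(inherits(stats, "contrast_stats"), inherits(m, "merged_pair"))
  side <- match.arg(side)
  idx <- if (side == "a") m$rows_a else m$rows_b
  if (max(idx) > length(stats))
    stop("stats are shorter than the dataset they should cover",
         call. = FALSE)
  contrast_stats(stats$contrast_name, p = stats$p[idx], fdr = stats$fdr[idx],
                 log2fc = stats$log2fc[idx], ave = stats$ave[idx])
}
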