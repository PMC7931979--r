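#' Run a full cross-comparison between two contrasts
#'
#' High-level driver used by the command-line interface: merges two
#' datasets on their shared ID column, classifies every shared feature
#' across the two contrasts, computes the direction-concordance profile and
#' the significance/direction overlap counts, and writes tables
#' (TSV), side-by-side volcano figures (PNG + SVG) and a settings snapshot
#' into `out_dir`. Running it twice with identical inputs and settings
#' yields byte-identical tables.
#'
#' @param a,b [omic_dataset]s carrying the contrast statistic columns.
#' @param contrast_a,contrast_b contrast names resolvable by
#'   [extract_contrast()] in `a` and `b` respectively.
#' @param t a [thresholds()].
#' @param out_dir output directory (created).
#' @param id_column shared ID column, default `a$id_column`.
#' @param bin_edges concordance profile bin edges.
#' @param extra_settings additional entries recorded in the snapshot.
#' @return invisibly, a list with the computed objects (`merged`,
#'   `classification`, `concordance`, `intersections`) and the written
#'   `files`.
#' @export
run_comparison <- function(a, b, contrast_a, contrast_b, t = thresholds(),
                           out_dir, id_column = a$id_column,
                           bin_edges = c(0, 0.001, 0.01, 0.05, 0.1, 0.5, 1),
                           extra_settings = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- merge_on_id(a, b, id_column = id_column)
  log_step("merge", shared = length(m$shared_ids),
           dropped_a = m$dropped_duplicates_a$count,
           dropped_b = m$dropped_duplicates_b$count)
  sa <- align_stats(extract_contrast(a, contrast_a), m, "a")
  sb <- align_stats(extract_contrast(b, contrast_b), m, "b")

  cls <- classify_features(m, sa, sb, t)
  log_step("classify", n = nrow(cls),
           both_same = sum(cls$category == "both_same"),
           both_contra = sum(cls$category == "both_contra"))
  cp <- concordance_profile(m, sa, sb, bin_edges = bin_edges)

  specs <- list(a = list(stats = sa, t = t), b = list(stats = sb, t = t))
  # set labels must be unique even when a contrast is compared with itself
  names(specs) <- make.unique(c(contrast_a, contrast_b), sep = "_")
  ic <- exclusive_intersections(significance_membership(specs, m$shared_ids))
  icd <- exclusive_intersections(direction_split_membership(specs,
                                                            m$shared_ids))

  files <- c(
    classification = write_table_tsv(
      cls[c("id", "category", "sig_a", "sig_b", "lfc_a", "lfc_b",
            "p_a", "p_b", "fdr_a", "fdr_b")],
      file.path(out_dir, "classification.tsv")),
    concordance = write_table_tsv(cp, file.path(out_dir, "concordance.tsv")),
    intersections = write_table_tsv(ic,
      file.path(out_dir, "intersections.tsv")),
    intersections_direction = write_table_tsv(icd,
      file.path(out_dir, "intersections_direction.tsv")))

  va <- volcano_table(sa, ids = m$shared_ids)
  vb <- volcano_table(sb, ids = m$shared_ids)
  figs <- export_figure(function() {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot_volcano(va, cls, main = contrast_a)
    plot_volcano(vb, cls, main = contrast_b)
  }, file.path(out_dir, "volcano_side_by_side"), width = 10, height = 5)

  settings <- c(list(tool_version = as.character(
                       utils::packageVersion("omicomp")),
                     module = "compare",
                     contrast_a = contrast_a, contrast_b = contrast_b,
                     id_column = id_column, alpha = t$alpha,
                     stat_column = t$stat_column, lfc_min = t$lfc_min,
                     bin_edges = bin_edges),
                extra_settings)
  snap <- save_settings(settings, file.path(out_dir, "settings.json"))

  invisible(list(merged = m, classification = cls, concordance = cp,
                 intersections = ic, intersections_direction = icd,
                 files = c(files, figs, settings = snap)))
}
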