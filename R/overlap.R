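#' Build a membership matrix
#'
#' The boolean feature-by-set matrix underlying all Venn/UpSet analytics.
#'
#' @param membership logical matrix (features in rows, sets in columns) with
#'   set labels as column names.
#' @param ids feature IDs, one per row, unique.
#' @return a `membership_matrix` object.
#' @export
membership_matrix <- function(membership, ids) {
  membership <- as.matrix(membership)
  storage.mode(membership) <- "logical"
  membership[is.na(membership)] <- FALSE
  if (ncol(membership) < 1L)
    stop("at least one set is required", call. = FALSE)
  if (is.null(colnames(membership)))
    stop("set labels (column names) are required", call. = FALSE)
  if (anyDuplicated(colnames(membership)))
    stop("set labels must be unique", call. = FALSE)
  ids <- as.character(ids)
  if (length(ids) != nrow(membership))
    stop("one feature ID per membership row is required", call. = FALSE)
  if (anyDuplicated(ids))
    stop("feature IDs must be unique", call. = FALSE)
  rownames(membership) <- ids
  structure(list(membership = membership, ids = ids,
                 sets = colnames(membership)),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership_matrix: %d features x %d sets (%s)\n",
              length(x$ids), length(x$sets), paste(x$sets, collapse = ", ")))
  cat(sprintf("  features in >=1 set: %d; in none: %d\n",
              sum(rowSums(x$membership) > 0),
              sum(rowSums(x$membership) == 0)))
  invisible(x)
}

#' Significance membership across several contrasts
#'
#' One set per contrast: a feature belongs to a set when it passes that
#' contrast's thresholds. Features with missing statistics in a contrast are
#' simply absent from that set; all-absent features stay in the universe
#' (they appear in the "none" tally but in no intersection).
#'
#' @param specs named list; each element a list with `stats` (a
#'   [contrast_stats] over the shared feature universe) and optionally `t`
#'   (a [thresholds()], default `thresholds()`). Element names label the
#'   sets (default: the contrast names).
#' @param ids feature IDs of the shared universe.
#' @return a [membership_matrix()].
#' @export
significance_membership <- function(specs, ids) {
  if (length(specs) < 1L) stop("at least one spec is required", call. = FALSE)
  labels <- names(specs)
  cols <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    t <- if (is.null(sp$t)) thresholds() else sp$t
    flags <- is_significant(sp$stats, t)
    if (length(flags) != length(ids))
      stop("spec stats must cover the shared feature universe",
           call. = FALSE)
    flags
  })
  mm <- do.call(cbind, cols)
  colnames(mm) <- if (is.null(labels))
    vapply(specs, function(sp) sp$stats$contrast_name, "") else labels
  membership_matrix(mm, ids)
}

#' Fold-direction-split significance membership
#'
#' Two sets per contrast, `<label>_up` and `<label>_down`: significant
#' features with a positive fold change go up, negative go down. An
#' intersection pairing one contrast's up-set with another's down-set is
#' exactly the "contra" pattern — shared significance with opposing
#' direction. Significant features with a fold change of exactly zero join
#' neither set and are tallied in the `n_zero_lfc` attribute.
#'
#' @inheritParams significance_membership
#' @return a [membership_matrix()] with `2 * length(specs)` sets.
#' @export
direction_split_membership <- function(specs, ids) {
  if (length(specs) < 1L) stop("at least one spec is required", call. = FALSE)
  labels <- names(specs)
  if (is.null(labels))
    labels <- vapply(specs, function(sp) sp$stats$contrast_name, "")
  n_zero <- 0L
  cols <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    t <- if (is.null(sp$t)) thresholds() else sp$t
    sig <- is_significant(sp$stats, t)
    lfc <- sp$stats$log2fc
    up <- sig & !is.na(lfc) & lfc > 0
    down <- sig & !is.na(lfc) & lfc < 0
    n_zero <- n_zero + sum(sig & !is.na(lfc) & lfc == 0)
    cols[[paste0(labels[i], "_up")]] <- up
    cols[[paste0(labels[i], "_down")]] <- down
  }
  mm <- do.call(cbind, cols)
  out <- membership_matrix(mm, ids)
  attr(out, "n_zero_lfc") <- n_zero
  out
}

#' Presence/absence membership
#'
#' Qualitative detection analysis: a feature is "present" in a set when it
#' has at least `min_obs` non-missing values among that set's samples —
#' with the default `min_obs = 1`, present means not missing in all
#' samples. Useful for spotting features below the detection limit in some
#' datasets or conditions.
#'
#' @param matrices named list of numeric matrices over the same feature
#'   universe (rows aligned), e.g. each dataset's matrix subset to the
#'   merged rows, or one dataset's matrix split by condition groups.
#' @param ids feature IDs of the shared universe.
#' @param min_obs minimum number of observed values for presence.
#' @return a [membership_matrix()].
#' @export
presence_membership <- function(matrices, ids, min_obs = 1) {
  if (length(matrices) < 1L)
    stop("at least one matrix is required", call. = FALSE)
  stopifnot(min_obs >= 1)
  cols <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(ids))
      stop("matrices must be row-aligned to the feature universe",
           call. = FALSE)
    rowSums(!is.na(m)) >= min_obs
  })
  mm <- do.call(cbind, cols)
  colnames(mm) <- names(matrices)
  membership_matrix(mm, ids)
}

.pattern_key <- function(membership) {
  # canonical key: member set labels joined by "&" in column order
  sets <- colnames(membership)
  apply(membership, 1, function(r) paste(sets[r], collapse = "&"))
}

#' Exclusive intersections (UpSet counts)
#'
#' Partitions the features in at least one set by their full membership
#' pattern — the quantity UpSet bar plots display. Intersections are
#' ordered by decreasing count, ties broken by degree (number of sets) then
#' lexicographic key, so output is deterministic. Counts sum to the number
#' of features in at least one set; features in no set are reported in the
#' `n_none` attribute.
#'
#' @param m a [membership_matrix()].
#' @return data.frame `key` (set labels joined by `&`), `degree`, `count`;
#'   attribute `n_none`.
#' @export
exclusive_intersections <- function(m) {
  stopifnot(inherits(m, "membership_matrix"))
  deg <- rowSums(m$membership)
  inset <- deg > 0
  if (!any(inset)) {
    out <- data.frame(key = character(0), degree = integer(0),
                      count = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_none") <- sum(!inset)
    return(out)
  }
  keys <- .pattern_key(m$membership[inset, , drop = FALSE])
  tab <- table(keys)
  key <- names(tab)
  degree <- vapply(strsplit(key, "&", fixed = TRUE), length, 1L)
  count <- as.integer(tab)
  o <- order(-count, degree, key)
  out <- data.frame(key = key[o], degree = degree[o], count = count[o],
                    stringsAsFactors = FALSE)
  attr(out, "n_none") <- sum(!inset)
  out
}

#' Pairwise Venn counts
#'
#' @param m a [membership_matrix()] with exactly two sets.
#' @return named integer vector `(only_a, only_b, both)` where a/b are the
#'   first/second set.
#' @export
venn_counts <- function(m) {
  stopifnot(inherits(m, "membership_matrix"))
  if (ncol(m$membership) != 2L)
    stop("venn_counts needs exactly two sets", call. = FALSE)
  a <- m$membership[, 1]; b <- m$membership[, 2]
  c(only_a = sum(a & !b), only_b = sum(!a & b), both = sum(a & b))
}

#' Export the features of one exclusive intersection
#'
#' @param m a [membership_matrix()].
#' @param key intersection key: a character vector of set labels, or the
#'   `&`-joined key string from [exclusive_intersections()].
#' @param annotations optional feature table (one row per universe feature,
#'   row-aligned) joined onto the output.
#' @return data.frame of the features whose exclusive membership pattern
#'   equals `key`, in universe order; empty for an absent pattern.
#' @export
subset_export <- function(m, key, annotations = NULL) {
  stopifnot(inherits(m, "membership_matrix"))
  if (length(key) == 1L && grepl("&", key, fixed = TRUE))
    key <- strsplit(key, "&", fixed = TRUE)[[1]]
  unknown <- setdiff(key, m$sets)
  if (length(unknown))
    stop(sprintf("unknown set label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  want <- m$sets %in% key
  hit <- apply(m$membership, 1, function(r) all(r == want))
  out <- data.frame(id = m$ids[hit], stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != length(m$ids))
      stop("annotations must be row-aligned to the feature universe",
           call. = FALSE)
    out <- cbind(out, annotations[hit, , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}
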