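#' Construct an expression dataset
#'
#' Bundles a feature-by-sample numeric matrix with per-feature annotations
#' (one designated ID column) and a per-sample design table. This is the
#' central container consumed by every analysis function in the package:
#' values are expected on a log-like scale (log2 intensities, voom-transformed
#' counts, ...) and missing values are allowed throughout.
#'
#' @param matrix numeric matrix, features in rows, samples in columns. Column
#'   names must be sample identifiers present in `design`.
#' @param annotations data.frame of per-feature annotation columns, one row
#'   per matrix row. Must contain `id_column`.
#' @param design data.frame with one row per sample. The column named by
#'   `sample_column` holds the sample identifiers.
#' @param id_column name of the annotation column carrying the feature IDs
#'   used to map datasets onto each other (e.g. gene symbols).
#' @param name label for the dataset, used in outputs.
#' @param sample_column name of the design column holding sample identifiers.
#' @return An object of class `omic_dataset` with elements `name`, `matrix`,
#'   `annotations`, `design`, `id_column`, `sample_column`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("s1", "s2")))
#' ann <- data.frame(gene = c("g1", "g2", "g3"))
#' des <- data.frame(sample = c("s1", "s2"), group = c("a", "b"))
#' ds <- omic_dataset(m, ann, des, id_column = "gene")
#' @export
omic_dataset <- function(matrix, annotations, design, id_column,
                         name = "dataset", sample_column = "sample") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)

  if (!is.character(id_column) || length(id_column) != 1L)
    stop("`id_column` must be a single column name", call. = FALSE)
  if (!id_column %in% names(annotations))
    stop(sprintf("id_column '%s' not found; available annotation columns: %s",
                 id_column, paste(names(annotations), collapse = ", ")),
         call. = FALSE)
  if (nrow(matrix) != nrow(annotations))
    stop(sprintf("matrix has %d rows but annotations have %d",
                 nrow(matrix), nrow(annotations)), call. = FALSE)
  if (!sample_column %in% names(design))
    stop(sprintf("sample column '%s' not found in design; available: %s",
                 sample_column, paste(names(design), collapse = ", ")),
         call. = FALSE)
  samples <- as.character(design[[sample_column]])
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample names in design: %s",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
         call. = FALSE)
  if (is.null(colnames(matrix)))
    stop("matrix must have sample names as column names", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample names in matrix columns", call. = FALSE)
  missing_in_design <- setdiff(colnames(matrix), samples)
  if (length(missing_in_design))
    stop(sprintf("matrix samples absent from design: %s",
                 paste(missing_in_design, collapse = ", ")), call. = FALSE)

  structure(
    list(name = name, matrix = matrix, annotations = annotations,
         design = design, id_column = id_column,
         sample_column = sample_column),
    class = "omic_dataset")
}

#' @export
print.omic_dataset <- function(x, ...) {
  cat(sprintf("omic_dataset '%s': %d features x %d samples\n",
              x$name, nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  id column: %s; annotation columns: %s\n", x$id_column,
              paste(names(x$annotations), collapse = ", ")))
  cat(sprintf("  design columns: %s\n",
              paste(names(x$design), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$matrix)),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' @export
dim.omic_dataset <- function(x) dim(x$matrix)

#' Feature IDs of a dataset
#' @param ds an `omic_dataset`.
#' @return character vector of the ID column values, in row order.
#' @export
feature_ids <- function(ds) {
  stopifnot(inherits(ds, "omic_dataset"))
  as.character(ds$annotations[[ds$id_column]])
}

# Tokens treated as missing in input tables (case-insensitive).
MISSING_TOKENS <- c("", "na", "nan", "null")

#' Coerce a character/mixed vector to numeric with missing-token handling
#'
#' Empty strings and "NA"/"NaN"/"null" (any case) become NA; anything else
#' that fails numeric parsing also becomes NA. Zeros are kept unless
#' `zero_as_missing` is set (some upstream pipelines encode below-detection
#' values as zero).
#' @keywords internal
.parse_numeric <- function(x, zero_as_missing = FALSE) {
  if (is.numeric(x)) {
    out <- as.double(x)
  } else {
    x <- trimws(as.character(x))
    x[tolower(x) %in% MISSING_TOKENS] <- NA_character_
    out <- suppressWarnings(as.double(x))
  }
  if (zero_as_missing) out[!is.na(out) & out == 0] <- NA_real_
  out
}

# Sniff the delimiter of a text table: tab or comma only. A file whose first
# data line contains both (or neither) is ambiguous and needs an explicit
# `delim`.
.sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  has_tab <- grepl("\t", line, fixed = TRUE)
  has_comma <- grepl(",", line, fixed = TRUE)
  if (has_tab && !has_comma) return("\t")
  if (has_comma && !has_tab) return(",")
  if (has_tab && has_comma)
    stop(sprintf(
      "'%s' mixes tabs and commas on its first line; pass `delim` explicitly",
      path), call. = FALSE)
  "\t"  # single-column file: no delimiter in sight, either would do
}

.read_table <- function(path, delim = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) delim <- .sniff_delim(path)
  utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    comment.char = "", quote = "\"", na.strings = NULL)
}

#' Read an expression dataset from matrix and design tables
#'
#' The matrix file holds features in rows; its columns are a mix of
#' annotation columns (including `id_column` and any upstream statistics
#' columns) and one column per sample. Sample columns are recognised by name
#' against the design table's sample identifiers; everything else is kept as
#' annotation. Cells that are empty or read "NA"/"NaN"/"null" (any case), or
#' fail numeric parsing, become missing values.
#'
#' @param matrix_path path to the feature table (TSV or CSV; the delimiter is
#'   sniffed unless `delim` is given).
#' @param design_path path to the design table.
#' @param id_column name of the shared-ID column in the feature table.
#' @param name dataset label.
#' @param sample_column design column holding sample identifiers.
#' @param delim explicit field delimiter (`"\t"` or `","`); required when a
#'   file is ambiguous.
#' @param annotation_columns optional character vector naming the annotation
#'   columns. When given, every remaining matrix column must be a design
#'   sample and vice versa; a mismatch is a validation error naming the
#'   offending samples. When `NULL`, annotations are inferred as the columns
#'   not present in the design.
#' @param zero_as_missing treat exact zeros in the matrix as missing.
#' @return an [omic_dataset].
#' @export
read_omic_dataset <- function(matrix_path, design_path, id_column,
                              name = basename(matrix_path),
                              sample_column = "sample", delim = NULL,
                              annotation_columns = NULL,
                              zero_as_missing = FALSE) {
  feat <- .read_table(matrix_path, delim)
  design <- .read_table(design_path, delim)
  if (!sample_column %in% names(design))
    stop(sprintf("sample column '%s' not found in design; available: %s",
                 sample_column, paste(names(design), collapse = ", ")),
         call. = FALSE)
  if (!id_column %in% names(feat))
    stop(sprintf("id_column '%s' not found; available columns: %s",
                 id_column, paste(names(feat), collapse = ", ")),
         call. = FALSE)
  samples <- as.character(design[[sample_column]])

  if (is.null(annotation_columns)) {
    sample_cols <- intersect(names(feat), samples)
    annotation_columns <- setdiff(names(feat), sample_cols)
  } else {
    missing_ann <- setdiff(annotation_columns, names(feat))
    if (length(missing_ann))
      stop(sprintf("annotation columns not in matrix file: %s",
                   paste(missing_ann, collapse = ", ")), call. = FALSE)
    sample_cols <- setdiff(names(feat), annotation_columns)
    offenders <- setdiff(sample_cols, samples)
    if (length(offenders))
      stop(sprintf("matrix sample columns missing from design: %s",
                   paste(offenders, collapse = ", ")), call. = FALSE)
  }
  if (length(sample_cols) == 0L)
    stop("no matrix columns match design sample identifiers", call. = FALSE)

  m <- vapply(feat[sample_cols], .parse_numeric, numeric(nrow(feat)),
              zero_as_missing = zero_as_missing)
  if (nrow(feat) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(NULL, sample_cols)
  ann <- feat[annotation_columns]
  omic_dataset(m, ann, design, id_column = id_column, name = name,
               sample_column = sample_column)
}

#' Write a dataset back to the matrix/design TSV layout
#'
#' Produces `<prefix>_matrix.tsv` (annotations followed by sample columns)
#' and `<prefix>_design.tsv`. Numeric values are written with 17 significant
#' digits so a read/write cycle reproduces the matrix to full double
#' precision.
#'
#' @param ds an [omic_dataset].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, defaults to the dataset name.
#' @return invisibly, the two file paths.
#' @export
write_omic_dataset <- function(ds, dir, prefix = ds$name) {
  stopifnot(inherits(ds, "omic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- as.data.frame(apply(ds$matrix, 2, function(x)
    ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(ds$matrix) == 1L) {
    num <- as.data.frame(as.list(num[[1]]), check.names = FALSE)
    names(num) <- colnames(ds$matrix)
  }
  out <- cbind(ds$annotations, num)
  mpath <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  dpath <- file.path(dir, paste0(prefix, "_design.tsv"))
  utils::write.table(out, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$design, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mpath, design = dpath))
}

#' Merge two datasets on a shared ID column
#'
#' Maps the rows of two datasets onto each other through a shared ID column
#' (typically gene IDs). When an ID occurs several times within a dataset —
#' multiple transcripts mapping to one gene, say — the first listed entry in
#' file order is used (`dup_policy = "first"`, the "discard duplicates"
#' convention) or merging aborts (`dup_policy = "error"`). Shared IDs keep
#' dataset `a`'s order so downstream output is deterministic.
#'
#' @param a,b [omic_dataset] objects.
#' @param id_column shared ID column; defaults to `a`'s id_column and must
#'   exist in both.
#' @param dup_policy `"first"` (keep first occurrence per dataset) or
#'   `"error"`.
#' @param ignore_case fold IDs to lower case before matching (off by
#'   default: matching is case-sensitive).
#' @return A `merged_pair`: `id_column`, `shared_ids`, integer row indices
#'   `rows_a`/`rows_b`, and `dropped_duplicates_a`/`_b` (each a list with
#'   `count` and up to 10 `examples`).
#' @export
merge_on_id <- function(a, b, id_column = a$id_column,
                        dup_policy = c("first", "error"),
                        ignore_case = FALSE) {
  stopifnot(inherits(a, "omic_dataset"), inherits(b, "omic_dataset"))
  dup_policy <- match.arg(dup_policy)
  for (ds in list(a, b))
    if (!id_column %in% names(ds$annotations))
      stop(sprintf("id_column '%s' not found in dataset '%s'",
                   id_column, ds$name), call. = FALSE)
  ids_a <- as.character(a$annotations[[id_column]])
  ids_b <- as.character(b$annotations[[id_column]])
  key_a <- if (ignore_case) tolower(ids_a) else ids_a
  key_b <- if (ignore_case) tolower(ids_b) else ids_b

  dedup <- function(keys, label) {
    dup <- duplicated(keys)
    if (any(dup) && dup_policy == "error") {
      bad <- unique(keys[dup])
      stop(sprintf("duplicate IDs in dataset '%s': %s%s", label,
                   paste(utils::head(bad, 10), collapse = ", "),
                   if (length(bad) > 10) ", ..." else ""), call. = FALSE)
    }
    list(idx = which(!dup),
         dropped = list(count = sum(dup),
                        examples = utils::head(unique(keys[dup]), 10)))
  }
  da <- dedup(key_a, a$name)
  db <- dedup(key_b, b$name)

  keep_a <- da$idx[key_a[da$idx] %in% key_b[db$idx]]
  if (length(keep_a) == 0L)
    stop(sprintf("no shared IDs between '%s' and '%s' on column '%s'",
                 a$name, b$name, id_column), call. = FALSE)
  rows_b <- db$idx[match(key_a[keep_a], key_b[db$idx])]

  structure(
    list(id_column = id_column, shared_ids = ids_a[keep_a],
         rows_a = keep_a, rows_b = rows_b,
         dropped_duplicates_a = da$dropped,
         dropped_duplicates_b = db$dropped,
         name_a = a$name, name_b = b$name),
    class = "merged_pair")
}

#' @export
print.merged_pair <- function(x, ...) {
  cat(sprintf("merged_pair on '%s': %d shared IDs ('%s' vs '%s')\n",
              x$id_column, length(x$shared_ids), x$name_a, x$name_b))
  cat(sprintf("  dropped duplicates: %d in a, %d in b\n",
              x$dropped_duplicates_a$count, x$dropped_duplicates_b$count))
  invisible(x)
}

#' Save or load an analysis settings snapshot
#'
#' A snapshot is a named list of serialisable scalars/vectors/maps
#' (thresholds, bin edges, contrast names, seeds). It is written as UTF-8
#' JSON with full-precision numbers and stable key order, so saving, loading
#' and saving again yields a byte-identical file. JSON carries a single
#' number type: integers come back as doubles.
#'
#' @param s named list of settings.
#' @param path file path for the JSON snapshot.
#' @return `load_settings` returns the settings list; `save_settings` its
#'   path, invisibly.
#' @export
save_settings <- function(s, path) {
  stopifnot(is.list(s))
  json <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_settings
#' @export
load_settings <- function(path) {
  if (!file.exists(path))
    stop(sprintf("settings file not found: %s", path), call. = FALSE)
  out <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e)
      stop(sprintf("cannot parse settings file '%s': %s",
                   path, conditionMessage(e)), call. = FALSE))
  out
}
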