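#' Assemble a CITE-Seq dataset container
#'
#' Bundles a cells-by-features count matrix with its feature table and per-cell
#' metadata. Features carry a `kind` flag (`"surface"` for antibody-derived
#' tags, `"transcript"` for RNA) and a mitochondrial flag used by the droplet
#' filters; cells carry patient, group and batch labels, with patients nested
#' in groups.
#'
#' @param counts cells x features matrix of non-negative integer counts
#'   (dense or `Matrix` sparse).
#' @param features data frame with columns `feature_id`, `feature_name`,
#'   `kind` (one of `"surface"`, `"transcript"`) and `is_mitochondrial`.
#' @param cells data frame with columns `cell_id`, `patient_id`, `group_id`,
#'   `batch_id`, one row per matrix row.
#' @return An object of class `citeseq_dataset`: a list with elements
#'   `counts`, `features`, `cells`.
#' @export
new_dataset <- function(counts, features, cells) {
  features <- as.data.frame(features)
  cells <- as.data.frame(cells)
  needed_f <- c("feature_id", "feature_name", "kind", "is_mitochondrial")
  if (!all(needed_f %in% names(features)))
    stop("features must have columns: ", paste(needed_f, collapse = ", "))
  needed_c <- c("cell_id", "patient_id", "group_id", "batch_id")
  if (!all(needed_c %in% names(cells)))
    stop("cells must have columns: ", paste(needed_c, collapse = ", "))
  if (nrow(counts) != nrow(cells))
    stop("counts has ", nrow(counts), " rows but cells has ", nrow(cells))
  if (ncol(counts) != nrow(features))
    stop("counts has ", ncol(counts), " columns but features has ", nrow(features))
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell barcodes: ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]), collapse = ", "))
  if (!all(features$kind %in% c("surface", "transcript")))
    stop("feature kind must be 'surface' or 'transcript'")
  if (any(features$is_mitochondrial & features$kind == "surface"))
    stop("surface features cannot be flagged mitochondrial")
  # each patient belongs to exactly one group
  pg <- unique(cells[, c("patient_id", "group_id")])
  dup <- pg$patient_id[duplicated(pg$patient_id)]
  if (length(dup))
    stop("patient(s) mapped to more than one group: ", paste(dup, collapse = ", "))
  if (length(counts) && min(counts) < 0) stop("counts must be non-negative")
  rownames(counts) <- cells$cell_id
  colnames(counts) <- features$feature_id
  structure(list(counts = counts, features = features, cells = cells),
            class = "citeseq_dataset")
}

#' @export
print.citeseq_dataset <- function(x, ...) {
  cat("citeseq_dataset:", nrow(x$cells), "cells x", nrow(x$features), "features\n")
  cat("  surface markers:", sum(x$features$kind == "surface"),
      " transcripts:", sum(x$features$kind == "transcript"),
      " (mitochondrial:", sum(x$features$is_mitochondrial), ")\n")
  cat("  patients:", length(unique(x$cells$patient_id)),
      " groups:", paste(unique(x$cells$group_id), collapse = "/"),
      " batches:", length(unique(x$cells$batch_id)), "\n")
  invisible(x)
}

#' @export
dim.citeseq_dataset <- function(x) c(nrow(x$cells), nrow(x$features))

#' Subset a dataset by cells and/or features
#'
#' @param dataset a `citeseq_dataset`.
#' @param cells logical/integer/character index into cell rows.
#' @param features logical/integer/character index into feature rows.
#' @return The subsetted `citeseq_dataset`.
#' @export
subset_dataset <- function(dataset, cells = NULL, features = NULL) {
  counts <- dataset$counts
  cell_df <- dataset$cells
  feat_df <- dataset$features
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, cell_df$cell_id)
    counts <- counts[cells, , drop = FALSE]
    cell_df <- cell_df[cells, , drop = FALSE]
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, feat_df$feature_id)
    counts <- counts[, features, drop = FALSE]
    feat_df <- feat_df[features, , drop = FALSE]
  }
  rownames(cell_df) <- NULL
  rownames(feat_df) <- NULL
  new_dataset(counts, feat_df, cell_df)
}

#' Extract the surface-marker count submatrix
#'
#' @param dataset a `citeseq_dataset`.
#' @return Dense cells x markers matrix of ADT counts, columns named by
#'   feature name.
#' @export
marker_counts <- function(dataset) {
  keep <- dataset$features$kind == "surface"
  m <- as.matrix(dataset$counts[, keep, drop = FALSE])
  colnames(m) <- dataset$features$feature_name[keep]
  m
}

#' Extract the transcript count submatrix
#'
#' @param dataset a `citeseq_dataset`.
#' @return Sparse cells x genes matrix, columns named by feature name.
#' @export
transcript_counts <- function(dataset) {
  keep <- dataset$features$kind == "transcript"
  m <- dataset$counts[, keep, drop = FALSE]
  colnames(m) <- dataset$features$feature_name[keep]
  m
}
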