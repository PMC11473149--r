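#' Read a CellRanger-style MTX triplet plus cell metadata
#'
#' Loads a Matrix Market count matrix with its `features.tsv` /
#' `barcodes.tsv` sidecars (genes/markers as matrix rows, cells as columns,
#' as CellRanger writes them) and joins per-cell metadata. The returned
#' dataset stores cells as rows.
#'
#' The features file is tab-delimited with columns id, name, type; type
#' `"Antibody Capture"` maps to surface markers, anything else to
#' transcripts. Mitochondrial genes are recognised by a feature-name prefix.
#' The metadata join is strict: every barcode must appear in the metadata
#' table, because the downstream harmonization requires complete
#' patient/group/batch nesting.
#'
#' @param matrix_path Matrix Market coordinate file (plain or gzipped).
#' @param features_path tab-delimited features file, no header.
#' @param barcodes_path one barcode per line, no header.
#' @param metadata_path delimited text with header, columns `cell_id`,
#'   `patient_id`, `group_id`, `batch_id`.
#' @param mito_prefix feature-name prefix flagging mitochondrial transcripts.
#' @param known_groups,known_batches optional vectors of allowed labels;
#'   labels outside them raise an error.
#' @return A [new_dataset()] container with cells ordered as in the barcodes
#'   file.
#' @export
read_mtx_dataset <- function(matrix_path, features_path, barcodes_path,
                             metadata_path, mito_prefix = "MT-",
                             known_groups = NULL, known_batches = NULL) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(feats))
    stop("matrix has ", nrow(m), " rows but features file lists ", nrow(feats))
  if (ncol(m) != length(barcodes))
    stop("matrix has ", ncol(m), " columns but barcodes file lists ",
         length(barcodes))
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  kind <- if (ncol(feats) >= 3) {
    ifelse(feats[[3]] == "Antibody Capture", "surface", "transcript")
  } else rep("transcript", nrow(feats))
  features <- data.frame(
    feature_id = feats[[1]],
    feature_name = if (ncol(feats) >= 2) feats[[2]] else feats[[1]],
    kind = kind,
    is_mitochondrial = kind == "transcript" &
      startsWith(if (ncol(feats) >= 2) feats[[2]] else feats[[1]], mito_prefix),
    stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(meta))
    stop("metadata must contain a cell_id column")
  idx <- match(barcodes, meta$cell_id)
  if (anyNA(idx))
    stop("metadata missing barcode(s): ",
         paste(barcodes[is.na(idx)], collapse = ", "))
  cells <- meta[idx, c("cell_id", "patient_id", "group_id", "batch_id")]
  rownames(cells) <- NULL
  if (!is.null(known_groups) && !all(cells$group_id %in% known_groups))
    stop("unknown group label(s): ",
         paste(setdiff(cells$group_id, known_groups), collapse = ", "))
  if (!is.null(known_batches) && !all(cells$batch_id %in% known_batches))
    stop("unknown batch label(s): ",
         paste(setdiff(cells$batch_id, known_batches), collapse = ", "))
  counts <- Matrix::t(Matrix::Matrix(m, sparse = TRUE))  # cells x features
  new_dataset(counts, features, cells)
}

#' Write a dataset as an MTX triplet plus metadata
#'
#' Inverse of [read_mtx_dataset()]; features are written as matrix rows in
#' the CellRanger dialect.
#'
#' @param dataset a `citeseq_dataset`.
#' @param dir output directory, created if absent.
#' @return The directory path, invisibly.
#' @export
write_mtx_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(Matrix::Matrix(dataset$counts, sparse = TRUE)),
                  file.path(dir, "matrix.mtx"))
  type <- ifelse(dataset$features$kind == "surface",
                 "Antibody Capture", "Gene Expression")
  utils::write.table(
    data.frame(dataset$features$feature_id, dataset$features$feature_name, type),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dataset$cells$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.csv(dataset$cells, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write / read a patients-by-clusters abundance table
#'
#' Comma-delimited text with a header row; the first column holds patient
#' ids, remaining columns one cluster each. Round-trips to full precision.
#' On read, rows that do not sum to 1 within tolerance raise a warning (not
#' an error: count-derived tables may be re-normalized downstream).
#'
#' @param table an [abundance_table()] or plain patients x clusters matrix of
#'   proportions.
#' @param path file path.
#' @return `read_abundance_table` returns a proportions matrix of class
#'   `abundance_table` (with a `groups` attribute if the file carries a
#'   `group_id` column); `write_abundance_table` returns `path` invisibly.
#' @export
write_abundance_table <- function(table, path) {
  m <- unclass(table)
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0)
    stop("empty abundance table")
  if (any(m < 0)) stop("abundance table contains negative proportions")
  df <- data.frame(patient_id = rownames(m), check.names = FALSE)
  groups <- attr(table, "groups")
  if (!is.null(groups)) df$group_id <- as.character(groups[rownames(m)])
  # 17 significant digits: doubles survive the text round-trip exactly
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
               dimnames = dimnames(m))
  df <- cbind(df, as.data.frame(fm, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty abundance table")
  groups <- NULL
  if ("group_id" %in% names(df)) {
    groups <- stats::setNames(df$group_id, df$patient_id)
    df$group_id <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (ncol(m) == 0) stop("empty abundance table")
  if (any(m < 0)) stop("abundance table contains negative proportions")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6))
    warning("abundance rows do not sum to 1 (max deviation ",
            format(max(abs(rs - 1))), "); table may need re-normalization")
  structure(m, class = "abundance_table", groups = groups)
}
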