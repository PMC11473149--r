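#' Centered log-ratio normalization of marker counts
#'
#' Per cell, zero counts are replaced by `zero_replacement` (half the
#' quantification limit, assuming a limit of 1 count) and the values are
#' mapped to `log(x) - mean(log(x))` over markers, so every row has mean 0.
#' The log lives inside the CLR; no further log is applied (a second log
#' would be ill-defined for negative CLR values).
#'
#' @param marker_counts cells x markers matrix of non-negative counts.
#' @param zero_replacement value substituted for exact zeros (default 0.5);
#'   positive entries are never altered.
#' @return A `clr_matrix`: the transformed matrix with attributes
#'   `zero_replacement` and `replaced_fraction` (share of entries replaced).
#' @export
clr_normalize <- function(marker_counts, zero_replacement = 0.5) {
  x <- as.matrix(marker_counts)
  if (ncol(x) < 1) stop("need at least one marker")
  if (any(x < 0)) stop("marker counts must be non-negative")
  zero <- x == 0
  if (zero_replacement <= 0 && any(rowSums(!zero) == 0))
    stop("cell(s) with all counts zero and no positive zero replacement")
  x[zero] <- zero_replacement
  lx <- log(x)
  out <- lx - rowMeans(lx)
  structure(out, class = c("clr_matrix", class(out)),
            zero_replacement = zero_replacement,
            replaced_fraction = mean(zero))
}

# per-marker mean by label, cells x markers in, labels x markers out
.means_by <- function(x, labels) {
  f <- factor(labels)
  sums <- rowsum(x, f)
  sums / as.vector(table(f))[match(rownames(sums), levels(f))]
}

#' Remove batch effects by marker-mean equalization
#'
#' Per marker, subtracts each batch's mean deviation from the overall mean,
#' so after correction every batch has the same (the overall, cell-weighted)
#' mean for every marker. The overall marker mean is unchanged.
#'
#' @param clr cells x markers CLR-scale matrix.
#' @param cells per-cell metadata with a `batch_id` column aligned to rows.
#' @return The corrected matrix, with a `batch_offsets` attribute recording
#'   the per-batch, per-marker offsets that were subtracted.
#' @export
harmonize_batches <- function(clr, cells) {
  x <- unclass(clr)
  if (nrow(x) != nrow(cells)) stop("metadata rows must match matrix rows")
  batch <- as.character(cells$batch_id)
  tab <- table(batch)
  if (any(tab == 0)) stop("batch with 0 cells")
  overall <- colMeans(x)
  bm <- .means_by(x, batch)
  offsets <- sweep(bm, 2, overall)       # batch mean - overall mean
  out <- x - offsets[batch, , drop = FALSE]
  attrs <- attributes(clr)
  attributes(out)[c("zero_replacement", "replaced_fraction")] <-
    attrs[c("zero_replacement", "replaced_fraction")]
  structure(out, class = class(clr), batch_offsets = offsets)
}

#' Group-preserving removal of between-patient variability
#'
#' For each marker m, patient i in group g: the patient mean over the
#' patient's cells and the group mean over all the group's cells are
#' computed, and every cell value is shifted by (group mean - patient mean).
#' After correction each patient's mean equals its group's mean, so patient
#' effects are cancelled while any existing difference in mean between
#' groups is kept exactly -- the property that off-the-shelf batch tools
#' would destroy in this nested design. The operation is an idempotent
#' linear projection.
#'
#' @param clr cells x markers CLR-scale matrix (typically batch-corrected).
#' @param cells per-cell metadata with `patient_id` and `group_id` columns
#'   aligned to rows; every patient needs at least one cell.
#' @return A `harmonized_matrix`: the corrected matrix with attributes
#'   `patient_means` and `group_means` (before correction), `group_sizes`
#'   (cells per group) and `patient_cells`.
#' @export
harmonize_patients <- function(clr, cells) {
  x <- unclass(clr)
  if (nrow(x) != nrow(cells)) stop("metadata rows must match matrix rows")
  n_cells <- table(cells$patient_id)  # factors keep empty levels
  if (any(n_cells == 0)) stop("patient with 0 cells: ",
                              paste(names(n_cells)[n_cells == 0], collapse = ", "))
  patient <- as.character(cells$patient_id)
  group <- as.character(cells$group_id)
  pg <- unique(data.frame(patient, group))
  if (anyDuplicated(pg$patient))
    stop("patient(s) in more than one group")
  n_cells <- table(patient)
  pat_means <- .means_by(x, patient)
  grp_means <- .means_by(x, group)
  grp_of <- stats::setNames(pg$group, pg$patient)
  offsets <- pat_means - grp_means[grp_of[rownames(pat_means)], , drop = FALSE]
  out <- x - offsets[patient, , drop = FALSE]
  structure(out,
            class = c("harmonized_matrix", "matrix", "array"),
            patient_means = pat_means,
            group_means = grp_means,
            group_sizes = as.vector(table(group)[rownames(grp_means)]),
            patient_cells = as.vector(n_cells[rownames(pat_means)]),
            patient_group = grp_of)
}

#' Full nested harmonization: batch then patient correction
#'
#' Composite of [harmonize_batches()] and [harmonize_patients()]; each marker
#' is corrected separately. Batch correction is applied first by default so
#' that the patient-mean-equals-group-mean invariant, stated on the final
#' matrix, survives exactly (only the last-applied correction's invariant
#' is exact); the opposite order is available via `batch_first = FALSE`.
#' With a single batch the composite reduces to the patient correction.
#'
#' @param clr cells x markers CLR-scale matrix.
#' @param cells per-cell metadata with `patient_id`, `group_id`, `batch_id`.
#' @param batch_first apply batch correction before patient correction.
#' @return A `harmonized_matrix` (see [harmonize_patients()]).
#' @export
harmonize <- function(clr, cells, batch_first = TRUE) {
  if (batch_first) {
    harmonize_patients(harmonize_batches(clr, cells), cells)
  } else {
    h <- harmonize_patients(clr, cells)
    out <- harmonize_batches(h, cells)
    class(out) <- class(h)
    out
  }
}
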