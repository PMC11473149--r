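#' Describe a synthetic CITE-Seq cohort
#'
#' Parameterises the generator used to exercise the pipeline with known
#' ground truth. Defaults emulate the design of a three-group bone marrow
#' engraftment cohort: 4 healthy donors (D), 7 recipients in stratum R1 and 3
#' in stratum R2, 36 cell clusters, 137 surface markers, and transcript
#' counts (with mitochondrial genes) for QC testing. The study analysed
#' roughly 5,000 cells per patient; the default here is 500 so that tests run
#' at desk scale, and `cells_per_patient` scales it back up.
#'
#' Marker signal for a cell is built on the CLR (log) scale as
#' archetype(cluster) + patient effect + batch effect + cell noise, then
#' inverted to counts by rounding the exponential, so zero counts occur and
#' the half-quantification-limit replacement path is exercised. Cluster
#' memberships are drawn from a logistic-normal abundance vector per patient
#' (baseline + group effect + patient noise), matching the log-ratio scale on
#' which abundances are later tested.
#'
#' @param groups named integer vector: patients per group.
#' @param n_clusters,n_markers,cells_per_patient,n_batches cohort dimensions.
#' @param n_genes,n_mito_genes transcript features (mitochondrial genes are
#'   named with the `MT-` prefix).
#' @param sigma_patient,sigma_batch,sigma_cell standard deviations of the
#'   patient, batch and cell-level marker noise on the CLR scale.
#' @param sigma_abund patient-level sd of cluster log-abundances.
#' @param baseline_logabund optional length-`n_clusters` baseline
#'   log-abundance vector; drawn N(0, 0.75) under the seed when `NULL`.
#' @param group_abundance_effects data frame with columns `group_id`,
#'   `cluster`, `effect`: log-abundance shifts for selected clusters. The
#'   default plants a +1 shift on cluster 1 in R2.
#' @param marker_group_effects optional data frame with columns `group_id`,
#'   `marker`, `effect`: direct CLR-scale group shifts on named markers
#'   (none by default; used for harmonization recovery experiments).
#' @param archetypes optional cluster x marker CLR-scale mean matrix; built
#'   under the seed when `NULL` (about `on_markers` markers at +`on_effect`
#'   per cluster over N(1, 0.5) marker baselines).
#' @param on_markers,on_effect archetype construction parameters.
#' @param mean_transcripts,transcript_size negative-binomial total transcript
#'   count per droplet (mean and dispersion size).
#' @param mito_shape1,mito_shape2 Beta parameters of the per-cell
#'   mitochondrial fraction (defaults give mean 5%).
#' @param qc_rates named list of planted QC-violation rates: `empty`,
#'   `no_mito`, `low_total`, `high_total`, `high_mito`.
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(groups = c(D = 4, R1 = 7, R2 = 3),
                              n_clusters = 36,
                              n_markers = 137,
                              cells_per_patient = 500,
                              n_batches = 2,
                              n_genes = 200,
                              n_mito_genes = 13,
                              sigma_patient = 0.3,
                              sigma_batch = 0.2,
                              sigma_cell = 0.5,
                              sigma_abund = 0.5,
                              baseline_logabund = NULL,
                              group_abundance_effects =
                                data.frame(group_id = "R2", cluster = 1,
                                           effect = 1),
                              marker_group_effects = NULL,
                              archetypes = NULL,
                              on_markers = 8,
                              on_effect = 2,
                              mean_transcripts = 2000,
                              transcript_size = 10,
                              mito_shape1 = 2,
                              mito_shape2 = 38,
                              qc_rates = list(empty = 0.01, no_mito = 0.01,
                                              low_total = 0.02,
                                              high_total = 0.01,
                                              high_mito = 0.02),
                              seed = 1) {
  if (n_clusters < 1) stop("need at least one cluster")
  if (any(groups < 1)) stop("every group needs at least one patient")
  sds <- c(sigma_patient, sigma_batch, sigma_cell, sigma_abund)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (!is.null(baseline_logabund)) {
    if (length(baseline_logabund) != n_clusters || !all(is.finite(baseline_logabund)))
      stop("baseline_logabund must be a finite vector of length n_clusters")
  }
  structure(as.list(environment()), class = "simulation_design")
}

# default marker names: M001..M135 plus the two light chains used to
# exercise the marker blacklist
.marker_names <- function(n) {
  nm <- sprintf("M%03d", seq_len(n))
  if (n >= 2) nm[(n - 1):n] <- c("Igkappa", "Iglambda")
  nm
}

#' Simulate a CITE-Seq cohort with ground truth
#'
#' Draws a full synthetic dataset under a [simulation_design()]: per-patient
#' cluster memberships, CLR-scale surface-marker signal with patient/batch
#' effects inverted to counts, and negative-binomial transcript totals with a
#' mitochondrial fraction, including planted QC violations (empty droplets,
#' no-mitochondria droplets, low/high totals, high mitochondrial fraction).
#'
#' @param design a [simulation_design()].
#' @return A list with elements `dataset` (a [new_dataset()]) and `truth`:
#'   per-cell true cluster labels, per-patient true abundance vectors, the
#'   planted patient/batch/group effect values, archetype matrix, and the ids
#'   of cells planted as QC violations.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(d$seed)
  patients <- unlist(lapply(names(d$groups), function(g)
    paste0(g, "_p", seq_len(d$groups[[g]]))))
  pat_group <- rep(names(d$groups), d$groups)
  names(pat_group) <- patients
  pat_batch <- paste0("B", ((seq_along(patients) - 1) %% d$n_batches) + 1)
  names(pat_batch) <- patients
  n_pat <- length(patients)
  n_cells <- n_pat * d$cells_per_patient

  marker_names <- .marker_names(d$n_markers)
  baseline_m <- stats::rnorm(d$n_markers, 1, 0.5)
  arch <- d$archetypes
  if (is.null(arch)) {
    arch <- matrix(0, d$n_clusters, d$n_markers)
    for (k in seq_len(d$n_clusters)) {
      on <- sample.int(d$n_markers, min(d$on_markers, d$n_markers))
      arch[k, on] <- d$on_effect
    }
  }
  rownames(arch) <- paste0("C", seq_len(d$n_clusters))
  colnames(arch) <- marker_names

  base_la <- d$baseline_logabund
  if (is.null(base_la)) base_la <- stats::rnorm(d$n_clusters, 0, 0.75)

  pat_eff <- matrix(stats::rnorm(n_pat * d$n_markers, 0, d$sigma_patient),
                    n_pat, d$n_markers, dimnames = list(patients, marker_names))
  batches <- paste0("B", seq_len(d$n_batches))
  batch_eff <- matrix(stats::rnorm(d$n_batches * d$n_markers, 0, d$sigma_batch),
                      d$n_batches, d$n_markers,
                      dimnames = list(batches, marker_names))
  group_marker <- matrix(0, length(d$groups), d$n_markers,
                         dimnames = list(names(d$groups), marker_names))
  if (!is.null(d$marker_group_effects)) {
    for (r in seq_len(nrow(d$marker_group_effects))) {
      e <- d$marker_group_effects[r, ]
      group_marker[as.character(e$group_id), as.character(e$marker)] <-
        group_marker[as.character(e$group_id), as.character(e$marker)] + e$effect
    }
  }

  # per-patient logistic-normal abundances
  abund <- matrix(0, n_pat, d$n_clusters,
                  dimnames = list(patients, rownames(arch)))
  for (i in seq_len(n_pat)) {
    la <- base_la + stats::rnorm(d$n_clusters, 0, d$sigma_abund)
    ge <- d$group_abundance_effects
    if (!is.null(ge) && nrow(ge)) {
      hit <- ge$group_id == pat_group[i]
      la[ge$cluster[hit]] <- la[ge$cluster[hit]] + ge$effect[hit]
    }
    p <- exp(la - max(la))
    abund[i, ] <- p / sum(p)
  }

  cell_patient <- rep(patients, each = d$cells_per_patient)
  cluster <- integer(n_cells)
  for (i in seq_len(n_pat)) {
    idx <- which(cell_patient == patients[i])
    cluster[idx] <- sample.int(d$n_clusters, length(idx), replace = TRUE,
                               prob = abund[i, ])
  }

  # surface-marker counts from CLR-scale signal
  signal <- matrix(baseline_m, n_cells, d$n_markers, byrow = TRUE) +
    arch[cluster, , drop = FALSE] +
    pat_eff[cell_patient, , drop = FALSE] +
    batch_eff[pat_batch[cell_patient], , drop = FALSE] +
    group_marker[pat_group[cell_patient], , drop = FALSE]
  signal <- signal + matrix(stats::rnorm(n_cells * d$n_markers, 0, d$sigma_cell),
                            n_cells, d$n_markers)
  surface <- round(exp(signal))

  # transcript counts: NB total, Beta mitochondrial fraction
  gene_names <- c(paste0("MT-G", seq_len(d$n_mito_genes)),
                  sprintf("G%04d", seq_len(d$n_genes - d$n_mito_genes)))
  is_mito_gene <- startsWith(gene_names, "MT-")
  w_rest <- stats::rexp(sum(!is_mito_gene))
  totals <- stats::rnbinom(n_cells, mu = d$mean_transcripts,
                           size = d$transcript_size)
  mito_frac <- stats::rbeta(n_cells, d$mito_shape1, d$mito_shape2)

  # plant QC violations on disjoint cell subsets
  rates <- d$qc_rates
  n_plant <- vapply(rates, function(r) round(r * n_cells), numeric(1))
  planted <- split(sample.int(n_cells, sum(n_plant)),
                   rep(names(n_plant), n_plant))
  for (nm in setdiff(names(rates), names(planted))) planted[[nm]] <- integer(0)
  totals[planted$empty] <- 0
  totals[planted$low_total] <- sample(1:250, length(planted$low_total),
                                      replace = TRUE)
  totals[planted$high_total] <- sample(12000:20000, length(planted$high_total),
                                       replace = TRUE)
  mito_frac[planted$no_mito] <- 0
  mito_frac[planted$high_mito] <- stats::runif(length(planted$high_mito),
                                               0.15, 0.30)

  mito_tot <- stats::rbinom(n_cells, totals, mito_frac)
  trans <- matrix(0L, n_cells, d$n_genes)
  colnames(trans) <- gene_names
  nm_idx <- which(!is_mito_gene)
  m_idx <- which(is_mito_gene)
  for (c_i in seq_len(n_cells)) {
    rest <- totals[c_i] - mito_tot[c_i]
    if (rest > 0)
      trans[c_i, nm_idx] <- stats::rmultinom(1, rest, w_rest)[, 1]
    if (mito_tot[c_i] > 0)
      trans[c_i, m_idx] <- stats::rmultinom(1, mito_tot[c_i],
                                            rep(1, length(m_idx)))[, 1]
  }

  counts <- cbind(surface, trans)
  features <- data.frame(
    feature_id = c(paste0("ADT-", marker_names), paste0("ENSG-", gene_names)),
    feature_name = c(marker_names, gene_names),
    kind = rep(c("surface", "transcript"), c(d$n_markers, d$n_genes)),
    is_mitochondrial = c(rep(FALSE, d$n_markers), is_mito_gene),
    stringsAsFactors = FALSE)
  cells <- data.frame(
    cell_id = sprintf("%s_c%04d", cell_patient,
                      sequence(rep(d$cells_per_patient, n_pat))),
    patient_id = cell_patient,
    group_id = pat_group[cell_patient],
    batch_id = pat_batch[cell_patient],
    stringsAsFactors = FALSE)

  dataset <- new_dataset(Matrix::Matrix(counts, sparse = TRUE), features, cells)
  truth <- list(
    cluster = stats::setNames(cluster, cells$cell_id),
    abundance = structure(abund, class = "abundance_table",
                          groups = pat_group),
    archetypes = arch,
    baseline_marker = stats::setNames(baseline_m, marker_names),
    baseline_logabund = base_la,
    patient_effects = pat_eff,
    batch_effects = batch_eff,
    group_marker_effects = group_marker,
    group_abundance_effects = d$group_abundance_effects,
    patient_group = pat_group,
    patient_batch = pat_batch,
    planted_qc = lapply(planted, function(i) cells$cell_id[i]))
  list(dataset = dataset, truth = truth)
}

# one null draw of per-patient log-abundances (no group effect):
# iid standard normal, rows = patients, cols = nodes
.null_logabund <- function(n_patients, n_nodes) {
  matrix(stats::rnorm(n_patients * n_nodes), n_patients, n_nodes)
}

#' Null per-patient abundance draws for threshold calibration
#'
#' Draws iid standard normal log-abundances per (patient, node) with no group
#' effect, exponentiates, and row-normalizes to the simplex. The two-sample t
#' statistic on between-node log-ratios is location/scale pivotal, so the
#' calibrated threshold does not depend on the null's mean or variance.
#'
#' @param n_nodes number of clusters (graph nodes), at least 2.
#' @param n1,n2 group sizes, each at least 2.
#' @param seed integer seed.
#' @return An `abundance_table` of `n1 + n2` rows whose `groups` attribute
#'   labels the first `n1` patients `"A"` and the rest `"B"`.
#' @export
simulate_null_abundances <- function(n_nodes, n1, n2, seed) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 patients (t-test undefined)")
  set.seed(seed)
  la <- .null_logabund(n1 + n2, n_nodes)
  p <- exp(la)
  p <- p / rowSums(p)
  rownames(p) <- c(paste0("A_p", seq_len(n1)), paste0("B_p", seq_len(n2)))
  colnames(p) <- paste0("C", seq_len(n_nodes))
  structure(p, class = "abundance_table",
            groups = stats::setNames(rep(c("A", "B"), c(n1, n2)), rownames(p)))
}
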