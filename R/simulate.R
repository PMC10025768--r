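#' Clustered ZINB simulation of source/target dataset pairs
#'
#' Generates a labeled reference ("source") dataset and an unlabeled query
#' ("target") dataset from per-cluster ZINB gene-expression profiles, with a
#' configurable overlap between the two label spaces and a gene-wise
#' multiplicative batch shift on the target. Every cluster owns a block of
#' marker genes whose mean is elevated over a shared baseline, which gives the
#' simulation a separability knob.
#'
#' @name simulate
NULL

#' Deterministic seed fan-out
#'
#' Each pipeline stage draws from its own derived seed so that stages can be
#' reproduced independently; every derived seed stays below 2^31.
#'
#' @param seed integer master seed.
#' @param k integer stage index.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Build a simulation configuration
#'
#' @param n_source_cells,n_target_cells positive cell counts.
#' @param n_genes number of genes.
#' @param cluster_names character vector of all cluster (cell-type) names.
#' @param source_clusters,target_clusters subsets of `cluster_names` present
#'   in each dataset; their relationship defines the closed / partial / open /
#'   open-partial setting.
#' @param base_mean baseline NB mean per gene.
#' @param marker_fold fold-change of a cluster's marker block over baseline.
#' @param n_marker_genes marker genes per cluster (consecutive disjoint
#'   blocks).
#' @param dispersion per-gene NB dispersion (scalar or length `n_genes`).
#' @param dropout zero-inflation probability (scalar or per gene).
#' @param batch_shift_scale standard deviation of the gene-wise log-normal
#'   batch factor applied to target cluster means; 0 disables the shift.
#' @param source_proportions,target_proportions cluster sampling proportions
#'   (default uniform over the respective cluster sets); must sum to 1.
#' @param seed integer seed controlling every random draw.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_source_cells = 600L,
                              n_target_cells = 400L,
                              n_genes = 200L,
                              cluster_names = c("A", "B", "C"),
                              source_clusters = cluster_names,
                              target_clusters = cluster_names,
                              base_mean = 2,
                              marker_fold = 5,
                              n_marker_genes = 20L,
                              dispersion = 2,
                              dropout = 0.1,
                              batch_shift_scale = 0.3,
                              source_proportions = NULL,
                              target_proportions = NULL,
                              seed = 1L) {
  stopifnot(n_source_cells >= 1, n_target_cells >= 1, n_genes >= 1)
  if (!all(source_clusters %in% cluster_names) ||
      !all(target_clusters %in% cluster_names))
    stop("source/target clusters must be subsets of `cluster_names`")
  if (length(source_clusters) == 0L || length(target_clusters) == 0L)
    stop("source and target cluster sets must be non-empty")
  if (base_mean <= 0 || marker_fold <= 0 || any(dispersion <= 0))
    stop("means and dispersions must be strictly positive")
  if (any(dropout < 0 | dropout > 1)) stop("`dropout` must lie in [0, 1]")
  if (batch_shift_scale < 0) stop("`batch_shift_scale` must be non-negative")
  prop <- function(p, set, what) {
    if (is.null(p)) p <- rep(1 / length(set), length(set))
    if (length(p) != length(set)) stop(sprintf("%s length mismatch", what))
    if (abs(sum(p) - 1) > 1e-9) stop(sprintf("%s must sum to 1", what))
    stats::setNames(p, set)
  }
  cfg <- list(
    n_source_cells = as.integer(n_source_cells),
    n_target_cells = as.integer(n_target_cells),
    n_genes = as.integer(n_genes),
    cluster_names = cluster_names,
    source_clusters = source_clusters,
    target_clusters = target_clusters,
    base_mean = base_mean, marker_fold = marker_fold,
    n_marker_genes = as.integer(n_marker_genes),
    dispersion = rep_len(dispersion, n_genes),
    dropout = dropout,
    batch_shift_scale = batch_shift_scale,
    source_proportions = prop(source_proportions, source_clusters, "source_proportions"),
    target_proportions = prop(target_proportions, target_clusters, "target_proportions"),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Per-cluster mean profiles: baseline everywhere, an elevated block of marker
# genes per cluster (blocks assigned in cluster_names order, wrapping if the
# gene panel is short).
cluster_profiles <- function(cfg) {
  K <- length(cfg$cluster_names)
  prof <- matrix(cfg$base_mean, K, cfg$n_genes,
                 dimnames = list(cfg$cluster_names, NULL))
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * cfg$n_marker_genes + seq_len(cfg$n_marker_genes) - 1L) %%
      cfg$n_genes + 1L
    prof[k, idx] <- cfg$base_mean * cfg$marker_fold
  }
  prof
}

#' Classify a source/target label-set relationship
#'
#' Computes the shared/private label sets together with three imbalance
#' indices: `openness` (fraction of target types absent from the source),
#' `partialness` (fraction of source types absent from the target) and
#' `privateness` (fraction of all types private to either side). The index
#' definitions are this package's own simple set-arithmetic conventions.
#'
#' @param source_set,target_set non-empty character vectors of cell-type
#'   names.
#' @return object of class `setting_descriptor` with fields `setting`
#'   (closed/partial/open/open_partial), `shared`, `source_private`,
#'   `target_private`, `openness`, `partialness`, `privateness`.
#' @export
setting_indices <- function(source_set, target_set) {
  source_set <- unique(source_set); target_set <- unique(target_set)
  if (length(source_set) == 0L || length(target_set) == 0L)
    stop("both label sets must be non-empty")
  shared <- intersect(source_set, target_set)
  s_priv <- setdiff(source_set, target_set)
  t_priv <- setdiff(target_set, source_set)
  setting <- if (length(s_priv) == 0L && length(t_priv) == 0L) "closed"
  else if (length(t_priv) == 0L) "partial"
  else if (length(s_priv) == 0L) "open"
  else "open_partial"
  structure(list(
    setting = setting, shared = shared,
    source_private = s_priv, target_private = t_priv,
    openness = length(t_priv) / length(target_set),
    partialness = length(s_priv) / length(source_set),
    privateness = (length(s_priv) + length(t_priv)) /
      length(union(source_set, target_set))),
    class = "setting_descriptor")
}

#' Simulate a source/target dataset pair
#'
#' Cells are assigned to clusters by a seeded multinomial draw over the
#' configured proportions, gene means come from the cluster profile (target
#' means additionally multiplied by seeded log-normal batch factors), and
#' counts are drawn from the ZINB model.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `source`, `target` (class `labeled_dataset`:
#'   `counts`, `labels`, `gene_names`, `cell_ids`, `label_set`, `role`) and
#'   `descriptor` (a `setting_descriptor`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  desc <- setting_indices(cfg$source_clusters, cfg$target_clusters)
  if (length(desc$shared) == 0L)
    warning("source and target share no cell types; 'known' annotation is vacuous")
  prof <- cluster_profiles(cfg)
  gene_names <- sprintf("g%04d", seq_len(cfg$n_genes))

  draw <- function(n, clusters, props, means, role, seed_cells, seed_counts) {
    set.seed(seed_cells)
    labels <- sample(clusters, n, replace = TRUE, prob = props)
    mu <- means[labels, , drop = FALSE]
    counts <- zinb_sample(mu, matrix(cfg$dispersion, n, cfg$n_genes, byrow = TRUE),
                          cfg$dropout, shape = c(n, cfg$n_genes),
                          seed = seed_counts)
    structure(list(
      counts = counts, labels = labels, gene_names = gene_names,
      cell_ids = sprintf("%s_cell%05d", role, seq_len(n)),
      label_set = clusters, role = role),
      class = "labeled_dataset")
  }

  set.seed(derive_seed(cfg$seed, 3L))
  shift <- exp(stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_scale))
  target_prof <- sweep(prof, 2L, shift, "*")

  src <- draw(cfg$n_source_cells, cfg$source_clusters, cfg$source_proportions,
              prof, "source", derive_seed(cfg$seed, 1L), derive_seed(cfg$seed, 2L))
  tgt <- draw(cfg$n_target_cells, cfg$target_clusters, cfg$target_proportions,
              target_prof, "target", derive_seed(cfg$seed, 4L), derive_seed(cfg$seed, 5L))
  list(source = src, target = tgt, descriptor = desc)
}

#' Write a simulated dataset to disk
#'
#' Emits the conventional MatrixMarket trio (`matrix.mtx` stored genes x
#' cells, `genes.tsv`, `barcodes.tsv`) plus `labels.tsv` and a
#' `manifest.json` recording orientation and, when given, the setting
#' descriptor.
#'
#' @param ds a `labeled_dataset`.
#' @param dir output directory (created if absent).
#' @param descriptor optional `setting_descriptor` stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, descriptor = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)  # genes x cells, 10x style
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_names, file.path(dir, "genes.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(ds$labels)) writeLines(ds$labels, file.path(dir, "labels.tsv"))
  manifest <- list(orientation = "genes_x_cells", role = ds$role,
                   label_set = as.list(ds$label_set))
  if (!is.null(descriptor)) manifest$descriptor <- unclass(descriptor)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
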