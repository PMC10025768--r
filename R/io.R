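#' Reading, gene alignment and network-input preprocessing
#'
#' Cells are rows everywhere inside the package. Raw counts are retained
#' untouched by preprocessing because the reconstruction likelihood is
#' evaluated on counts, never on the transformed network input.
#'
#' @name io_preprocess
NULL

new_expression_matrix <- function(counts, gene_names, cell_ids,
                                  modality = c("rna", "atac_binary", "generic"),
                                  labels = NULL) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("expression counts must be non-negative")
  if (modality == "atac_binary" && !all(counts %in% c(0, 1)))
    stop("atac_binary matrices must contain only 0/1 entries")
  if (length(gene_names) != ncol(counts)) stop("gene_names length != ncol(counts)")
  if (length(cell_ids) != nrow(counts)) stop("cell_ids length != nrow(counts)")
  structure(list(counts = counts, gene_names = as.character(gene_names),
                 cell_ids = as.character(cell_ids), modality = modality,
                 labels = labels),
            class = "expression_matrix")
}

#' Read a count matrix from disk
#'
#' @param path for `mtx`, a directory holding `matrix.mtx` with `genes.tsv`
#'   and `barcodes.tsv` sidecars (optionally `labels.tsv` and a
#'   `manifest.json` giving the orientation; genes x cells is assumed
#'   otherwise, as written by 10x-style tools and [write_dataset()]). For
#'   `csv`, a dense cells x genes table with a header of gene names and an
#'   optional leading cell-id column. For `h5ad`, an AnnData HDF5 file;
#'   conversion is delegated to the host `python` interpreter's `anndata`
#'   (the matrix is exported to a temporary MTX trio and read back).
#' @param format one of `"mtx"`, `"csv"`, `"h5ad"`.
#' @param modality `"rna"`, `"atac_binary"` or `"generic"`.
#' @return an `expression_matrix` (cells x genes).
#' @export
read_counts <- function(path, format = c("mtx", "csv", "h5ad"),
                        modality = "rna") {
  format <- match.arg(format)
  switch(format,
         mtx = .read_mtx(path, modality),
         csv = .read_csv(path, modality),
         h5ad = .read_h5ad(path, modality))
}

.read_mtx <- function(dir, modality) {
  mtx <- file.path(dir, "matrix.mtx")
  genes_f <- file.path(dir, "genes.tsv")
  bc_f <- file.path(dir, "barcodes.tsv")
  if (!file.exists(mtx)) stop(sprintf("no matrix.mtx under '%s'", dir))
  if (!file.exists(genes_f) || !file.exists(bc_f))
    stop(sprintf("MTX sidecars genes.tsv/barcodes.tsv missing under '%s'", dir))
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.delim(genes_f, header = FALSE)[[1L]]
  cells <- utils::read.delim(bc_f, header = FALSE)[[1L]]
  orientation <- "genes_x_cells"
  mani_f <- file.path(dir, "manifest.json")
  if (file.exists(mani_f)) {
    mani <- jsonlite::read_json(mani_f)
    if (!is.null(mani$orientation)) orientation <- mani$orientation
  }
  if (orientation == "genes_x_cells") m <- t(m)
  labels <- NULL
  lab_f <- file.path(dir, "labels.tsv")
  if (file.exists(lab_f)) labels <- utils::read.delim(lab_f, header = FALSE)[[1L]]
  new_expression_matrix(m, genes, cells, modality, labels = labels)
}

.read_csv <- function(path, modality) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) >= 1L && !is.numeric(df[[1L]])) {
    cells <- as.character(df[[1L]]); df <- df[, -1L, drop = FALSE]
  } else {
    cells <- sprintf("cell%05d", seq_len(nrow(df)))
  }
  new_expression_matrix(as.matrix(df), colnames(df), cells, modality)
}

.read_h5ad <- function(path, modality) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  py <- Sys.which("python")
  if (py == "") stop("reading h5ad requires a `python` interpreter with anndata on PATH")
  tmp <- tempfile("h5ad_export_")
  dir.create(tmp)
  script <- sprintf(paste0(
    "import anndata, scipy.io, scipy.sparse, numpy as np, json, os\n",
    "ad = anndata.read_h5ad(%s)\n",
    "X = scipy.sparse.csr_matrix(ad.X)\n",
    "d = %s\n",
    "scipy.io.mmwrite(os.path.join(d, 'matrix.mtx'), X.T)\n",
    "open(os.path.join(d, 'genes.tsv'), 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')\n",
    "open(os.path.join(d, 'barcodes.tsv'), 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')\n",
    "lab = None\n",
    "for key in ('cell_type', 'labels', 'celltype'):\n",
    "    if key in ad.obs.columns:\n",
    "        open(os.path.join(d, 'labels.tsv'), 'w').write('\\n'.join(map(str, ad.obs[key])) + '\\n')\n",
    "        break\n",
    "json.dump({'orientation': 'genes_x_cells'}, open(os.path.join(d, 'manifest.json'), 'w'))\n"),
    deparse(path), deparse(tmp))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    stop("h5ad conversion failed: ", paste(status, collapse = "\n"))
  .read_mtx(tmp, modality)
}

#' Align a matrix's genes to a model's gene list
#'
#' @param model_genes non-empty character vector (column order to enforce).
#' @param target an `expression_matrix`.
#' @param policy `"strict"` errors on genes absent from the target;
#'   `"pad_zero"` fills them with zero counts and warns with the gene names.
#' @return an `expression_matrix` whose columns are exactly `model_genes`.
#' @export
align_genes <- function(model_genes, target, policy = c("strict", "pad_zero")) {
  policy <- match.arg(policy)
  if (length(model_genes) == 0L) stop("`model_genes` must be non-empty")
  stopifnot(inherits(target, "expression_matrix"))
  missing <- setdiff(model_genes, target$gene_names)
  if (length(missing) > 0L) {
    if (policy == "strict")
      stop(sprintf("target is missing %d model gene(s): %s", length(missing),
                   paste(missing, collapse = ", ")))
    warning(sprintf("padding %d missing gene(s) with zeros: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  out <- matrix(0, nrow(target$counts), length(model_genes))
  present <- intersect(model_genes, target$gene_names)
  out[, match(present, model_genes)] <-
    target$counts[, match(present, target$gene_names), drop = FALSE]
  new_expression_matrix(out, model_genes, target$cell_ids, target$modality,
                        labels = target$labels)
}

#' Preprocess counts into the network input
#'
#' RNA recipe: per-cell size factor = library size / median library size
#' (all-zero cells get size factor 1, with a warning); network input is the
#' per-gene z-scored `log1p` of size-factor-normalized counts, capped at
#' |10|. The per-gene location/scale (`scaling_stats`) are recorded at
#' source-model time and must be passed back in for target data so that both
#' datasets live on the source scale. Binary ATAC matrices pass through
#' unchanged with unit size factors.
#'
#' @param em an `expression_matrix`.
#' @param stats optional `scaling_stats` (list with `center`, `scale`) from
#'   the source run; when `NULL` they are computed from `em`.
#' @return list of class `preprocessed_data`: `x_input`, `raw_counts`,
#'   `size_factors`, `scaling_stats`, `gene_names`, `cell_ids`, `modality`.
#' @export
preprocess <- function(em, stats = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  raw <- em$counts
  if (em$modality == "atac_binary") {
    out <- list(x_input = raw, raw_counts = raw,
                size_factors = rep(1, nrow(raw)),
                scaling_stats = list(center = rep(0, ncol(raw)),
                                     scale = rep(1, ncol(raw))),
                gene_names = em$gene_names, cell_ids = em$cell_ids,
                modality = em$modality)
    class(out) <- "preprocessed_data"
    return(out)
  }
  lib <- rowSums(raw)
  zero_cells <- lib == 0
  if (any(zero_cells))
    warning(sprintf("%d all-zero cell(s); size factor set to 1", sum(zero_cells)))
  med <- stats::median(lib[!zero_cells])
  if (!is.finite(med) || med == 0) med <- 1
  sf <- lib / med
  sf[zero_cells] <- 1
  xl <- log1p(raw / sf)
  if (is.null(stats)) {
    center <- colMeans(xl)
    scale <- apply(xl, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-8] <- 1
    stats <- list(center = center, scale = scale)
  }
  x <- sweep(sweep(xl, 2L, stats$center, "-"), 2L, stats$scale, "/")
  x <- pmin(pmax(x, -10), 10)
  out <- list(x_input = x, raw_counts = raw, size_factors = sf,
              scaling_stats = stats, gene_names = em$gene_names,
              cell_ids = em$cell_ids, modality = em$modality)
  class(out) <- "preprocessed_data"
  out
}
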