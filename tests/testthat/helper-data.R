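# Shared fixtures: everything is generated in code at test time.

as_em <- function(ds, modality = "rna") {
  new_expression_matrix(ds$counts, ds$gene_names, ds$cell_ids, modality,
                        labels = ds$labels)
}

# internal constructor is not exported
new_expression_matrix <- scOpenAnno:::new_expression_matrix
e_score_matrix <- scOpenAnno:::e_score_matrix

# Tiny well-separated 3-cluster pair for fast unit tests.
tiny_pair <- function(seed = 1, n_source = 240, n_target = 160, n_genes = 60,
                      source_clusters = c("A", "B", "C"),
                      target_clusters = c("A", "B", "C"), ...) {
  cfg <- simulation_config(
    n_source_cells = n_source, n_target_cells = n_target, n_genes = n_genes,
    cluster_names = union(source_clusters, target_clusters),
    source_clusters = source_clusters, target_clusters = target_clusters,
    n_marker_genes = 8L, seed = seed, ...)
  simulate_pair(cfg)
}

tiny_spec <- function(p, d = 6L, hidden = c(16L), likelihood = "zinb")
  network_spec(p, latent_dim = d, encoder_hidden = hidden,
               likelihood = likelihood)

tiny_model <- function(pair, seed = 1, epochs = 20, warmup = 3,
                       batch_size = 40, ...) {
  pre <- preprocess(as_em(pair$source))
  train_source(pre, pair$source$labels, tiny_spec(ncol(pre$x_input)),
               train_config(warmup_epochs = warmup, epochs = epochs,
                            batch_size = batch_size, seed = seed, ...))
}

target_preprocessed <- function(model, pair) {
  em <- as_em(pair$target)
  em$labels <- NULL
  preprocess(align_genes(model$gene_names, em, "pad_zero"),
             stats = model$scaling_stats)
}

## Benchmark conditions used by the acceptance suite: five shared clusters,
## marker-separated novel cluster at a third of the target, denoising
## corruption during source training (documented in the methods vignette).
BENCH <- list(
  clusters = c("A", "B", "C", "D", "E"),
  all_clusters = c("A", "B", "C", "D", "E", "F"),
  n_genes = 150L, n_markers = 15L, base_mean = 2, marker_fold = 5,
  n_source = 400L)

bench_sim_config <- function(setting, seed, n_target = 800L) {
  A5 <- BENCH$clusters
  cl <- switch(setting,
    closed = list(t = A5, p = NULL),
    partial = list(t = c("A", "B", "C", "D"), p = NULL),
    open = list(t = c(A5, "F"), p = c(rep(2 / 15, 5), 1 / 3)),
    open_partial = list(t = c("B", "C", "D", "E", "F"),
                        p = c(rep(1 / 6, 4), 1 / 3)))
  simulation_config(
    n_source_cells = BENCH$n_source, n_target_cells = n_target,
    n_genes = BENCH$n_genes, cluster_names = BENCH$all_clusters,
    source_clusters = A5, target_clusters = cl$t,
    n_marker_genes = BENCH$n_markers, base_mean = BENCH$base_mean,
    marker_fold = BENCH$marker_fold, target_proportions = cl$p, seed = seed)
}

bench_model <- function(pair, seed) {
  pre <- preprocess(as_em(pair$source))
  train_source(pre, pair$source$labels,
               network_spec(BENCH$n_genes, latent_dim = 6L,
                            encoder_hidden = c(24L)),
               train_config(warmup_epochs = 3, epochs = 40, batch_size = 50,
                            corruption_sd = 0.5, seed = seed))
}

# Train on source, score target, return model + banks + truth labels.
bench_run <- function(setting, seed, n_target = 800L) {
  pair <- simulate_pair(bench_sim_config(setting, seed, n_target))
  model <- bench_model(pair, seed)
  pre_t <- target_preprocessed(model, pair)
  banks <- init_banks(model, pre_t)
  list(model = model, pre_t = pre_t, banks = banks,
       truth = pair$target$labels, pair = pair)
}
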