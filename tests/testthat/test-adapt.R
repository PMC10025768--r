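test_that("memory banks equal a direct forward pass and e-scores recompute", {
  pair <- tiny_pair(seed = 11, n_source = 120, n_target = 60)
  model <- tiny_model(pair, seed = 11, epochs = 8)
  pre_t <- target_preprocessed(model, pair)
  banks <- init_banks(model, pre_t)
  fw <- model_forward(model, pre_t)
  expect_equal(banks$R, fw$Z, tolerance = 1e-12)
  expect_equal(banks$S, fw$p, tolerance = 1e-12)
  # batch-by-batch forward concatenation gives the same banks
  half <- 1:30
  fw1 <- scOpenAnno:::net_forward(model$net, pre_t$x_input[half, ], pre_t$size_factors[half])
  expect_equal(banks$R[half, ], fw1$Z, tolerance = 1e-10)
  # e-scores are exactly the row-wise score of the soft-label banks
  es <- e_score_matrix(banks$S, banks$S1, banks$S2)$e_score
  expect_equal(banks$e_scores, es, tolerance = 1e-12)
  # identical cells produce identical bank rows
  pre2 <- pre_t
  pre2$x_input[2, ] <- pre2$x_input[1, ]
  pre2$size_factors[2] <- pre2$size_factors[1]
  b2 <- init_banks(model, pre2)
  expect_equal(b2$R[1, ], b2$R[2, ], tolerance = 1e-12)
})

test_that("adaptation freezes all classifier heads and touches only the target", {
  pair <- tiny_pair(seed = 12, n_source = 150, n_target = 80)
  model <- tiny_model(pair, seed = 12, epochs = 10)
  pre_t <- target_preprocessed(model, pair)
  res <- suppressWarnings(
    adapt(model, pre_t, adapt_config(epochs = 3, batch_size = 40, n_boot = 50,
                                     seed = 12)))
  expect_identical(res$model$cls, model$cls)
  expect_identical(res$model$aux1, model$aux1)
  expect_identical(res$model$aux2, model$aux2)
  # encoder must have moved
  expect_gt(sum((res$model$net$enc[[1]]$W - model$net$enc[[1]]$W)^2), 0)
})

test_that("adapt demands gene-aligned input", {
  pair <- tiny_pair(seed = 13, n_source = 100, n_target = 30)
  model <- tiny_model(pair, seed = 13, epochs = 5)
  em <- as_em(pair$target)
  em$gene_names[1] <- "other_gene"
  pre_bad <- preprocess(em, stats = model$scaling_stats)
  expect_error(adapt(model, pre_bad), "align_genes")
})

test_that("annotate is deterministic and labels follow the partition rule", {
  pair <- tiny_pair(seed = 14, n_source = 150, n_target = 80,
                    target_clusters = c("A", "B", "C", "D"),
                    source_clusters = c("A", "B", "C"))
  model <- tiny_model(pair, seed = 14, epochs = 12)
  pre_t <- target_preprocessed(model, pair)
  r1 <- suppressWarnings(annotate(model, pre_t, adapt_config(n_boot = 50, seed = 3)))
  r2 <- suppressWarnings(annotate(model, pre_t, adapt_config(n_boot = 50, seed = 3)))
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$e_scores, r2$e_scores, tolerance = 1e-12)
  expect_true(all(r1$labels[r1$partition$unknown_idx] == "unknown"))
  known <- r1$partition$known_idx
  expect_identical(r1$labels[known],
                   model$class_names[max.col(r1$probs[known, , drop = FALSE],
                                             ties.method = "first")])
})

test_that("source-freeness: adaptation consumes only the artifact and target data", {
  pair <- tiny_pair(seed = 15, n_source = 120, n_target = 60)
  model <- tiny_model(pair, seed = 15, epochs = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  reloaded <- load_model(path)    # crosses the privacy boundary
  pre_t <- target_preprocessed(reloaded, pair)
  res <- suppressWarnings(
    adapt(reloaded, pre_t, adapt_config(epochs = 2, batch_size = 30,
                                        n_boot = 50, seed = 15)))
  expect_s3_class(res, "annotation_result")
  # the artifact itself carries no target or source expression rows
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  expect_false(grepl("source_cell", txt, fixed = TRUE))
  expect_false(grepl("target_cell", txt, fixed = TRUE))
})

test_that("bank consistency: stored e-scores match recomputation after adaptation", {
  pair <- tiny_pair(seed = 16, n_source = 120, n_target = 60)
  model <- tiny_model(pair, seed = 16, epochs = 8)
  pre_t <- target_preprocessed(model, pair)
  res <- suppressWarnings(
    adapt(model, pre_t, adapt_config(epochs = 2, batch_size = 30, n_boot = 50,
                                     seed = 16)))
  banks <- init_banks(res$model, pre_t)
  es <- e_score_matrix(banks$S, banks$S1, banks$S2)$e_score
  expect_equal(res$e_scores, es, tolerance = 1e-6)
})

test_that("closed-setting adaptation does not hurt accuracy (smoke)", {
  pair <- tiny_pair(seed = 17, n_source = 240, n_target = 120)
  model <- tiny_model(pair, seed = 17, epochs = 20)
  pre_t <- target_preprocessed(model, pair)
  r0 <- suppressWarnings(annotate(model, pre_t, adapt_config(n_boot = 50, seed = 17)))
  r1 <- suppressWarnings(
    adapt(model, pre_t, adapt_config(epochs = 4, batch_size = 60, n_boot = 50,
                                     seed = 17)))
  acc0 <- mean(r0$labels == pair$target$labels)
  acc1 <- mean(r1$labels == pair$target$labels)
  expect_gte(acc1, acc0 - 0.05)
})
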