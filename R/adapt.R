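#' Source-free model adaptation to target data
#'
#' Fine-tunes the encoder (and, by default, the decoder through the
#' reconstruction loss) on the unlabeled target data alone. Classifier heads
#' stay frozen so that the class semantics learned from the reference are
#' preserved. Memory banks cache every target cell's current embedding and
#' soft labels without gradient flow; they drive the global neighbor search
#' and the affinity loss. Novelty is tested once on the initial E-scores; the
#' mixup threshold delta is refreshed every epoch and the known/unknown
#' partition every iteration (for the cells whose bank rows were updated).
#'
#' @name adaptation
NULL

#' Adaptation configuration
#'
#' @param M neighborhood size (self included).
#' @param alpha affinity down-weight for unidirectional and extensional
#'   neighbors; `alpha2`/`alpha3` override the two tiers separately.
#' @param epochs,batch_size,lr optimizer settings (Adam).
#' @param freeze_decoder when `TRUE` only the encoder is updated.
#' @param alpha_dip,bc_threshold,n_boot novelty-detection settings.
#' @param mixup_pairs `"auto"`, `"all"` or an integer ([mixup_threshold()]).
#' @param seed integer seed.
#' @return list of class `adapt_config`.
#' @export
adapt_config <- function(M = 5L, alpha = 0.1, alpha2 = alpha, alpha3 = alpha,
                         epochs = 30L, batch_size = 256L, lr = 1e-4,
                         freeze_decoder = FALSE, alpha_dip = 0.05,
                         bc_threshold = 5 / 9, n_boot = 200L,
                         mixup_pairs = "auto", seed = 1L) {
  if (M < 1L) stop("`M` must be >= 1")
  if (alpha2 < 0 || alpha3 < 0) stop("affinity weights must be non-negative")
  structure(list(M = as.integer(M), alpha2 = alpha2, alpha3 = alpha3,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, freeze_decoder = freeze_decoder,
                 alpha_dip = alpha_dip, bc_threshold = bc_threshold,
                 n_boot = as.integer(n_boot), mixup_pairs = mixup_pairs,
                 seed = as.integer(seed)),
            class = "adapt_config")
}

#' Initialize the memory banks
#'
#' One full forward pass through the model fills the representation bank `R`,
#' the soft-label banks `S`, `S1`, `S2` and the per-cell E-scores.
#'
#' @param model a `source_model`.
#' @param target `preprocessed_data` aligned to the model genes.
#' @return list of class `memory_banks`.
#' @export
init_banks <- function(model, target) {
  fw <- model_forward(model, target)
  es <- e_score_matrix(fw$p, fw$p1, fw$p2)
  structure(list(R = fw$Z, S = fw$p, S1 = fw$p1, S2 = fw$p2,
                 e_scores = es$e_score),
            class = "memory_banks")
}

#' Adapt a source model to target data and annotate it
#'
#' @param model a `source_model` (the only reference-side input).
#' @param target `preprocessed_data` for the target cells, aligned to
#'   `model$gene_names`.
#' @param config an [adapt_config()].
#' @return an `annotation_result`: per-cell `labels` (class name or
#'   `"unknown"`), `probs`, `e_scores`, the final `partition`, the
#'   `bimodality` result, the `delta_trajectory` and a per-epoch `log`. The
#'   adapted model is returned as `$model`.
#' @export
adapt <- function(model, target, config = adapt_config()) {
  stopifnot(inherits(model, "source_model"),
            inherits(target, "preprocessed_data"))
  if (!identical(target$gene_names, model$gene_names))
    stop("target is not aligned to the model genes; run align_genes() first")
  n <- nrow(target$x_input)
  banks <- init_banks(model, target)
  bim <- detect_novelty(banks$e_scores, alpha_dip = config$alpha_dip,
                        bc_threshold = config$bc_threshold,
                        n_boot = config$n_boot,
                        seed = derive_seed(config$seed, 21L))
  delta <- NA_real_
  part <- partition_cells(banks$e_scores, delta, FALSE)

  trainable <- if (config$freeze_decoder) list(enc = model$net$enc)
  else list(enc = model$net$enc, dec = model$net$dec, heads = model$net$heads)
  adam <- adam_init(trainable)
  log <- vector("list", config$epochs)
  delta_traj <- numeric(0)
  set.seed(derive_seed(config$seed, 22L))

  for (epoch in seq_len(config$epochs)) {
    if (bim$novel_detected) {
      delta <- mixup_threshold(banks$R, model, n_pairs = config$mixup_pairs,
                               seed = derive_seed(config$seed, 23L + epoch))
      delta_traj <- c(delta_traj, delta)
      part <- partition_cells(banks$e_scores, delta, TRUE)
    }
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_rec <- ep_nbh <- 0
    for (b in batches) {
      fw <- net_forward(model$net, target$x_input[b, , drop = FALSE],
                        target$size_factors[b])
      pr <- classifier_probs(model, fw$Z)
      # bank update (no gradient flows through the banks)
      banks$R[b, ] <- fw$Z
      banks$S[b, ] <- pr$p
      banks$S1[b, ] <- pr$p1
      banks$S2[b, ] <- pr$p2
      banks$e_scores[b] <- e_score_matrix(pr$p, pr$p1, pr$p2)$e_score
      if (bim$novel_detected)
        part <- partition_cells(banks$e_scores, delta, TRUE)

      raw_b <- target$raw_counts[b, , drop = FALSE]
      rec <- recon_nll(model$net, raw_b, fw$params)
      ep_rec <- ep_rec + rec * length(b)
      d_par <- recon_nll_grad(model$net, raw_b, fw$params)
      back <- net_backward_decoder(model$net, fw, d_par)
      dZ <- back$dZ

      VM <- cosine_knn(banks$R, M = min(config$M, n))
      nbh <- split_neighbors(VM)
      af <- suppressWarnings(
        affinity_loss(b, pr$p, nbh, banks$S, part,
                      alpha2 = config$alpha2, alpha3 = config$alpha3,
                      grad = TRUE))
      ep_nbh <- ep_nbh + af$loss * length(b)
      dZ <- dZ + tcrossprod(af$d_logits, model$cls$W)  # cls weights frozen

      enc_grad <- net_backward_encoder(model$net, fw, dZ)
      grads <- if (config$freeze_decoder) list(enc = enc_grad)
      else list(enc = enc_grad, dec = back$dec, heads = back$heads)
      st <- adam_step(trainable, grads, adam, lr = config$lr)
      trainable <- st$params; adam <- st$state
      model$net$enc <- trainable$enc
      if (!config$freeze_decoder) {
        model$net$dec <- trainable$dec
        model$net$heads <- trainable$heads
      }
    }
    log[[epoch]] <- list(epoch = epoch, recon_nll = ep_rec / n,
                         affinity_loss = ep_nbh / n,
                         delta = if (bim$novel_detected) delta else NA_real_,
                         n_known = length(part$known_idx),
                         n_unknown = length(part$unknown_idx))
  }

  # final refresh: full forward pass, fresh delta and partition
  banks <- init_banks(model, target)
  if (bim$novel_detected) {
    delta <- mixup_threshold(banks$R, model, n_pairs = config$mixup_pairs,
                             seed = derive_seed(config$seed, 99L))
    delta_traj <- c(delta_traj, delta)
    part <- partition_cells(banks$e_scores, delta, TRUE)
    if (length(part$unknown_idx) == 0L) {
      warning("novelty was detected but no cell falls below delta; proceeding as closed")
      part <- partition_cells(banks$e_scores, NA_real_, FALSE)
    }
  } else {
    part <- partition_cells(banks$e_scores, NA_real_, FALSE)
  }
  res <- .make_annotation(model, target, banks, part, bim)
  res$delta_trajectory <- delta_traj
  res$log <- log
  res$model <- model
  res
}

.make_annotation <- function(model, target, banks, part, bim) {
  labels <- model$class_names[max.col(banks$S, ties.method = "first")]
  labels[part$unknown_idx] <- "unknown"
  structure(list(labels = labels, probs = banks$S,
                 e_scores = banks$e_scores, partition = part,
                 bimodality = bim, cell_ids = target$cell_ids),
            class = "annotation_result")
}

#' Annotate target data without adaptation
#'
#' Inference-only pass: embeds the target, scores it, tests for novelty, sets
#' delta by manifold mixup when novelty is detected, and labels every cell
#' (argmax class for known cells, `"unknown"` otherwise). No weight is
#' updated.
#'
#' @inheritParams adapt
#' @param config an [adapt_config()] (only the novelty/mixup settings are
#'   used).
#' @return an `annotation_result`.
#' @export
annotate <- function(model, target, config = adapt_config()) {
  stopifnot(inherits(model, "source_model"))
  if (!identical(target$gene_names, model$gene_names))
    stop("target is not aligned to the model genes; run align_genes() first")
  banks <- init_banks(model, target)
  bim <- detect_novelty(banks$e_scores, alpha_dip = config$alpha_dip,
                        bc_threshold = config$bc_threshold,
                        n_boot = config$n_boot,
                        seed = derive_seed(config$seed, 21L))
  if (bim$novel_detected) {
    delta <- mixup_threshold(banks$R, model, n_pairs = config$mixup_pairs,
                             seed = derive_seed(config$seed, 23L))
    part <- partition_cells(banks$e_scores, delta, TRUE)
    if (length(part$unknown_idx) == 0L) {
      warning("novelty was detected but no cell falls below delta; proceeding as closed")
      part <- partition_cells(banks$e_scores, NA_real_, FALSE)
    }
  } else {
    part <- partition_cells(banks$e_scores, NA_real_, FALSE)
  }
  res <- .make_annotation(model, target, banks, part, bim)
  res$delta_trajectory <- if (bim$novel_detected) part$delta else numeric(0)
  res
}
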