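#' Source-model training
#'
#' Supervised training of the reference ("source") model: the autoencoder
#' reconstruction loss, the main classifier's label-smoothed cross-entropy,
#' and a co-training loss through two auxiliary classifiers whose weights are
#' never updated (their random initializations are kept distinct so the
#' ensemble stays diverse); the auxiliary loss back-propagates only into the
#' encoder. The packaged artifact carries weights and preprocessing metadata
#' only — no source cell is ever serialized.
#'
#' @name source_trainer
NULL

MODEL_SCHEMA_VERSION <- 1L

#' Label-smoothed cross-entropy
#'
#' Mean over cells of `-sum_k q'_k log p_k` with
#' `q' = (1 - eps) * onehot(y) + eps / K`. `eps = 0` gives the plain
#' cross-entropy.
#'
#' @param p N x K matrix of predicted probabilities (rows sum to 1).
#' @param y integer class indices in `1..K`.
#' @param K number of classes.
#' @param eps smoothing weight in `[0, 0.5)`.
#' @return non-negative scalar.
#' @export
smoothed_cross_entropy <- function(p, y, K, eps = 0) {
  p <- matrix(p, ncol = K)
  if (any(y < 1 | y > K)) stop("labels must lie in 1..K")
  if (any(abs(rowSums(p) - 1) > 1e-4)) stop("prediction rows must sum to 1")
  q <- matrix(eps / K, nrow(p), K)
  q[cbind(seq_len(nrow(p)), y)] <- q[cbind(seq_len(nrow(p)), y)] + (1 - eps)
  -base::mean(rowSums(q * log(pmax(p, 1e-12))))
}

#' Co-training loss of the two auxiliary classifiers
#'
#' Sum of the two heads' label-smoothed cross-entropies. In training the
#' gradient of this loss reaches only the encoder; the heads stay frozen.
#'
#' @param p1,p2 N x K probability matrices from the two auxiliary heads.
#' @inheritParams smoothed_cross_entropy
#' @return non-negative scalar.
#' @export
aux_co_training_loss <- function(p1, p2, y, K, eps = 0) {
  smoothed_cross_entropy(p1, y, K, eps) + smoothed_cross_entropy(p2, y, K, eps)
}

# d(loss)/d(logits) for the smoothed cross-entropy (mean over N rows).
.ce_logit_grad <- function(p, y, K, eps) {
  q <- matrix(eps / K, nrow(p), K)
  q[cbind(seq_len(nrow(p)), y)] <- q[cbind(seq_len(nrow(p)), y)] + (1 - eps)
  (p - q) / nrow(p)
}

#' Training configuration for the source model
#'
#' @param warmup_epochs likelihood-only epochs before the classifiers join.
#' @param epochs joint epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param label_smoothing smoothing weight `eps` in `[0, 0.5)`.
#' @param corruption_sd sd of Gaussian input corruption for the denoising
#'   objective (0 disables corruption).
#' @param seed integer seed.
#' @return list of class `train_config`.
#' @export
train_config <- function(warmup_epochs = 20L, epochs = 80L, batch_size = 256L,
                         lr = 1e-3, label_smoothing = 0.1, corruption_sd = 0,
                         seed = 1L) {
  if (label_smoothing < 0 || label_smoothing >= 0.5)
    stop("`label_smoothing` must lie in [0, 0.5)")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be positive")
  structure(list(warmup_epochs = as.integer(warmup_epochs),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, label_smoothing = label_smoothing,
                 corruption_sd = corruption_sd, seed = as.integer(seed)),
            class = "train_config")
}

# Forward all classifier heads from latent Z.
classifier_probs <- function(model, Z) {
  list(p = softmax(nn_affine(model$cls, Z)),
       p1 = softmax(nn_affine(model$aux1, Z)),
       p2 = softmax(nn_affine(model$aux2, Z)))
}

#' Train the source model
#'
#' Minimizes reconstruction NLL + classifier cross-entropy + auxiliary
#' co-training loss by mini-batch Adam, after `warmup_epochs` of
#' likelihood-only training. The two auxiliary heads keep their (distinct)
#' random initial weights throughout.
#'
#' @param pre `preprocessed_data` for the labeled reference cells.
#' @param labels character vector of per-cell type labels.
#' @param spec a [network_spec()]; defaults to the package architecture for
#'   `ncol` genes.
#' @param config a [train_config()].
#' @return object of class `source_model` carrying the autoencoder, the three
#'   classifier heads, `class_names`, `gene_names`, `scaling_stats` and the
#'   training log.
#' @export
train_source <- function(pre, labels, spec = NULL, config = train_config()) {
  stopifnot(inherits(pre, "preprocessed_data"))
  X <- pre$x_input; n <- nrow(X)
  if (length(labels) != n) stop("labels length != number of cells")
  class_names <- sort(unique(as.character(labels)))
  K <- length(class_names)
  if (K < 2L) stop("source data must contain at least two classes")
  y <- match(as.character(labels), class_names)
  if (is.null(spec))
    spec <- network_spec(ncol(X),
                         likelihood = if (pre$modality == "atac_binary") "bernoulli" else "zinb")
  net <- init_network(spec, seed = derive_seed(config$seed, 11L))
  set.seed(derive_seed(config$seed, 12L))
  cls <- nn_linear_init(spec$latent_dim, K)
  set.seed(derive_seed(config$seed, 13L))
  aux1 <- nn_linear_init(spec$latent_dim, K)
  set.seed(derive_seed(config$seed, 14L))
  aux2 <- nn_linear_init(spec$latent_dim, K)

  model <- structure(list(net = net, cls = cls, aux1 = aux1, aux2 = aux2,
                          class_names = class_names,
                          gene_names = pre$gene_names,
                          scaling_stats = pre$scaling_stats,
                          label_smoothing = config$label_smoothing,
                          likelihood = spec$likelihood,
                          schema_version = MODEL_SCHEMA_VERSION),
                     class = "source_model")

  trainable <- list(net = list(enc = net$enc, dec = net$dec, heads = net$heads),
                    cls = cls)
  adam <- adam_init(trainable)
  eps <- config$label_smoothing
  total_epochs <- config$warmup_epochs + config$epochs
  log <- vector("list", total_epochs)
  set.seed(derive_seed(config$seed, 15L))

  for (epoch in seq_len(total_epochs)) {
    joint <- epoch > config$warmup_epochs
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_rec <- ep_cls <- ep_aux <- 0
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      if (config$corruption_sd > 0) {
        # denoising corruption: i.i.d. noise plus a gene-wise offset shared
        # by the batch, so the encoder learns invariance both to counting
        # noise and to mild systematic gene-level (batch-like) shifts
        Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, config$corruption_sd),
                          nrow(Xb), ncol(Xb)) +
          rep(stats::rnorm(ncol(Xb), 0, config$corruption_sd), each = nrow(Xb))
      }
      fw <- net_forward(model$net, Xb, pre$size_factors[b])
      d_par <- recon_nll_grad(model$net, pre$raw_counts[b, , drop = FALSE], fw$params)
      ep_rec <- ep_rec + recon_nll(model$net, pre$raw_counts[b, , drop = FALSE],
                                   fw$params) * length(b)
      back <- net_backward_decoder(model$net, fw, d_par)
      dZ <- back$dZ
      cls_grad <- list(W = model$cls$W * 0, b = model$cls$b * 0)
      if (joint) {
        probs <- classifier_probs(model, fw$Z)
        yb <- y[b]
        ep_cls <- ep_cls + smoothed_cross_entropy(probs$p, yb, K, eps) * length(b)
        ep_aux <- ep_aux + aux_co_training_loss(probs$p1, probs$p2, yb, K, eps) * length(b)
        dL <- .ce_logit_grad(probs$p, yb, K, eps)
        cls_grad <- list(W = crossprod(fw$Z, dL), b = colSums(dL))
        dZ <- dZ + tcrossprod(dL, model$cls$W)
        # auxiliary heads: frozen weights, gradient into the encoder only
        dL1 <- .ce_logit_grad(probs$p1, yb, K, eps)
        dL2 <- .ce_logit_grad(probs$p2, yb, K, eps)
        dZ <- dZ + tcrossprod(dL1, model$aux1$W) + tcrossprod(dL2, model$aux2$W)
      }
      enc_grad <- net_backward_encoder(model$net, fw, dZ)
      grads <- list(net = list(enc = enc_grad, dec = back$dec, heads = back$heads),
                    cls = cls_grad)
      st <- adam_step(trainable, grads, adam, lr = config$lr)
      trainable <- st$params; adam <- st$state
      model$net$enc <- trainable$net$enc
      model$net$dec <- trainable$net$dec
      model$net$heads <- trainable$net$heads
      model$cls <- trainable$cls
    }
    log[[epoch]] <- list(epoch = epoch, phase = if (joint) "joint" else "warmup",
                         recon_nll = ep_rec / n,
                         cls_loss = if (joint) ep_cls / n else NA_real_,
                         aux_loss = if (joint) ep_aux / n else NA_real_,
                         total = (ep_rec + ep_cls + ep_aux) / n)
  }
  model$train_log <- log
  model
}

#' Predict with a source model (inference only)
#'
#' @param model a `source_model`.
#' @param pre `preprocessed_data` aligned to the model's genes.
#' @return list with `Z` (latent), `p`, `p1`, `p2` (probability matrices),
#'   `labels` (argmax class names) and `params` (reconstruction parameters).
#' @export
model_forward <- function(model, pre) {
  fw <- net_forward(model$net, pre$x_input, pre$size_factors)
  pr <- classifier_probs(model, fw$Z)
  list(Z = fw$Z, p = pr$p, p1 = pr$p1, p2 = pr$p2,
       labels = model$class_names[max.col(pr$p, ties.method = "first")],
       params = fw$params)
}

## ---- serialization ----------------------------------------------------

.layers_to_json <- function(layers)
  lapply(layers, function(l) list(W = as.vector(l$W), dim = dim(l$W), b = l$b))

.layers_from_json <- function(js)
  lapply(js, function(l) list(W = matrix(unlist(l$W), l$dim[[1]], l$dim[[2]]),
                              b = as.numeric(unlist(l$b))))

#' Save / load a source model artifact
#'
#' The artifact is a single JSON file holding the architecture, weights,
#' class names, gene list and scaling statistics — and nothing else, so its
#' size is independent of the number of reference cells and it can be shared
#' without exposing the reference data.
#'
#' @param model a `source_model`.
#' @param path file path for the artifact.
#' @return `path` invisibly; `load_model` returns the restored
#'   `source_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "source_model"))
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              spec = unclass(model$net$spec),
              enc = .layers_to_json(model$net$enc),
              dec = .layers_to_json(model$net$dec),
              heads = lapply(model$net$heads, function(l)
                list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
              cls = list(W = as.vector(model$cls$W), dim = dim(model$cls$W),
                         b = model$cls$b),
              aux1 = list(W = as.vector(model$aux1$W), dim = dim(model$aux1$W),
                          b = model$aux1$b),
              aux2 = list(W = as.vector(model$aux2$W), dim = dim(model$aux2$W),
                          b = model$aux2$b),
              class_names = model$class_names,
              gene_names = model$gene_names,
              scaling_stats = model$scaling_stats,
              label_smoothing = model$label_smoothing,
              likelihood = model$likelihood)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' not found", path))
  obj <- jsonlite::read_json(path)
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    stop(sprintf("model schema version mismatch: artifact has '%s', package expects %d",
                 obj$schema_version, MODEL_SCHEMA_VERSION))
  sp <- obj$spec
  spec <- network_spec(sp$input_dim[[1]], sp$latent_dim[[1]],
                       as.integer(unlist(sp$encoder_hidden)),
                       as.integer(unlist(sp$decoder_hidden)),
                       sp$activation[[1]], sp$likelihood[[1]])
  one <- function(l) list(W = matrix(unlist(l$W), l$dim[[1]], l$dim[[2]]),
                          b = as.numeric(unlist(l$b)))
  net <- list(spec = spec,
              enc = .layers_from_json(obj$enc),
              acts_e = c(rep("elu", length(spec$encoder_hidden)), "linear"),
              dec = .layers_from_json(obj$dec),
              acts_d = rep("elu", length(spec$decoder_hidden)),
              heads = lapply(obj$heads, one))
  structure(list(net = net, cls = one(obj$cls), aux1 = one(obj$aux1),
                 aux2 = one(obj$aux2),
                 class_names = as.character(unlist(obj$class_names)),
                 gene_names = as.character(unlist(obj$gene_names)),
                 scaling_stats = list(
                   center = as.numeric(unlist(obj$scaling_stats$center)),
                   scale = as.numeric(unlist(obj$scaling_stats$scale))),
                 label_smoothing = obj$label_smoothing,
                 likelihood = obj$likelihood,
                 schema_version = MODEL_SCHEMA_VERSION),
            class = "source_model")
}
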