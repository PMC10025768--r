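#' Denoising autoencoder network
#'
#' A small fully-connected autoencoder written directly in R matrix algebra:
#' encoder `h` maps the preprocessed input to a d-dimensional latent space,
#' a decoder trunk feeds three linear heads emitting the ZINB parameters
#' (mean via `size_factor * exp`, dispersion via softplus, dropout via
#' logistic) or a single Bernoulli head. Gradients are computed by hand in
#' reverse mode; the tests verify them against finite differences.
#'
#' @name network
NULL

#' Describe the network architecture
#'
#' @param input_dim number of genes `p`.
#' @param latent_dim latent dimension `d` (>= 2).
#' @param encoder_hidden,decoder_hidden integer vectors of hidden widths.
#' @param activation hidden activation (`"elu"`).
#' @param likelihood `"zinb"` or `"bernoulli"`.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(input_dim, latent_dim = 32L,
                         encoder_hidden = c(256L, 64L),
                         decoder_hidden = rev(encoder_hidden),
                         activation = "elu",
                         likelihood = c("zinb", "bernoulli")) {
  likelihood <- match.arg(likelihood)
  if (latent_dim < 2L) stop("`latent_dim` must be >= 2")
  if (any(c(encoder_hidden, decoder_hidden) < 1L)) stop("widths must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 activation = activation, likelihood = likelihood),
            class = "network_spec")
}

## ---- layer primitives -------------------------------------------------

nn_linear_init <- function(n_in, n_out, zero = FALSE) {
  W <- if (zero) matrix(0, n_in, n_out)
  else matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), n_in, n_out)
  list(W = W, b = rep(0, n_out))
}

nn_affine <- function(layer, X) X %*% layer$W + rep(layer$b, each = nrow(X))

.elu <- function(a) ifelse(a > 0, a, exp(pmin(a, 0)) - 1)
.elu_grad <- function(a) ifelse(a > 0, 1, exp(pmin(a, 0)))

# Stack of layers; act per layer ("elu" or "linear").
mlp_forward <- function(layers, acts, X) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    A <- nn_affine(layers[[i]], H)
    caches[[i]] <- list(X = H, A = A)
    H <- if (acts[i] == "elu") .elu(A) else A
  }
  list(out = H, caches = caches)
}

# dOut: gradient w.r.t. the stack output. Returns per-layer grads + dX.
mlp_backward <- function(layers, acts, caches, dOut) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    dA <- if (acts[i] == "elu") d * .elu_grad(caches[[i]]$A) else d
    grads[[i]] <- list(W = crossprod(caches[[i]]$X, dA), b = colSums(dA))
    d <- tcrossprod(dA, layers[[i]]$W)
  }
  list(grads = grads, dX = d)
}

softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

## ---- network assembly -------------------------------------------------

# The trainable state is a nested list of layers; the classifier heads are
# separate entries so that they can be frozen independently.
init_network <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  widths_e <- c(spec$input_dim, spec$encoder_hidden, spec$latent_dim)
  enc <- Map(nn_linear_init, widths_e[-length(widths_e)], widths_e[-1L])
  acts_e <- c(rep("elu", length(spec$encoder_hidden)), "linear")
  widths_d <- c(spec$latent_dim, spec$decoder_hidden)
  dec <- Map(nn_linear_init, widths_d[-length(widths_d)], widths_d[-1L])
  acts_d <- rep("elu", length(spec$decoder_hidden))
  last <- widths_d[length(widths_d)]
  heads <- if (spec$likelihood == "zinb") {
    list(mean = nn_linear_init(last, spec$input_dim),
         dispersion = nn_linear_init(last, spec$input_dim),
         dropout = nn_linear_init(last, spec$input_dim))
  } else {
    list(theta = nn_linear_init(last, spec$input_dim))
  }
  list(spec = spec, enc = enc, acts_e = acts_e, dec = dec, acts_d = acts_d,
       heads = heads)
}

encode <- function(net, X) mlp_forward(net$enc, net$acts_e, X)$out

# Full forward pass with caches kept for the backward pass.
net_forward <- function(net, X, size_factors = rep(1, nrow(X))) {
  ef <- mlp_forward(net$enc, net$acts_e, X)
  Z <- ef$out
  df <- mlp_forward(net$dec, net$acts_d, Z)
  H <- df$out
  if (net$spec$likelihood == "zinb") {
    Am <- nn_affine(net$heads$mean, H)
    Ad <- nn_affine(net$heads$dispersion, H)
    Ao <- nn_affine(net$heads$dropout, H)
    Amc <- pmin(pmax(Am, -15), 15)
    params <- list(mean = size_factors * exp(Amc),
                   dispersion = log1p(exp(-abs(Ad))) + pmax(Ad, 0) + 1e-4,
                   dropout = .clamp(stats::plogis(Ao), .PARAM_FLOOR, 1 - .PARAM_FLOOR))
    cache_h <- list(Am = Am, Ad = Ad, Ao = Ao, H = H)
  } else {
    At <- nn_affine(net$heads$theta, H)
    params <- list(theta = .clamp(stats::plogis(At), .PARAM_FLOOR, 1 - .PARAM_FLOOR))
    cache_h <- list(At = At, H = H)
  }
  list(Z = Z, params = params,
       cache = list(enc = ef$caches, dec = df$caches, heads = cache_h,
                    size_factors = size_factors))
}

# Backward through decoder + heads given d(params); returns grads for dec and
# heads plus dZ. d_params uses the same names as params.
net_backward_decoder <- function(net, fw, d_params) {
  ch <- fw$cache$heads
  hgrads <- list()
  if (net$spec$likelihood == "zinb") {
    mask <- (ch$Am > -15 & ch$Am < 15) * 1
    dAm <- d_params$mean * fw$params$mean * mask           # mu = sf * exp(Am)
    dAd <- d_params$dispersion * stats::plogis(ch$Ad)      # softplus'
    om <- stats::plogis(ch$Ao)
    dAo <- d_params$dropout * om * (1 - om)
    hgrads$mean <- list(W = crossprod(ch$H, dAm), b = colSums(dAm))
    hgrads$dispersion <- list(W = crossprod(ch$H, dAd), b = colSums(dAd))
    hgrads$dropout <- list(W = crossprod(ch$H, dAo), b = colSums(dAo))
    dH <- tcrossprod(dAm, net$heads$mean$W) +
      tcrossprod(dAd, net$heads$dispersion$W) +
      tcrossprod(dAo, net$heads$dropout$W)
  } else {
    th <- stats::plogis(ch$At)
    dAt <- d_params$theta * th * (1 - th)
    hgrads$theta <- list(W = crossprod(ch$H, dAt), b = colSums(dAt))
    dH <- tcrossprod(dAt, net$heads$theta$W)
  }
  bb <- mlp_backward(net$dec, net$acts_d, fw$cache$dec, dH)
  list(dec = bb$grads, heads = hgrads, dZ = bb$dX)
}

net_backward_encoder <- function(net, fw, dZ) {
  mlp_backward(net$enc, net$acts_e, fw$cache$enc, dZ)$grads
}

recon_nll <- function(net, x_raw, params) {
  if (net$spec$likelihood == "zinb") zinb_nll(x_raw, params)
  else bernoulli_nll(x_raw, params)
}

recon_nll_grad <- function(net, x_raw, params) {
  if (net$spec$likelihood == "zinb") zinb_nll_grad(x_raw, params)
  else bernoulli_nll_grad(x_raw, params)
}

## ---- Adam over nested parameter lists ---------------------------------

.map_params <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1L]]) && !is.null(names(xs[[1L]])) &&
      all(c("W", "b") %in% names(xs[[1L]]))) {
    return(list(W = do.call(f, lapply(xs, `[[`, "W")),
                b = do.call(f, lapply(xs, `[[`, "b"))))
  }
  if (is.list(xs[[1L]]))
    return(Map(function(...) .map_params(f, ...), ...))
  do.call(f, xs)
}

adam_init <- function(params) {
  zeros <- .map_params(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- .map_params(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                        params, state$m, state$v)
  list(params = params, state = state)
}
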