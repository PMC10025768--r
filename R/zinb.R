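#' Zero-inflated negative binomial likelihoods
#'
#' The count model used throughout the package. A count x is zero with
#' probability `dropout` (a technical zero) and otherwise drawn from a
#' negative binomial with mean `mu` and dispersion `phi`, parameterized so
#' that the variance is `mu + mu^2 / phi`:
#'
#'   P(x | omega, mu, phi) = omega * 1(x = 0) +
#'     (1 - omega) * Gamma(x + phi) / (Gamma(x + 1) Gamma(phi)) *
#'     (phi / (phi + mu))^phi * (mu / (phi + mu))^x
#'
#' All likelihood evaluation happens in log space with `lgamma`; the x = 0
#' branch mixes the two components with a log-sum-exp.
#'
#' @name zinb
NULL

.PARAM_FLOOR <- 1e-7

#' Sample zero-inflated negative binomial counts
#'
#' @param mean matrix (or vector/scalar, recycled) of strictly positive NB
#'   means.
#' @param dispersion strictly positive NB dispersion(s); recycled against
#'   `mean`.
#' @param dropout zero-inflation probability in `[0, 1]`; scalar, per-gene
#'   vector, or matrix.
#' @param shape integer vector `c(n_cells, n_genes)`; required when `mean` is
#'   not already a matrix.
#' @param seed integer seed; the same seed reproduces the draw exactly.
#' @return integer matrix of counts with dimensions `shape`.
#' @export
zinb_sample <- function(mean, dispersion, dropout, shape = dim(mean), seed = 1L) {
  if (is.null(shape)) stop("`shape` must be given when `mean` has no dim")
  n <- as.integer(shape[1L]); p <- as.integer(shape[2L])
  if (any(mean <= 0)) stop("`mean` must be strictly positive")
  if (any(dispersion <= 0)) stop("`dispersion` must be strictly positive")
  if (any(dropout < 0 | dropout > 1)) stop("`dropout` must lie in [0, 1]")
  mu  <- matrix(rep_len(as.numeric(mean), n * p), n, p)
  phi <- matrix(rep_len(as.numeric(dispersion), n * p), n, p, byrow = !is.matrix(dispersion))
  om  <- matrix(rep_len(as.numeric(dropout), n * p), n, p, byrow = !is.matrix(dropout))
  set.seed(as.integer(seed))
  x <- matrix(stats::rnbinom(n * p, size = phi, mu = mu), n, p)
  drop <- matrix(stats::runif(n * p) < om, n, p)
  x[drop] <- 0L
  storage.mode(x) <- "integer"
  x
}

#' Log-probability of counts under the ZINB model
#'
#' @param x non-negative count matrix.
#' @param dropout,mean,dispersion parameter matrices (recycled to `dim(x)`),
#'   `dropout` in `[0, 1)`/clamped, `mean` and `dispersion` positive.
#' @return matrix of per-entry log-probabilities.
#' @export
zinb_logpmf <- function(x, dropout, mean, dispersion) {
  d <- dim(x)
  om  <- .clamp(matrix(rep_len(as.numeric(dropout), length(x)), d[1], d[2]), 0, 1)
  mu  <- pmax(matrix(rep_len(as.numeric(mean), length(x)), d[1], d[2]), .PARAM_FLOOR)
  phi <- pmax(matrix(rep_len(as.numeric(dispersion), length(x)), d[1], d[2]), .PARAM_FLOOR)
  log_nb0 <- phi * (log(phi) - log(phi + mu))          # log NB(0)
  ll <- matrix(0, d[1], d[2])
  z <- x == 0
  if (any(z)) {
    # log( omega + (1 - omega) * NB(0) ) via log-sum-exp; the boundaries
    # omega = 0 and omega = 1 pass through exactly (exp(-Inf) = 0)
    a <- log(om[z]); b <- log1p(-om[z]) + log_nb0[z]
    m <- pmax(a, b)
    lse <- m + log(exp(a - m) + exp(b - m))
    lse[!is.finite(m)] <- -Inf
    ll[z] <- lse
  }
  if (any(!z)) {
    xs <- x[!z]; mus <- mu[!z]; phis <- phi[!z]
    ll[!z] <- log1p(-om[!z]) +
      lgamma(xs + phis) - lgamma(xs + 1) - lgamma(phis) +
      phis * (log(phis) - log(phis + mus)) +
      xs * (log(mus) - log(phis + mus))
  }
  ll
}

#' Mean ZINB negative log-likelihood
#'
#' Returns `-(1 / (N * p)) * sum(log P(x_ij))`, the reconstruction loss of the
#' autoencoder.
#'
#' @param x non-negative integer count matrix.
#' @param params list with elements `dropout`, `mean`, `dispersion` (see
#'   [zinb_logpmf()]).
#' @return non-negative scalar.
#' @export
zinb_nll <- function(x, params) {
  .check_params(x, params, c("dropout", "mean", "dispersion"))
  -base::mean(zinb_logpmf(x, params$dropout, params$mean, params$dispersion))
}

# Gradient of the mean NLL w.r.t. omega, mu, phi (per entry, including the
# 1/(N p) factor). Used by the network backward pass; finite-difference
# checked in the tests.
zinb_nll_grad <- function(x, params) {
  d <- dim(x); np <- length(x)
  om  <- .clamp(params$dropout, .PARAM_FLOOR, 1 - .PARAM_FLOOR)
  mu  <- pmax(params$mean, .PARAM_FLOOR)
  phi <- pmax(params$dispersion, .PARAM_FLOOR)
  g_om <- g_mu <- g_phi <- matrix(0, d[1], d[2])
  z <- x == 0
  if (any(z)) {
    omz <- om[z]; muz <- mu[z]; phz <- phi[z]
    r <- exp(phz * (log(phz) - log(phz + muz)))       # NB(0)
    p0 <- omz + (1 - omz) * r
    g_om[z]  <- -(1 - r) / p0
    g_mu[z]  <- ((1 - omz) * r * phz / (phz + muz)) / p0
    g_phi[z] <- -((1 - omz) * r * (log(phz / (phz + muz)) + muz / (phz + muz))) / p0
  }
  if (any(!z)) {
    xs <- x[!z]; muz <- mu[!z]; phz <- phi[!z]
    g_om[!z]  <- 1 / (1 - om[!z])
    g_mu[!z]  <- (xs + phz) / (phz + muz) - xs / muz
    g_phi[!z] <- -(digamma(xs + phz) - digamma(phz) +
                     log(phz / (phz + muz)) + (muz - xs) / (phz + muz))
  }
  list(dropout = g_om / np, mean = g_mu / np, dispersion = g_phi / np)
}

#' Mean Bernoulli negative log-likelihood
#'
#' Loss for binarized scATAC gene-activity matrices: the decoder emits a
#' single mean parameter `theta` per entry and the reconstruction loss is the
#' mean binary cross-entropy.
#'
#' @param x binary matrix (entries 0/1).
#' @param params list with element `theta`, probabilities in `(0, 1)`; values
#'   are clamped to `[1e-7, 1 - 1e-7]` before taking logs.
#' @return non-negative scalar.
#' @export
bernoulli_nll <- function(x, params) {
  .check_params(x, params, "theta")
  if (!all(x %in% c(0, 1))) stop("`x` must be binary for the Bernoulli likelihood")
  th <- .clamp(matrix(rep_len(as.numeric(params$theta), length(x)), nrow(x), ncol(x)),
               .PARAM_FLOOR, 1 - .PARAM_FLOOR)
  -base::mean(x * log(th) + (1 - x) * log1p(-th))
}

bernoulli_nll_grad <- function(x, params) {
  th <- .clamp(params$theta, .PARAM_FLOOR, 1 - .PARAM_FLOOR)
  list(theta = (-(x / th) + (1 - x) / (1 - th)) / length(x))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.check_params <- function(x, params, fields) {
  for (f in fields) {
    p <- params[[f]]
    if (is.null(p)) stop(sprintf("params$%s is missing", f))
    if (anyNA(p)) stop(sprintf("params$%s contains NA/NaN", f))
    if (length(p) != 1L && length(p) != length(x) &&
        !(is.matrix(p) && all(dim(p) == dim(x))))
      stop(sprintf("params$%s shape does not match x", f))
  }
  if (any(x < 0)) stop("`x` must be non-negative")
  invisible(TRUE)
}
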