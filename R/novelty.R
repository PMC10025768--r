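#' Novel cell-type perception
#'
#' Each target cell gets an ensemble certainty score (E-score) built from
#' three complementary classifier read-outs: the entropy EN and confidence CF
#' of the main classifier, and the consistency CS (inner product) of the two
#' auxiliary classifiers' predictions:
#'
#'   E-score = (1 - EN / log K + CF + CS) / 3
#'
#' High scores mark cells that the source classifiers agree on confidently
#' (likely a known type). If the target contains novel types, the E-score
#' distribution tends to be bimodal; the presence of novel types is declared
#' when either the bimodality coefficient exceeds its threshold or Hartigan's
#' dip test rejects unimodality. The cut point delta between "known" and
#' "unknown" cells is then set adaptively as the mean E-score of manifold
#' mixup interpolants of target embeddings.
#'
#' @name novelty_perception
NULL

#' E-score components of one cell
#'
#' @param p main-classifier probability vector (length K).
#' @param p1,p2 auxiliary-classifier probability vectors.
#' @param K number of classes.
#' @return named vector `c(EN, CF, CS)`: entropy of `p` (natural log),
#'   maximum of `p`, and the inner product `p1 . p2`.
#' @export
e_score_components <- function(p, p1, p2, K = length(p)) {
  for (v in list(p, p1, p2)) {
    if (length(v) != K) stop("probability vectors must have length K")
    if (abs(sum(v) - 1) > 1e-4) stop("probability vectors must sum to 1")
  }
  c(EN = -sum(ifelse(p > 0, p * log(p), 0)),
    CF = max(p),
    CS = sum(p1 * p2))
}

#' E-score from its components
#'
#' @param EN entropy in `[0, log K]`.
#' @param CF confidence in `[1/K, 1]`.
#' @param CS consistency in `(0, 1]`.
#' @param K number of classes (>= 2; the `log K` normalization is undefined
#'   for a single class).
#' @return score in `[0, 1]`; higher means more certainly "known".
#' @export
e_score <- function(EN, CF, CS, K) {
  if (K < 2) stop("E-score requires K >= 2")
  (1 - EN / log(K) + CF + CS) / 3
}

# Vectorized over cells: P, P1, P2 are N x K probability matrices.
e_score_matrix <- function(P, P1, P2) {
  K <- ncol(P)
  EN <- -rowSums(ifelse(P > 0, P * log(P), 0))
  CF <- apply(P, 1L, max)
  CS <- rowSums(P1 * P2)
  data.frame(EN = EN, CF = CF, CS = CS,
             e_score = e_score(EN, CF, CS, K))
}

#' Bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' bias-corrected sample skewness and `g2` the bias-corrected excess
#' kurtosis (SAS convention; moments from `e1071`). Benchmarks: 1/3 for a
#' normal, 5/9 for a uniform, approaching 1 for a balanced two-point
#' distribution; values above 5/9 suggest bimodality.
#'
#' @param samples numeric vector with `n >= 4`.
#' @return BC in `[0, 1]` (0, with a warning, for a zero-variance sample).
#' @export
bimodality_coefficient <- function(samples) {
  n <- length(samples)
  if (n < 4L) stop("bimodality coefficient needs n >= 4")
  if (stats::var(samples) == 0) {
    warning("zero-variance sample; bimodality coefficient defined as 0")
    return(0)
  }
  g1 <- e1071::skewness(samples, type = 2)
  g2 <- e1071::kurtosis(samples, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Detect the presence of novel cell types
#'
#' OR-rule over the two bimodality measures: novelty is declared when
#' `BC > bc_threshold` or the dip test p-value falls below `alpha_dip`.
#'
#' @param escores per-cell E-scores (length >= 10).
#' @param alpha_dip dip-test significance level.
#' @param bc_threshold BC decision threshold (uniform benchmark 5/9).
#' @param n_boot,seed bootstrap settings passed to [dip_test()].
#' @return list of class `bimodality_result`: `bc_value`, `bc_threshold`,
#'   `dip_statistic`, `dip_pvalue`, `alpha_dip`, `novel_detected`.
#' @export
detect_novelty <- function(escores, alpha_dip = 0.05, bc_threshold = 5 / 9,
                           n_boot = 200L, seed = 1L) {
  if (length(escores) < 10L) stop("need at least 10 cells to test bimodality")
  bc <- bimodality_coefficient(escores)
  dt <- dip_test(escores, n_boot = n_boot, seed = seed)
  structure(list(bc_value = bc, bc_threshold = bc_threshold,
                 dip_statistic = dt$dip_statistic, dip_pvalue = dt$p_value,
                 alpha_dip = alpha_dip,
                 novel_detected = (bc > bc_threshold) || (dt$p_value < alpha_dip)),
            class = "bimodality_result")
}

#' Adaptive partition threshold via manifold mixup
#'
#' Draws pairs of distinct cells, interpolates their embeddings with a
#' Uniform(0,1) coefficient per pair, scores the interpolants through the
#' three (frozen) classifier heads, and returns the mean E-score. With
#' `n_pairs = "all"` every ordered pair is enumerated (the exact all-pairs
#' average); otherwise a seeded Monte-Carlo subsample of the pairs is used.
#' By default enumeration is used when `Nt <= 1500` and `min(Nt(Nt-1),
#' 50 Nt)` sampled pairs otherwise.
#'
#' @param R Nt x d matrix of embeddings.
#' @param model a `source_model` supplying the classifier heads.
#' @param n_pairs `"auto"`, `"all"`, or a positive integer.
#' @param seed integer seed for pair and lambda draws.
#' @param lambda optional fixed mixing coefficient(s) (recycled over pairs)
#'   overriding the Uniform(0,1) draw; intended for exact oracles in tests.
#' @return the threshold delta (scalar).
#' @export
mixup_threshold <- function(R, model, n_pairs = "auto", seed = 1L,
                            lambda = NULL) {
  n <- nrow(R)
  if (n < 2L) stop("mixup threshold needs at least 2 cells")
  set.seed(as.integer(seed))
  if (identical(n_pairs, "auto"))
    n_pairs <- if (n <= 1500L) "all" else min(n * (n - 1), 50L * n)
  if (identical(n_pairs, "all")) {
    ii <- rep(seq_len(n), each = n - 1L)
    jj <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]))
  } else {
    ii <- sample.int(n, n_pairs, replace = TRUE)
    jj <- sample.int(n - 1L, n_pairs, replace = TRUE)
    jj <- ifelse(jj >= ii, jj + 1L, jj)   # j != i, uniform over the rest
  }
  lam <- if (is.null(lambda)) stats::runif(length(ii))
  else rep_len(lambda, length(ii))
  total <- 0; cnt <- 0
  chunk <- 100000L
  for (start in seq(1L, length(ii), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(ii))
    Zm <- lam[sel] * R[ii[sel], , drop = FALSE] +
      (1 - lam[sel]) * R[jj[sel], , drop = FALSE]
    pr <- classifier_probs(model, Zm)
    es <- e_score_matrix(pr$p, pr$p1, pr$p2)$e_score
    total <- total + sum(es); cnt <- cnt + length(es)
  }
  total / cnt
}

#' Partition target cells into known and unknown groups
#'
#' When novelty was detected, cells with E-score strictly above `delta` are
#' "known" and the rest (ties included) are "unknown"; otherwise every cell
#' is "known" and `delta` is `NA`.
#'
#' @param escores per-cell E-scores.
#' @param delta threshold from [mixup_threshold()].
#' @param novel_detected logical from [detect_novelty()].
#' @return list of class `partition`: `delta`, `known_idx`, `unknown_idx`.
#' @export
partition_cells <- function(escores, delta, novel_detected) {
  n <- length(escores)
  if (!isTRUE(novel_detected)) {
    out <- list(delta = NA_real_, known_idx = seq_len(n), unknown_idx = integer(0))
  } else {
    known <- which(escores > delta)
    out <- list(delta = delta, known_idx = known,
                unknown_idx = setdiff(seq_len(n), known))
  }
  class(out) <- "partition"
  out
}
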