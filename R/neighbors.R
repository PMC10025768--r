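#' Multi-order neighborhoods and the affinity loss
#'
#' Neighbor search runs against the full memory bank by exact cosine
#' similarity. Each cell's M-nearest-neighbor set deliberately includes the
#' cell itself (self-regularization). Neighbors are then split into three
#' tiers: bidirectional (mutual) neighbors V1, unidirectional neighbors V2,
#' and extensional neighbors V3 (neighbors-of-neighbors, deduplicated and
#' excluding VM itself). The affinity loss pulls a known cell's prediction
#' toward the bank soft labels of its neighbors, down-weighting V2 and V3.
#'
#' @name neighbors
NULL

#' Exact cosine M-nearest neighbors against a bank
#'
#' The query cell itself is always ranked first; remaining slots are filled
#' by decreasing cosine similarity with ties broken by lower index.
#' Zero-norm rows get similarity 0 to everything (with a warning).
#'
#' @param R Nt x d embedding bank.
#' @param query_idx indices of the cells to query (must index rows of `R`).
#' @param M neighborhood size, `1 <= M <= Nt`.
#' @return named list mapping each query index to its integer neighbor set
#'   `VM(i)` (self first).
#' @export
cosine_knn <- function(R, query_idx = seq_len(nrow(R)), M) {
  n <- nrow(R)
  if (M < 1L || M > n) stop("`M` must lie in 1..nrow(R)")
  nrm <- sqrt(rowSums(R^2))
  if (any(nrm == 0)) {
    warning("zero-norm embedding row(s); their cosine similarity is defined as 0")
    nrm[nrm == 0] <- Inf
  }
  Rn <- R / nrm
  out <- vector("list", length(query_idx))
  S <- Rn[query_idx, , drop = FALSE] %*% t(Rn)
  for (q in seq_along(query_idx)) {
    i <- query_idx[q]
    s <- S[q, ]
    s[i] <- Inf                       # self always included, ranked first
    ord <- order(-s, seq_len(n))      # ties: lower index first
    out[[q]] <- ord[seq_len(M)]
  }
  names(out) <- as.character(query_idx)
  out
}

#' Split M-nearest-neighbor sets into the three affinity tiers
#'
#' `V1(i)` are mutual neighbors (`j` in `VM(i)` with `i` in `VM(j)`), `V2(i)`
#' the rest of `VM(i)`, and `V3(i)` the deduplicated neighbors-of-neighbors
#' minus `VM(i)`.
#'
#' @param VM named list over all cells as returned by [cosine_knn()] with
#'   `query_idx = seq_len(Nt)` (V1 and V3 need every cell's neighborhood).
#' @return list of class `neighbor_sets` with lists `V1`, `V2`, `V3` indexed
#'   like `VM`, plus `VM` itself.
#' @export
split_neighbors <- function(VM) {
  n <- length(VM)
  V1 <- V2 <- V3 <- vector("list", n)
  for (i in seq_len(n)) {
    vm <- VM[[i]]
    mutual <- vapply(vm, function(j) i %in% VM[[j]], logical(1))
    V1[[i]] <- vm[mutual]
    V2[[i]] <- vm[!mutual]
    V3[[i]] <- setdiff(unique(unlist(VM[vm])), vm)
  }
  structure(list(VM = VM, V1 = V1, V2 = V2, V3 = V3), class = "neighbor_sets")
}

#' Multi-order local affinity loss
#'
#' For each batch cell i in the known set D, an aggregate neighbor soft
#' label `a_i = sum_{V1 cap D} S_j + alpha2 * sum_{V2 cap D} S_k + alpha3 *
#' sum_{V3 cap D} S_l` is formed from the (gradient-free) soft-label bank,
#' and the loss is `-(1/|D|) * sum_i a_i . p_i`. Cells outside D contribute
#' nothing (and receive no gradient).
#'
#' @param batch_idx integer indices of the mini-batch cells.
#' @param P matrix of current predictions for the batch (rows follow
#'   `batch_idx`).
#' @param nbh a `neighbor_sets` over all cells.
#' @param S Nt x K soft-label bank (treated as constant).
#' @param part a `partition` (supplies D).
#' @param alpha2,alpha3 down-weights for unidirectional and extensional
#'   neighbors (default 0.1 each).
#' @param grad when `TRUE` also return the gradient w.r.t. the classifier
#'   logits of the batch rows.
#' @return the scalar loss, or (with `grad`) a list `loss`, `A` (aggregate
#'   targets), `d_logits`.
#' @export
affinity_loss <- function(batch_idx, P, nbh, S, part, alpha2 = 0.1,
                          alpha3 = 0.1, grad = FALSE) {
  D <- part$known_idx
  nD <- length(D)
  K <- ncol(S)
  A <- matrix(0, length(batch_idx), K)
  if (nD == 0L) {
    warning("known set D is empty; affinity loss is 0")
  } else {
    inD <- logical(nrow(S)); inD[D] <- TRUE
    for (r in seq_along(batch_idx)) {
      i <- batch_idx[r]
      if (!inD[i]) next
      v1 <- nbh$V1[[i]]; v1 <- v1[inD[v1]]
      v2 <- nbh$V2[[i]]; v2 <- v2[inD[v2]]
      v3 <- nbh$V3[[i]]; v3 <- v3[inD[v3]]
      a <- rep(0, K)
      if (length(v1)) a <- a + colSums(S[v1, , drop = FALSE])
      if (length(v2)) a <- a + alpha2 * colSums(S[v2, , drop = FALSE])
      if (length(v3)) a <- a + alpha3 * colSums(S[v3, , drop = FALSE])
      A[r, ] <- a
    }
  }
  loss <- if (nD == 0L) 0 else -sum(A * P) / nD
  if (!grad) return(loss)
  # d loss / d logits through the softmax: -(1/|D|) p * (a - (a . p))
  ap <- rowSums(A * P)
  d_logits <- if (nD == 0L) A else -(P * (A - ap)) / nD
  list(loss = loss, A = A, d_logits = d_logits)
}
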