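# Exhaustive O(n^2) oracle used against the package's neighbor machinery.
brute_vm <- function(R, M) {
  n <- nrow(R)
  nrm <- sqrt(rowSums(R^2)); nrm[nrm == 0] <- Inf
  Rn <- R / nrm
  lapply(seq_len(n), function(i) {
    s <- as.numeric(Rn %*% Rn[i, ])
    s[i] <- Inf
    order(-s, seq_len(n))[seq_len(M)]
  })
}

brute_split <- function(VM) {
  n <- length(VM)
  list(V1 = lapply(seq_len(n), function(i)
         VM[[i]][vapply(VM[[i]], function(j) i %in% VM[[j]], logical(1))]),
       V2 = lapply(seq_len(n), function(i)
         VM[[i]][!vapply(VM[[i]], function(j) i %in% VM[[j]], logical(1))]),
       V3 = lapply(seq_len(n), function(i)
         setdiff(unique(unlist(lapply(VM[[i]], function(j) VM[[j]]))), VM[[i]])))
}

test_that("cosine_knn solves the worked 3-point instance", {
  R <- rbind(c(1, 0), c(1, 0.1) / sqrt(1.01), c(0, 1))
  vm <- cosine_knn(R, M = 2)
  expect_setequal(vm[["1"]], c(1L, 2L))
  expect_setequal(vm[["3"]], c(3L, 2L))
})

test_that("M = 1 returns only the cell itself", {
  set.seed(51)
  R <- matrix(rnorm(40), 10, 4)
  vm <- cosine_knn(R, M = 1)
  for (i in 1:10) expect_equal(vm[[i]], i)
})

test_that("zero-norm rows get similarity 0 with a warning", {
  R <- rbind(c(1, 0), c(0, 0), c(1, 0.2))
  expect_warning(vm <- cosine_knn(R, M = 2), "zero-norm")
  expect_equal(sort(vm[["1"]]), c(1L, 3L))  # zero row never preferred
})

test_that("neighbor sets match the exhaustive oracle on random instances", {
  set.seed(52)
  for (i in 1:25) {
    n <- sample(10:60, 1); d <- sample(2:8, 1); M <- sample(1:min(10, n), 1)
    R <- matrix(rnorm(n * d), n, d)
    vm <- cosine_knn(R, M = M)
    expect_identical(unname(vm), brute_vm(R, M))
    nbh <- split_neighbors(vm)
    oracle <- brute_split(vm)
    for (j in seq_len(n)) {
      expect_setequal(nbh$V1[[j]], oracle$V1[[j]])
      expect_setequal(nbh$V2[[j]], oracle$V2[[j]])
      expect_setequal(nbh$V3[[j]], oracle$V3[[j]])
      # structural invariants
      expect_true(j %in% nbh$V1[[j]])
      expect_length(intersect(nbh$V1[[j]], nbh$V2[[j]]), 0)
      expect_setequal(union(nbh$V1[[j]], nbh$V2[[j]]), vm[[j]])
      expect_length(intersect(nbh$V3[[j]], vm[[j]]), 0)
    }
  }
})

test_that("split_neighbors solves the worked 3-point instance", {
  R <- rbind(c(1, 0), c(1, 0.1) / sqrt(1.01), c(0, 1))
  nbh <- split_neighbors(cosine_knn(R, M = 2))
  expect_setequal(nbh$V1[[1]], c(1L, 2L))
  expect_length(nbh$V2[[1]], 0)
  expect_setequal(nbh$V1[[3]], 3L)
  expect_setequal(nbh$V2[[3]], 2L)
  expect_setequal(nbh$V3[[3]], 1L)
})

test_that("affinity loss reproduces the single-cell self-regularization value", {
  S <- matrix(0.5, 1, 2)
  nbh <- structure(list(VM = list(1L), V1 = list(1L), V2 = list(integer(0)),
                        V3 = list(integer(0))), class = "neighbor_sets")
  part <- partition_cells(1, 0.5, TRUE)  # known = {1}
  loss <- affinity_loss(1L, matrix(0.5, 1, 2), nbh, S, part)
  expect_equal(loss, -0.5, tolerance = 1e-12)
})

test_that("onehot neighbor agreement contributes -1 per neighbor", {
  S <- rbind(c(1, 0), c(1, 0))
  nbh <- structure(list(VM = list(c(1L, 2L), c(2L, 1L)),
                        V1 = list(c(1L, 2L), c(2L, 1L)),
                        V2 = list(integer(0), integer(0)),
                        V3 = list(integer(0), integer(0))),
                   class = "neighbor_sets")
  part <- partition_cells(c(1, 1), 0.5, TRUE)
  loss <- affinity_loss(1:2, rbind(c(1, 0), c(1, 0)), nbh, S, part)
  # each cell: V1 = {self, other} both onehot-matching -> contribution -2;
  # mean over |D| = 2 cells
  expect_equal(loss, -2, tolerance = 1e-12)
})

test_that("vectorized affinity loss equals a loop-based reference", {
  set.seed(53)
  for (rep in 1:10) {
    n <- 10; K <- 3; M <- 3
    R <- matrix(rnorm(n * 4), n, 4)
    S <- matrix(rexp(n * K), n, K); S <- S / rowSums(S)
    P <- matrix(rexp(n * K), n, K); P <- P / rowSums(P)
    vm <- cosine_knn(R, M = M)
    nbh <- split_neighbors(vm)
    known <- sort(sample(n, 7))
    part <- list(delta = 0.5, known_idx = known,
                 unknown_idx = setdiff(1:n, known))
    class(part) <- "partition"
    a2 <- 0.1; a3 <- 0.07
    # independent loop over Eq-style terms
    ref <- 0
    for (i in known) {
      a <- rep(0, K)
      for (j in intersect(nbh$V1[[i]], known)) a <- a + S[j, ]
      for (k in intersect(nbh$V2[[i]], known)) a <- a + a2 * S[k, ]
      for (l in intersect(nbh$V3[[i]], known)) a <- a + a3 * S[l, ]
      ref <- ref - sum(a * P[i, ])
    }
    ref <- ref / length(known)
    expect_equal(affinity_loss(1:n, P, nbh, S, part, a2, a3), ref,
                 tolerance = 1e-10)
  }
})

test_that("cells outside D contribute neither loss nor gradient", {
  set.seed(54)
  n <- 8; K <- 3
  R <- matrix(rnorm(n * 4), n, 4)
  S <- matrix(rexp(n * K), n, K); S <- S / rowSums(S)
  P <- matrix(rexp(n * K), n, K); P <- P / rowSums(P)
  nbh <- split_neighbors(cosine_knn(R, M = 3))
  part <- list(delta = .5, known_idx = c(1L, 3L, 5L), unknown_idx = c(2L, 4L, 6L, 7L, 8L))
  class(part) <- "partition"
  out <- affinity_loss(1:n, P, nbh, S, part, grad = TRUE)
  expect_true(all(out$d_logits[part$unknown_idx, ] == 0))
  # and an empty D warns with zero loss
  part0 <- list(delta = .5, known_idx = integer(0), unknown_idx = 1:n)
  class(part0) <- "partition"
  expect_warning(l0 <- affinity_loss(1:n, P, nbh, S, part0), "empty")
  expect_equal(l0, 0)
})

test_that("affinity gradient w.r.t. classifier logits matches finite differences", {
  set.seed(55)
  n <- 6; K <- 3
  R <- matrix(rnorm(n * 4), n, 4)
  S <- matrix(rexp(n * K), n, K); S <- S / rowSums(S)
  logits <- matrix(rnorm(n * K), n, K)
  nbh <- split_neighbors(cosine_knn(R, M = 3))
  part <- list(delta = .5, known_idx = 1:n, unknown_idx = integer(0))
  class(part) <- "partition"
  sm <- function(L) exp(L) / rowSums(exp(L))
  out <- affinity_loss(1:n, sm(logits), nbh, S, part, grad = TRUE)
  h <- 1e-6
  for (k in sample(length(logits), 6)) {
    up <- logits; up[k] <- up[k] + h
    dn <- logits; dn[k] <- dn[k] - h
    fd <- (affinity_loss(1:n, sm(up), nbh, S, part) -
             affinity_loss(1:n, sm(dn), nbh, S, part)) / (2 * h)
    expect_equal(out$d_logits[k], fd, tolerance = 1e-5)
  }
})
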