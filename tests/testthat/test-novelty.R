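test_that("E-score components reproduce the worked examples", {
  onehot <- c(1, 0, 0)
  expect_equal(unname(e_score_components(onehot, onehot, onehot)), c(0, 1, 1))
  unif <- rep(0.25, 4)
  expect_equal(unname(e_score_components(unif, unif, unif)),
               c(log(4), 0.25, 0.25), tolerance = 1e-12)
  comp <- e_score_components(c(0.7, 0.2, 0.1), c(0.6, 0.3, 0.1), c(0.5, 0.4, 0.1))
  expect_equal(unname(comp), c(0.801819, 0.7, 0.43), tolerance = 1e-6)
  expect_error(e_score_components(c(.5, .2, .1), unif[1:3], unif[1:3]), "sum to 1")
})

test_that("E-score combines components with the logK normalization", {
  expect_equal(e_score(0, 1, 1, 5), 1)
  expect_equal(e_score(log(4), 0.25, 0.25, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(e_score(0.801819, 0.7, 0.43, 3), 0.466717, tolerance = 1e-5)
  expect_error(e_score(0, 1, 1, 1), "K >= 2")
})

test_that("E-score is monotone in each component over random probability triples", {
  set.seed(31)
  K <- 4
  EN <- runif(1e4, 0, log(K)); CF <- runif(1e4, 1 / K, 1); CS <- runif(1e4, 0.01, 1)
  base <- e_score(EN, CF, CS, K)
  expect_true(all(e_score(EN + 1e-3, CF, CS, K) < base))
  expect_true(all(e_score(EN, CF + 1e-3, CS, K) > base))
  expect_true(all(e_score(EN, CF, CS + 1e-3, K) > base))
  expect_true(all(base >= 0 & base <= 1 + 1e-12))
})

test_that("per-cell scores permute with the cells", {
  set.seed(32)
  P <- matrix(rexp(30), 10, 3); P <- P / rowSums(P)
  P1 <- matrix(rexp(30), 10, 3); P1 <- P1 / rowSums(P1)
  P2 <- matrix(rexp(30), 10, 3); P2 <- P2 / rowSums(P2)
  es <- e_score_matrix(P, P1, P2)
  perm <- sample(10)
  es_p <- e_score_matrix(P[perm, ], P1[perm, ], P2[perm, ])
  expect_equal(es_p$e_score, es$e_score[perm], tolerance = 1e-12)
})

test_that("bimodality coefficient hits the normal/uniform/two-point benchmarks", {
  set.seed(33)
  expect_equal(bimodality_coefficient(rnorm(1e5)), 1 / 3, tolerance = 0.02)
  expect_equal(bimodality_coefficient(runif(1e5)), 5 / 9, tolerance = 0.02)
  expect_equal(bimodality_coefficient(rep(c(0, 1), 5e4)), 1, tolerance = 0.02)
  expect_error(bimodality_coefficient(c(1, 2, 3)), "n >= 4")
  expect_warning(bc0 <- bimodality_coefficient(rep(2, 10)), "zero-variance")
  expect_equal(bc0, 0)
})

test_that("detect_novelty applies the OR rule over BC and dip", {
  set.seed(34)
  # strongly bimodal: both measures fire
  x <- c(rbeta(300, 2, 10), rbeta(450, 10, 2))
  r <- detect_novelty(x, seed = 1)
  expect_true(r$novel_detected)
  # skewed-but-unimodal sample chosen so BC fires while the dip does not:
  # the OR rule must still declare novelty
  y <- c(rbeta(500, 8, 2), rbeta(12, 1, 8))
  ry <- detect_novelty(y, seed = 1)
  if (ry$bc_value > 5 / 9 && ry$dip_pvalue >= 0.05)
    expect_true(ry$novel_detected)
  expect_error(detect_novelty(runif(5)), "at least 10")
})

test_that("detect_novelty separates unimodal and bimodal score simulations", {
  set.seed(35)
  fired_uni <- fired_bi <- 0L
  for (i in 1:60) {
    uni <- rbeta(400, 8, 2)
    bi <- c(rbeta(160, 2, 10), rbeta(240, 10, 2))
    fired_uni <- fired_uni + detect_novelty(uni, seed = 1)$novel_detected
    fired_bi <- fired_bi + detect_novelty(bi, seed = 1)$novel_detected
  }
  expect_lte(fired_uni, 3L)   # >= 95% silent on the unimodal null
  expect_gte(fired_bi, 57L)   # >= 95% firing on the bimodal mixture
})

test_that("mixup threshold collapses to the common E-score for identical embeddings", {
  pair <- tiny_pair(seed = 7, n_source = 100, n_target = 20)
  model <- tiny_model(pair, seed = 7, epochs = 6)
  z <- matrix(rnorm(6), 1, 6)
  R <- z[rep(1, 12), ]
  pr <- scOpenAnno:::classifier_probs(model, z)
  expected <- e_score_matrix(pr$p, pr$p1, pr$p2)$e_score
  expect_equal(mixup_threshold(R, model, n_pairs = "all", seed = 1), expected,
               tolerance = 1e-10)
})

test_that("all-pairs mixup threshold equals a brute-force enumeration", {
  pair <- tiny_pair(seed = 8, n_source = 100, n_target = 20)
  model <- tiny_model(pair, seed = 8, epochs = 6)
  set.seed(41)
  R <- matrix(rnorm(18), 3, 6)
  lam <- 0.3
  # independent loop-based oracle over the 6 ordered pairs
  es <- numeric(0)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    z <- lam * R[i, ] + (1 - lam) * R[j, ]
    pr <- scOpenAnno:::classifier_probs(model, matrix(z, 1))
    es <- c(es, e_score(-sum(pr$p * log(pr$p)), max(pr$p), sum(pr$p1 * pr$p2),
                        ncol(pr$p)))
  }
  expect_equal(mixup_threshold(R, model, n_pairs = "all", seed = 5, lambda = lam),
               mean(es), tolerance = 1e-10)
})

test_that("Monte-Carlo mixup threshold converges to the all-pairs value", {
  pair <- tiny_pair(seed = 9, n_source = 120, n_target = 200)
  model <- tiny_model(pair, seed = 9, epochs = 8)
  pre_t <- target_preprocessed(model, pair)
  R <- init_banks(model, pre_t)$R
  # fix lambda so only pair sampling varies between estimates
  full <- mixup_threshold(R, model, n_pairs = "all", seed = 2, lambda = 0.5)
  errs <- vapply(c(1e2, 1e3, 1e4), function(np)
    abs(mixup_threshold(R, model, n_pairs = np, seed = 2, lambda = 0.5) - full),
    numeric(1))
  expect_lt(errs[3], errs[1] + 0.01)
  expect_lt(errs[3], 0.01)
  expect_error(mixup_threshold(R[1, , drop = FALSE], model), "at least 2")
})

test_that("partition applies the strict-inequality rule and the closed shortcut", {
  p <- partition_cells(c(0.9, 0.2, 0.55), 0.55, TRUE)
  expect_equal(p$known_idx, 1L)
  expect_equal(p$unknown_idx, c(2L, 3L))
  p2 <- partition_cells(c(0.9, 0.2, 0.55), 0.55, FALSE)
  expect_equal(p2$known_idx, 1:3)
  expect_length(p2$unknown_idx, 0)
  expect_true(is.na(p2$delta))
})

test_that("partition separates well-separated score populations", {
  set.seed(43)
  hits <- 0
  for (i in 1:10) {
    known <- rbeta(300, 10, 2); unknown <- rbeta(100, 2, 10)
    es <- c(known, unknown)
    truth <- rep(c(TRUE, FALSE), c(300, 100))
    delta <- 0.5 * mean(known) + 0.5 * mean(unknown)  # stand-in threshold
    part <- partition_cells(es, delta, TRUE)
    acc <- (sum(truth[part$known_idx]) + sum(!truth[part$unknown_idx])) / 400
    hits <- hits + (acc >= 0.95)
  }
  expect_gte(hits, 9)
})
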