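# Normalization and per-sample enrichment scoring.

test_that("expression_matrix validates its invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_s3_class(expression_matrix(m), "expression_matrix")
  expect_error(expression_matrix(unname(m)), "rownames")
  expect_error(expression_matrix(m - 10, "FPKM"), "non-negative")
  m2 <- m; rownames(m2) <- c("a", "a")
  expect_error(expression_matrix(m2), "duplicate")
})

test_that("quantile normalization matches the hand-worked 3x2 case", {
  m <- matrix(c(0, 3, 7, 1, 3, 15), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- log_quantile_normalize(expression_matrix(m))
  # log2(FPKM+1) columns: (0,2,3) and (1,2,4); sorted means (0.5, 2, 3.5)
  expect_equal(unname(unclass(out)),
               matrix(c(0.5, 2, 3.5, 0.5, 2, 3.5), 3, 2),
               ignore_attr = TRUE)
  expect_identical(transform_state(out), "LOG2_QNORM")
})

test_that("quantile step is idempotent and conserves the reference mass", {
  e <- rand_expr(50, 8, seed = 2, state = "FPKM")
  out1 <- log_quantile_normalize(e)
  # re-applying the quantile step to the already-normalized values
  again <- metsubtype:::quantile_normalize_columns(unclass(out1))
  expect_equal(unname(again), unname(unclass(out1)), tolerance = 1e-12)
  ref_sum <- sum(rowMeans(apply(log2(unclass(e) + 1), 2, sort)))
  expect_equal(sum(unclass(out1)), ncol(e) * ref_sum, tolerance = 1e-8)
})

test_that("identically distributed columns become permutations of one multiset", {
  base <- c(1, 2, 4, 9, 16)
  m <- cbind(s1 = base, s2 = rev(base), s3 = sample(base))
  rownames(m) <- paste0("g", 1:5)
  out <- log_quantile_normalize(expression_matrix(m))
  for (j in 2:3)
    expect_equal(unname(sort(unclass(out)[, j])),
                 unname(sort(unclass(out)[, 1])))
})

test_that("ties within a column stay tied after normalization", {
  m <- matrix(c(5, 5, 1, 2, 3, 4), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  out <- unclass(log_quantile_normalize(expression_matrix(m)))
  expect_equal(out[1, 1], out[2, 1])
})

test_that("ssGSEA matches the brute-force random-walk oracle to 1e-12", {
  set.seed(21)
  for (rep in 1:25) {
    g <- sample(6:10, 1)
    n <- sample(2:4, 1)
    e <- rand_expr(g, n, seed = rep)
    k <- sample(2:(g - 2), 1)
    members <- sample(rownames(e), k)
    sets <- gene_set_collection(list(S = members))
    tau <- sample(c(0, 0.25, 1), 1)
    got <- ssgsea_scores(e, sets, tau = tau, normalize = FALSE)
    for (j in seq_len(n)) {
      exp_es <- ssgsea_oracle(unclass(e)[, j],
                              which(rownames(e) %in% members), tau)
      expect_equal(unname(got["S", j]), exp_es, tolerance = 1e-12)
    }
  }
})

test_that("a set occupying the top ranks outscores any other set", {
  e <- rand_expr(40, 3)
  j <- 1
  ord <- order(-unclass(e)[, j])
  top_set <- rownames(e)[ord[1:10]]
  other_sets <- lapply(1:10, function(i) sample(rownames(e), 10))
  names(other_sets) <- paste0("other", 1:10)
  sc <- ssgsea_scores(e, gene_set_collection(c(list(top = top_set),
                                               other_sets)),
                      normalize = FALSE)
  expect_true(all(sc["top", j] > sc[-1, j]))
})

test_that("scores are invariant to gene relabeling and row order", {
  e <- rand_expr(30, 4)
  sets <- gene_set_collection(list(S = rownames(e)[c(3, 8, 15, 22)]))
  sc1 <- ssgsea_scores(e, sets, normalize = FALSE)
  perm <- sample(nrow(e))
  e2 <- expression_matrix(unclass(e)[perm, ], "LOG2_QNORM")
  sc2 <- ssgsea_scores(e2, sets, normalize = FALSE)
  expect_equal(sc1, sc2, tolerance = 1e-12)
})

test_that("raising in-set expression never decreases the set score", {
  set.seed(5)
  for (rep in 1:10) {
    e <- rand_expr(25, 2, seed = rep + 100)
    members <- sample(rownames(e), 6)
    sets <- gene_set_collection(list(S = members))
    s0 <- ssgsea_scores(e, sets, normalize = FALSE)["S", 1]
    m2 <- unclass(e)
    m2[members, 1] <- m2[members, 1] + runif(6, 0, 3)
    s1 <- ssgsea_scores(expression_matrix(m2, "LOG2_QNORM"), sets,
                        normalize = FALSE)["S", 1]
    expect_gte(s1, s0 - 1e-10)
  }
})

test_that("zero-overlap sets and constant samples warn per contract", {
  e <- rand_expr(10, 2)
  sets <- gene_set_collection(list(S = rownames(e)[1:3], Z = c("nope")))
  expect_warning(sc <- ssgsea_scores(e, sets), "zero overlap")
  expect_true(all(is.na(sc["Z", ])))
  m <- unclass(e); m[, 1] <- 5
  expect_warning(ssgsea_scores(expression_matrix(m, "LOG2_QNORM"),
                               sets["S"]), "constant")
})

test_that("marker-mean scores: singleton, linearity, hand computation", {
  m <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9,
                10, 11, 12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  e <- expression_matrix(m, "LOG2_QNORM")
  sets <- gene_set_collection(list(single = "g2",
                                   trio = c("g1", "g2", "g3")))
  sc <- marker_signature_scores(e, sets)
  expect_equal(unname(sc["single", ]), m["g2", ], ignore_attr = TRUE)
  expect_equal(unname(sc["trio", ]), colMeans(m), ignore_attr = TRUE)
  sc2 <- marker_signature_scores(expression_matrix(m + 3, "LOG2_QNORM"),
                                 sets)
  expect_equal(sc2["trio", ], sc["trio", ] + 3)
  expect_error(marker_signature_scores(expression_matrix(2^m, "FPKM"),
                                       sets), "LOG2_QNORM")
})

test_that("GMT round-trips sets and source labels", {
  d <- withr::local_tempdir()
  sets <- gene_set_collection(list(a = c("g1", "g2"), b = c("g9")),
                              source = c("pathway", "TME-signature"))
  p <- file.path(d, "sets.gmt")
  write_gmt(sets, p)
  back <- read_gmt(p)
  expect_equal(unclass(back), unclass(sets), ignore_attr = TRUE)
  expect_identical(unname(attr(back, "source")),
                   c("pathway", "TME-signature"))
})
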