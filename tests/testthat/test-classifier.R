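# Odds-ratio screening, lasso selection, refit, prediction, CV.

norm_cohort <- function(seed = 1, ...) {
  co <- small_cohort(seed = seed, ...)
  list(cohort = co, norm = log_quantile_normalize(co$expression))
}

test_that("screening returns 20 genes per subtype from the planted blocks", {
  co <- simulate_cohort(cohort_config(n_samples = 120, n_genes = 800,
                                      seed = 2))
  cn <- list(cohort = co, norm = log_quantile_normalize(co$expression))
  scr <- screen_leading_genes(cn$norm, cn$cohort$labels)
  expect_length(scr$panel, 80)
  for (s in LETTERS[1:4]) {
    sel <- scr$selected[[s]]
    expect_length(sel, 20)
    expect_true(all(head(sel, 10) %in% cn$cohort$truth$up_genes[[s]]))
    expect_true(all(tail(sel, 10) %in% cn$cohort$truth$down_genes[[s]]))
  }
})

test_that("pure-noise genes still yield the 20-per-class contract", {
  set.seed(3)
  m <- matrix(rnorm(200 * 48, 7, 1), 200, 48,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("s%02d", 1:48)))
  labels <- rep(LETTERS[1:4], each = 12)
  scr <- screen_leading_genes(m, labels)
  for (s in LETTERS[1:4]) expect_length(scr$selected[[s]], 20)
  ors <- unlist(lapply(scr$per_subtype, function(t) t$or))
  expect_lt(median(abs(log(ors))), 1)
})

test_that("constant genes are excluded with a warning", {
  m <- matrix(rnorm(50 * 30, 5, 1), 50, 30,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%02d", 1:30)))
  m[7, ] <- 3
  expect_warning(scr <- screen_leading_genes(m, rep(c("A", "B"), 15)),
                 "constant")
  expect_identical(scr$excluded, "g07")
  expect_false("g07" %in% scr$panel)
})

test_that("lasso selection shrinks fully at large lambda and never exceeds the panel", {
  cn <- norm_cohort(seed = 4)
  scr <- screen_leading_genes(cn$norm, cn$cohort$labels)
  panel_m <- unclass(cn$norm)[scr$panel, ]
  big <- glmnet::glmnet(t(panel_m), cn$cohort$labels,
                        family = "multinomial", lambda = 10)
  nz <- Reduce(`|`, lapply(stats::coef(big), function(ci)
    as.matrix(ci)[-1, 1] != 0))
  expect_equal(sum(nz), 0)
  las <- fit_lasso_multinomial(panel_m, cn$cohort$labels, seed = 11)
  expect_lte(length(las$selected), length(scr$panel))
  expect_gt(length(las$selected), 0)
  # every planted block contributes at least one selected gene
  for (s in LETTERS[1:4])
    expect_gt(length(intersect(las$selected,
                               c(cn$cohort$truth$up_genes[[s]],
                                 cn$cohort$truth$down_genes[[s]]))), 0)
})

test_that("refit separates training data and matches after serialization", {
  cn <- norm_cohort(seed = 5)
  model <- train_subtype_classifier(cn$norm, cn$cohort$labels, seed = 3)
  pred <- predict_subtype(model, cn$norm)
  expect_gte(mean(as.character(pred$label) ==
                    as.character(cn$cohort$labels)), 0.95)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.json")
  write_classifier(model, p)
  back <- read_classifier(p)
  pred2 <- predict_subtype(back, cn$norm)
  expect_equal(pred2[model$classes], pred[model$classes], tolerance = 1e-9)
  expect_identical(pred2$label, pred$label)
})

test_that("label permutation drops training accuracy at matched shrinkage", {
  cn <- norm_cohort(seed = 6)
  set.seed(8)
  perm <- sample(cn$cohort$labels)
  fit_acc <- function(lbl) {
    scr <- screen_leading_genes(cn$norm, lbl)
    model <- refit_final(cn$norm, lbl, genes = scr$panel, ridge_lambda = 8)
    mean(as.character(predict_subtype(model, cn$norm)$label) ==
           as.character(lbl))
  }
  acc_true <- fit_acc(cn$cohort$labels)
  acc_perm <- fit_acc(perm)
  expect_gte(acc_true, 0.95)          # signal survives strong shrinkage
  expect_lt(acc_perm, acc_true - 0.3) # permuted labels collapse toward chance
})

test_that("prediction probabilities are a proper simplex with fixed ties", {
  cn <- norm_cohort(seed = 7)
  model <- train_subtype_classifier(cn$norm, cn$cohort$labels, seed = 2)
  pred <- predict_subtype(model, cn$norm)
  expect_equal(rowSums(as.matrix(pred[model$classes])), rep(1, nrow(pred)),
               tolerance = 1e-12)
  zero <- model
  zero$coefficients[] <- 0
  zero$intercepts[] <- 0
  p0 <- predict_subtype(zero, cn$norm)
  expect_true(all(abs(as.matrix(p0[model$classes]) - 0.25) < 1e-12))
  expect_true(all(p0$label == "A"))   # tie broken by class order
  expect_error(predict_subtype(model,
                               unclass(cn$norm)[-match(model$panel[1],
                                                       rownames(cn$norm)), ]),
               "missing")
})

test_that("class centroids predict their own class", {
  cn <- norm_cohort(seed = 8)
  model <- train_subtype_classifier(cn$norm, cn$cohort$labels, seed = 4)
  m <- unclass(cn$norm)
  cents <- vapply(levels(cn$cohort$labels), function(s)
    rowMeans(m[, cn$cohort$labels == s, drop = FALSE]),
    numeric(nrow(m)))
  colnames(cents) <- paste0("centroid_", levels(cn$cohort$labels))
  pred <- predict_subtype(model, cents)
  expect_identical(as.character(pred$label), levels(cn$cohort$labels))
})

test_that("repeated CV is deterministic and near-perfect on separable data", {
  cn <- norm_cohort(seed = 9)
  cv1 <- repeated_cv(cn$norm, cn$cohort$labels, iterations = 2, seed = 21)
  cv2 <- repeated_cv(cn$norm, cn$cohort$labels, iterations = 2, seed = 21)
  expect_identical(cv1$per_iteration, cv2$per_iteration)
  expect_gte(cv1$mean_accuracy, 0.95)
})

test_that("no leakage: held-out samples cannot influence fold training", {
  cn <- norm_cohort(seed = 10, n_samples = 100)
  m <- unclass(cn$norm)
  fold <- stratified_folds <- metsubtype:::stratified_folds(
    cn$cohort$labels, 5, seed = 2)
  tr <- fold != 1
  model_a <- train_subtype_classifier(m[, tr], cn$cohort$labels[tr],
                                      cv_folds = 3, seed = 5)
  m2 <- m
  m2[, !tr] <- m2[, !tr] + matrix(rnorm(sum(!tr) * nrow(m), 0, 5),
                                  nrow(m))
  model_b <- train_subtype_classifier(m2[, tr], cn$cohort$labels[tr],
                                      cv_folds = 3, seed = 5)
  expect_identical(model_a$panel, model_b$panel)
  expect_equal(model_a$coefficients, model_b$coefficients)
})

test_that("no-information cohorts give chance-level CV accuracy", {
  # the clean null removes the planted programs entirely: with latent
  # cluster structure left in place, label permutation alone stays above
  # 1/4 (the model recovers each true cluster's permuted-majority label;
  # see the methods vignette)
  cfg <- small_config(seed = 30, n_samples = 80, effect = 0,
                      subtype_proportions = rep(0.25, 4))
  co <- simulate_cohort(cfg)
  norm <- log_quantile_normalize(co$expression)
  cv <- repeated_cv(norm, co$labels, iterations = 5, seed = 6)
  expect_lt(abs(cv$mean_accuracy - 0.25), 0.05)
})

test_that("LOOCV bookkeeping matches its confusion-matrix oracle", {
  cfg <- cohort_config(n_samples = 32, n_genes = 200,
                       program_genes_per_subtype = 8,
                       program_down_genes_per_subtype = 8,
                       program_log2_effect = 2.5,
                       subtype_proportions = rep(0.25, 4), seed = 12)
  co <- simulate_cohort(cfg)
  norm <- log_quantile_normalize(co$expression)
  res <- loocv(norm, co$labels, seed = 3, n_top = 5, n_bottom = 5)
  expect_equal(nrow(res$predictions), 32)
  cm <- table(factor(res$predictions$truth, LETTERS[1:4]),
              factor(res$predictions$predicted, LETTERS[1:4]))
  trace <- sum(diag(cm))
  expect_equal(res$concordance, trace / 32)
  expect_gte(res$concordance, 0.9)
})
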