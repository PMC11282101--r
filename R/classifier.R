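# Subtype classifier: odds-ratio screening (top/bottom 10 genes per
# subtype), lasso-multinomial gene selection, ridge-stabilized multinomial
# refit, repeated stratified cross-validation and leave-one-out validation.

# Z-score genes (rows) across samples; constant genes get scale NA.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, NA)
  list(z = z, center = mu, scale = sd)
}

# Vectorized per-gene univariate logistic regression (intercept + one
# z-scored covariate) against a binary outcome, with a tiny ridge penalty
# for deterministic behavior under separation. Newton-Raphson run
# elementwise across all genes at once.
univariate_logistic_or <- function(z, y, ridge = 1e-8, max_iter = 40,
                                   tol = 1e-8) {
  g <- nrow(z)
  b0 <- rep(log(mean(y) / (1 - mean(y))), g)
  b1 <- numeric(g)
  active <- seq_len(g)               # genes whose Newton step still moves
  for (it in seq_len(max_iter)) {
    za <- z[active, , drop = FALSE]
    eta <- pmin(pmax(b0[active] + za * b1[active], -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    resid <- sweep(-mu, 2, y, "+")
    u0 <- rowSums(resid) - ridge * b0[active]
    u1 <- rowSums(za * resid) - ridge * b1[active]
    h00 <- rowSums(w) + ridge
    wz <- w * za
    h01 <- rowSums(wz)
    h11 <- rowSums(wz * za) + ridge
    det <- h00 * h11 - h01^2
    d0 <- (h11 * u0 - h01 * u1) / det
    d1 <- (h00 * u1 - h01 * u0) / det
    b0[active] <- b0[active] + d0
    b1[active] <- b1[active] + d1
    done <- pmax(abs(d0), abs(d1)) < tol | abs(b1[active]) > 25
    active <- active[!done]
    if (length(active) == 0) break
  }
  list(beta = b1, or = exp(b1), separated = abs(b1) > 15)
}

#' Screen leading genes per subtype by univariate logistic odds ratio
#'
#' For every subtype a one-vs-rest univariate logistic regression is fitted
#' per gene on z-scored expression, and the 10 genes with the highest and
#' the 10 with the lowest odds ratios are taken. The union across subtypes
#' (duplicates collapsed) is the candidate panel for the lasso step — 80
#' genes when the per-subtype selections do not overlap.
#'
#' @param expr [expression_matrix] (log scale) or numeric genes x samples
#'   matrix.
#' @param labels subtype labels per sample.
#' @param n_top,n_bottom genes taken from each end of the OR ranking.
#' @param ridge ridge stabilizer for the logistic fits.
#' @return a `screen_result` list: `per_subtype` (data.frames of gene, OR,
#'   ranked), `selected` (per subtype, the 20 chosen genes), `panel`
#'   (deduplicated union), `excluded` (constant genes).
#' @export
screen_leading_genes <- function(expr, labels, n_top = 10, n_bottom = 10,
                                 ridge = 1e-8) {
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)
  if (ncol(m) != length(labels))
    stop("labels must match samples", call. = FALSE)
  zs <- zscore_rows(m)
  constant <- which(is.na(zs$scale) | zs$scale == 0)
  if (length(constant)) {
    warning(sprintf("%d constant gene(s) excluded from screening",
                    length(constant)), call. = FALSE)
    z <- zs$z[-constant, , drop = FALSE]
  } else z <- zs$z
  genes <- rownames(z) %||% as.character(seq_len(nrow(z)))
  if (nrow(z) < n_top + n_bottom)
    stop("fewer usable genes than n_top + n_bottom", call. = FALSE)

  per_subtype <- list()
  selected <- list()
  for (s in levels(labels)) {
    fit <- univariate_logistic_or(z, as.integer(labels == s), ridge = ridge)
    ord <- order(-fit$or, seq_along(fit$or))
    tab <- data.frame(gene = genes[ord], or = fit$or[ord],
                      beta = fit$beta[ord], separated = fit$separated[ord],
                      row.names = NULL)
    if (any(tab$separated))
      warning(sprintf("subtype %s: %d gene(s) with separation-scale OR (ridge-stabilized)",
                      s, sum(tab$separated)), call. = FALSE)
    per_subtype[[s]] <- tab
    selected[[s]] <- c(utils::head(tab$gene, n_top),
                       utils::tail(tab$gene, n_bottom))
  }
  panel <- unique(unlist(selected, use.names = FALSE))
  structure(list(per_subtype = per_subtype, selected = selected,
                 panel = panel,
                 excluded = if (length(constant)) rownames(m)[constant]
                            else character(0),
                 n_top = n_top, n_bottom = n_bottom),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d subtypes x (%d top + %d bottom) -> %d-gene panel\n",
              length(x$selected), x$n_top, x$n_bottom, length(x$panel)))
  invisible(x)
}

# glmnet warns on every multinomial fit with a class under 8 observations;
# routine for the small stratified folds used here, so that one warning is
# muffled (everything else propagates).
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Stratified fold assignment, deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (s in levels(labels)) {
      idx <- sample(which(labels == s))
      if (length(idx) < k)
        stop(sprintf("class %s too small for %d-fold stratification", s, k),
             call. = FALSE)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Lasso-multinomial gene selection over a candidate panel
#'
#' Multinomial logistic regression with an L1 penalty over a 50-point log
#' lambda grid; lambda is chosen by stratified cross-validated multinomial
#' deviance with the one-standard-error rule. A gene is selected if any
#' class coefficient is nonzero at the chosen lambda. If the 1-SE lambda
#' shrinks every gene away, the deviance-minimizing lambda is used instead
#' (flagged in the result).
#'
#' @param expr [expression_matrix] or matrix restricted to the candidate
#'   panel (genes x samples).
#' @param labels subtype labels.
#' @param lambda optional explicit lambda grid.
#' @param nlambda grid size when `lambda` is NULL.
#' @param cv_folds folds for the internal lambda cross-validation.
#' @param seed seed for fold assignment.
#' @return list: `selected` (gene IDs), `lambda` (chosen value), `rule`
#'   (`"1se"` or `"min"`), `cvfit` (the cv.glmnet object).
#' @export
fit_lasso_multinomial <- function(expr, labels, lambda = NULL, nlambda = 50,
                                  cv_folds = 5, seed = 1) {
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  labels <- factor(labels)
  if (min(table(labels)) < cv_folds)
    stop("each class needs >= cv_folds samples", call. = FALSE)
  foldid <- stratified_folds(labels, cv_folds, seed)
  x <- t(m)
  cvfit <- quiet_small_class(
    glmnet::cv.glmnet(x, labels, family = "multinomial",
                      type.measure = "deviance", foldid = foldid,
                      lambda = lambda, nlambda = nlambda,
                      standardize = TRUE))
  pick <- function(s) {
    cf <- stats::coef(cvfit, s = s)
    nz <- Reduce(`|`, lapply(cf, function(ci) as.matrix(ci)[-1, 1] != 0))
    rownames(m)[nz]
  }
  sel <- pick(cvfit$lambda.1se)
  rule <- "1se"
  lam <- cvfit$lambda.1se
  if (length(sel) == 0) {
    sel <- pick(cvfit$lambda.min)
    rule <- "min"
    lam <- cvfit$lambda.min
  }
  list(selected = sel, lambda = lam, rule = rule, cvfit = cvfit)
}

#' Final multinomial refit on the selected genes
#'
#' Multinomial logistic regression on the selected genes with a tiny ridge
#' penalty (deterministic under separation), storing the per-gene training
#' normalization so prediction applies identical scaling.
#'
#' @param expr [expression_matrix] or matrix (genes x samples) containing
#'   the selected genes.
#' @param labels subtype labels.
#' @param genes selected gene IDs (default: all rows of `expr`).
#' @param ridge_lambda ridge penalty of the stabilized refit.
#' @return a `subtype_classifier`: `panel`, `classes`, `center`, `scale`,
#'   `intercepts`, `coefficients` (genes x classes), `ridge_lambda`,
#'   `version`.
#' @export
refit_final <- function(expr, labels, genes = NULL, ridge_lambda = 1e-4) {
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  labels <- factor(labels)
  if (is.null(genes)) genes <- rownames(m)
  if (length(genes) == 0) stop("empty selected gene set", call. = FALSE)
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) stop("genes absent from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- m[genes, , drop = FALSE]
  zs <- zscore_rows(m)
  if (any(is.na(zs$scale) | zs$scale == 0))
    stop("constant gene in selected set", call. = FALSE)
  x <- t(zs$z)
  # decreasing lambda path ending at the tiny ridge; glmnet fits the path
  # efficiently and we read coefficients at its end
  lambdas <- exp(seq(log(1), log(ridge_lambda), length.out = 20))
  fit <- quiet_small_class(
    glmnet::glmnet(x, labels, family = "multinomial", alpha = 0,
                   lambda = lambdas, standardize = FALSE))
  cf <- stats::coef(fit, s = ridge_lambda, exact = FALSE)
  coefs <- vapply(cf, function(ci) as.matrix(ci)[-1, 1],
                  numeric(length(genes)))
  if (length(genes) == 1L)
    coefs <- matrix(coefs, nrow = 1,
                    dimnames = list(genes, levels(labels)))
  intercepts <- vapply(cf, function(ci) as.matrix(ci)[1, 1], 0)
  structure(list(panel = genes, classes = levels(labels),
                 center = stats::setNames(zs$center, genes),
                 scale = stats::setNames(zs$scale, genes),
                 intercepts = intercepts,
                 coefficients = coefs,
                 ridge_lambda = ridge_lambda,
                 version = as.character(utils::packageVersion("metsubtype"))),
            class = "subtype_classifier")
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("subtype_classifier: %d-gene panel, classes %s\n",
              length(x$panel), paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict subtypes for new samples
#'
#' Applies the stored training normalization, computes per-class linear
#' scores and softmax probabilities, and assigns each sample to the
#' maximum-probability class (ties broken by class order A < B < C < D).
#' All panel genes must be present; missing genes are an error, never
#' silently imputed.
#'
#' @param model a `subtype_classifier`.
#' @param expr [expression_matrix] or matrix (genes x samples) for the new
#'   samples.
#' @return data.frame: `sample_id`, `label`, one probability column per
#'   class.
#' @export
predict_subtype <- function(model, expr) {
  stopifnot(inherits(model, "subtype_classifier"))
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  miss <- setdiff(model$panel, rownames(m))
  if (length(miss))
    stop("panel genes missing from input: ", paste(miss, collapse = ", "),
         call. = FALSE)
  z <- (m[model$panel, , drop = FALSE] - model$center) / model$scale
  eta <- t(z) %*% model$coefficients +
    matrix(model$intercepts, ncol(m), length(model$classes), byrow = TRUE)
  eta <- eta - apply(eta, 1, max)
  prob <- exp(eta) / rowSums(exp(eta))
  colnames(prob) <- model$classes
  label <- factor(model$classes[apply(prob, 1, which.max)],
                  levels = model$classes)
  out <- data.frame(sample_id = colnames(m) %||%
                      as.character(seq_len(ncol(m))),
                    label = label, prob, check.names = FALSE,
                    row.names = NULL)
  out
}

#' Train the full screen / lasso / refit classifier
#'
#' Convenience wrapper running the three construction stages on one
#' training set. Used directly and inside every cross-validation fold (the
#' whole pipeline is re-run per fold, so no selection leakage).
#'
#' @param expr genes x samples training matrix.
#' @param labels training subtype labels.
#' @param n_top,n_bottom screening selection sizes.
#' @param cv_folds folds for the internal lambda CV.
#' @param seed seed (fold assignment).
#' @return a `subtype_classifier` with attributes `screen` and `lasso`.
#' @export
train_subtype_classifier <- function(expr, labels, n_top = 10,
                                     n_bottom = 10, cv_folds = 5, seed = 1) {
  scr <- screen_leading_genes(expr, labels, n_top = n_top,
                              n_bottom = n_bottom)
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  las <- fit_lasso_multinomial(m[scr$panel, , drop = FALSE], labels,
                               cv_folds = cv_folds, seed = seed)
  model <- refit_final(m, labels, genes = las$selected)
  attr(model, "screen") <- scr
  attr(model, "lasso") <- las[c("lambda", "rule", "selected")]
  model
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' Screening, lasso selection and the final refit are repeated inside every
#' training fold; held-out samples are predicted with the fold's model.
#' Deterministic given `seed`.
#'
#' @param expr genes x samples matrix.
#' @param labels subtype labels.
#' @param folds folds per iteration.
#' @param iterations repeat count.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param n_top,n_bottom screening sizes.
#' @param inner_folds folds for the lambda cross-validation inside each
#'   training fold; default adapts to the smallest training-class size
#'   (capped at 5).
#' @return list: `mean_accuracy`, `sd_accuracy`, `per_iteration` (mean
#'   accuracy per iteration), `per_fold` (iterations x folds matrix).
#' @export
repeated_cv <- function(expr, labels, folds = 5, iterations = 200, seed = 1,
                        n_top = 10, n_bottom = 10, inner_folds = NULL) {
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  labels <- factor(labels)
  per_fold <- matrix(NA_real_, iterations, folds)
  for (it in seq_len(iterations)) {
    it_seed <- child_seed(seed, it)
    foldid <- stratified_folds(labels, folds, it_seed)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fi <- inner_folds %||% min(5, min(table(labels[tr])))
      model <- train_subtype_classifier(m[, tr, drop = FALSE], labels[tr],
                                        n_top = n_top, n_bottom = n_bottom,
                                        cv_folds = fi,
                                        seed = child_seed(it_seed, f))
      pred <- predict_subtype(model, m[, !tr, drop = FALSE])
      per_fold[it, f] <- mean(as.character(pred$label) ==
                                as.character(labels[!tr]))
    }
  }
  per_iter <- rowMeans(per_fold)
  list(mean_accuracy = mean(per_fold), sd_accuracy = stats::sd(per_iter),
       per_iteration = per_iter, per_fold = per_fold)
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a classifier trained (full pipeline) on all
#' other samples; concordance is the fraction of predictions matching the
#' given (consensus-clustering) labels.
#'
#' @inheritParams repeated_cv
#' @return list: `predictions` (data.frame sample_id, truth, predicted),
#'   `concordance`.
#' @export
loocv <- function(expr, labels, seed = 1, n_top = 10, n_bottom = 10) {
  m <- if (inherits(expr, "expression_matrix")) unclass(expr) else as.matrix(expr)
  labels <- factor(labels)
  n <- ncol(m)
  if (n < nlevels(labels) + 1) stop("too few samples for LOOCV",
                                    call. = FALSE)
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- train_subtype_classifier(m[, -i, drop = FALSE], labels[-i],
                                      n_top = n_top, n_bottom = n_bottom,
                                      cv_folds = min(5, min(table(labels[-i]))),
                                      seed = child_seed(seed, i))
    pred[i] <- as.character(predict_subtype(model,
                                            m[, i, drop = FALSE])$label)
  }
  data <- data.frame(sample_id = colnames(m) %||% as.character(seq_len(n)),
                     truth = as.character(labels), predicted = pred)
  list(predictions = data,
       concordance = mean(data$truth == data$predicted))
}

#' Serialize / deserialize a subtype classifier as JSON
#'
#' The JSON model carries the panel, per-class coefficients and intercepts,
#' training normalization, ridge lambda, and package version, so a stored
#' model reproduces identical predictions after a round trip.
#'
#' @param model a `subtype_classifier`.
#' @param path JSON path.
#' @export
write_classifier <- function(model, path) {
  payload <- list(panel = model$panel, classes = model$classes,
                  center = as.list(model$center),
                  scale = as.list(model$scale),
                  intercepts = as.list(stats::setNames(model$intercepts,
                                                       model$classes)),
                  coefficients = apply(model$coefficients, 2, as.list),
                  ridge_lambda = model$ridge_lambda,
                  version = model$version)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- vapply(p$classes,
                  function(cl) unlist(p$coefficients[[cl]])[p$panel],
                  numeric(length(p$panel)))
  coefs <- matrix(coefs, nrow = length(p$panel),
                  dimnames = list(p$panel, p$classes))
  structure(list(panel = p$panel, classes = p$classes,
                 center = unlist(p$center)[p$panel],
                 scale = unlist(p$scale)[p$panel],
                 intercepts = stats::setNames(unlist(p$intercepts)[p$classes],
                                              p$classes),
                 coefficients = coefs[, p$classes, drop = FALSE],
                 ridge_lambda = p$ridge_lambda,
                 version = p$version),
            class = "subtype_classifier")
}
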