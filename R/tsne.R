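#' t-SNE embedding of samples
#'
#' Exact (non-Barnes-Hut) t-distributed stochastic neighbor embedding,
#' suitable for the cohort sizes this package targets (tens to a few
#' hundred samples). Conditional input affinities use a per-point Gaussian
#' bandwidth found by bisection to match `perplexity`; the embedding is
#' optimized by gradient descent with momentum and early exaggeration.
#' Deterministic given `seed`.
#'
#' @param x numeric matrix with samples in rows (e.g. `t(scores)` for an
#'   enrichment matrix), or an enrichment matrix with `samples_in` set to
#'   `"cols"`.
#' @param perplexity effective neighborhood size; requires at least
#'   `3 * perplexity` samples.
#' @param seed integer seed for the random initialization.
#' @param n_iter gradient-descent iterations.
#' @param samples_in `"rows"` (default) or `"cols"`.
#' @return numeric matrix, samples x 2, rownames preserved.
#' @export
tsne_embed <- function(x, perplexity = 10, seed = 1, n_iter = 500,
                       samples_in = c("rows", "cols")) {
  samples_in <- match.arg(samples_in)
  if (samples_in == "cols") x <- t(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3 * perplexity)
    stop("need at least 3 * perplexity samples", call. = FALSE)

  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_perp <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(ifelse(pr > 0, pr * log(pr), 0))
      }
      if (abs(h - log_perp) < 1e-7) break
      if (h > log_perp) {            # entropy too high -> narrow kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    p[i, -i] <- if (sum(exp(-di * beta)) > 0) exp(-di * beta) / sum(exp(-di * beta)) else 1 / (n - 1)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  with_local_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    eta <- 100
    for (it in seq_len(n_iter)) {
      exagg <- if (it <= 100) 4 else 1
      momentum <- if (it <= 250) 0.5 else 0.8
      num <- 1 / (1 + as.matrix(stats::dist(y))^2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      stiff <- (exagg * p - q) * num
      grad <- 4 * (diag(rowSums(stiff)) - stiff) %*% y
      inc <- momentum * inc - eta * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    rownames(y) <- rownames(x)
    colnames(y) <- c("tsne1", "tsne2")
    y
  })
}
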