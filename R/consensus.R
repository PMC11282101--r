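# Subtype discovery: consensus k-means over resampled enrichment profiles,
# CDF / delta-AUC model-order selection, final labels from the consensus
# matrix itself.

# k-means++ seeding, then Lloyd iterations via stats::kmeans.
kmeanspp <- function(x, k, n_restart = 10, iter_max = 50) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(n_restart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1) for (c in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[c, ] <- x[sample.int(n, 1L, prob = probs), ]
      d2c <- rowSums((x - matrix(centers[c, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2c)
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Consensus clustering of an enrichment matrix
#'
#' Resampling-based cluster-stability analysis in the style of
#' ConsensusClusterPlus. For every k in `k_range`, samples are repeatedly
#' subsampled without replacement, the subsample is partitioned by k-means
#' (k-means++ seeding, `n_restart` restarts), and co-clustering of sample
#' pairs is tallied. The consensus matrix entry (i, j) is the fraction of
#' resamples containing both i and j in which they landed in the same
#' cluster. Final subtype labels at the selected k come from average-linkage
#' hierarchical clustering of 1 - consensus, so the consensus evidence
#' itself determines the partition.
#'
#' @param enrich numeric matrix, features (gene sets) x samples, e.g. from
#'   [ssgsea_scores()]. Columns are clustered.
#' @param k_range integer vector of cluster numbers to scan (default 2:6).
#' @param n_resamples number of subsampling iterations per k (default 250).
#' @param subsample_fraction fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param threshold relative delta-AUC threshold for [select_k()].
#' @param inner per-resample clustering algorithm: `"hclust"`
#'   (average-linkage hierarchical, the default of the reference consensus
#'   implementation) or `"kmeans"` (k-means++ seeding with `n_restart`
#'   restarts). With strongly separated planted clusters, k-means partitions
#'   beyond the true k are near-deterministic across resamples, which keeps
#'   the relative delta-AUC above the selection threshold and inflates the
#'   chosen k; hierarchical inner clustering sheds only small outlier
#'   groups beyond the true k and restores the sharp CDF elbow the
#'   delta-AUC rule expects.
#' @param n_restart k-means restarts per resample (`inner = "kmeans"`).
#' @return a `consensus_result` list: `consensus` (named list of per-k
#'   matrices), `stats` (per-k AUC and relative delta-AUC, see
#'   [cdf_delta_auc()]), `selected_k`, `labels` (named integer vector at the
#'   selected k), and `resample_log`.
#' @export
consensus_cluster <- function(enrich, k_range = 2:6, n_resamples = 250,
                              subsample_fraction = 0.8, seed = 1,
                              threshold = 0.05,
                              inner = c("hclust", "kmeans"),
                              n_restart = 10) {
  inner <- match.arg(inner)
  if (!is.matrix(enrich) || !is.numeric(enrich))
    stop("'enrich' must be a numeric matrix (sets x samples)", call. = FALSE)
  enrich <- enrich[stats::complete.cases(enrich), , drop = FALSE]
  n <- ncol(enrich)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= n)
    stop("k_max must be smaller than the number of samples", call. = FALSE)
  if (n < max(k_range) + 1L) stop("too few samples", call. = FALSE)
  if (n_resamples < 2L) stop("need at least 2 resamples", call. = FALSE)
  x <- t(enrich)                      # samples as rows
  if (all(apply(x, 2, stats::var) == 0))
    stop("zero-variance enrichment matrix", call. = FALSE)
  m_sub <- max(2L, floor(subsample_fraction * n))

  consensus <- vector("list", length(k_range))
  names(consensus) <- paste0("k", k_range)
  with_local_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      co <- matrix(0, n, n)
      tog <- matrix(0, n, n)
      for (b in seq_len(n_resamples)) {
        idx <- sort(sample.int(n, m_sub))
        part <- if (inner == "kmeans") {
          kmeanspp(x[idx, , drop = FALSE], k,
                   n_restart = n_restart)$cluster
        } else {
          stats::cutree(stats::hclust(stats::dist(x[idx, , drop = FALSE]),
                                      method = "average"), k = k)
        }
        tog[idx, idx] <- tog[idx, idx] + 1
        for (cl in seq_len(k)) {
          mem <- idx[part == cl]
          co[mem, mem] <- co[mem, mem] + 1
        }
      }
      never <- tog == 0
      if (any(never[lower.tri(never)]))
        warning(sprintf("k=%d: %d sample pair(s) never co-sampled; consensus set to 0",
                        k, sum(never[lower.tri(never)])), call. = FALSE)
      cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
      diag(cons) <- 1
      dimnames(cons) <- list(colnames(enrich), colnames(enrich))
      consensus[[ki]] <- cons
    }
  })

  res <- structure(list(consensus = consensus, k_range = k_range,
                        stats = NULL, selected_k = NA_integer_,
                        labels = NULL,
                        resample_log = list(n_resamples = n_resamples,
                                            subsample_fraction = subsample_fraction,
                                            seed = seed, inner = inner,
                                            n_restart = n_restart)),
                   class = "consensus_result")
  res$stats <- cdf_delta_auc(res)
  res$selected_k <- select_k(res$stats, threshold = threshold)
  res$labels <- consensus_labels(res, res$selected_k)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in [%d, %d], selected k = %d\n",
              min(x$k_range), max(x$k_range), x$selected_k))
  print(x$stats)
  invisible(x)
}

#' Cut final labels from a consensus matrix
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity
#' (1 - consensus) cut at k clusters. Labels are relabeled A, B, C, ... in
#' decreasing cluster size for reporting stability.
#'
#' @param result a `consensus_result`.
#' @param k number of clusters (defaults to the selected k).
#' @return named factor of subtype labels per sample.
#' @export
consensus_labels <- function(result, k = result$selected_k) {
  cons <- result$consensus[[paste0("k", k)]]
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(hc, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  remap <- stats::setNames(LETTERS[seq_len(k)], names(sizes))
  stats::setNames(factor(unname(remap[as.character(cl)]),
                         levels = LETTERS[seq_len(k)]),
                  rownames(cons))
}

#' CDF and delta-AUC statistics of consensus matrices
#'
#' For each k the empirical CDF of the lower-triangle consensus entries is
#' summarized (reported on a 100-bin grid over [0, 1]) and its area under
#' the curve computed as the exact integral of the empirical step CDF,
#' `AUC = 1 - mean(entries)` — the limit of the binned trapezoid sum. The
#' relative delta-AUC at k is `(AUC_k - AUC_{k-1}) / AUC_{k-1}`; at the
#' smallest k it is defined as `AUC_kmin` itself.
#'
#' @param result a `consensus_result` (or a list with `consensus` and
#'   `k_range`).
#' @return data.frame with columns `k`, `auc`, `delta_auc`, plus a `cdf`
#'   attribute (list of 101-point CDF curves per k).
#' @export
cdf_delta_auc <- function(result) {
  ks <- result$k_range
  grid <- seq(0, 1, length.out = 101L)
  auc <- numeric(length(ks))
  cdfs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    cons <- result$consensus[[paste0("k", ks[i])]]
    v <- cons[lower.tri(cons)]
    auc[i] <- 1 - mean(v)
    cdfs[[i]] <- stats::ecdf(v)(grid)
  }
  delta <- c(auc[1], diff(auc) / auc[-length(auc)])
  out <- data.frame(k = ks, auc = auc, delta_auc = delta)
  names(cdfs) <- paste0("k", ks)
  attr(out, "cdf") <- cdfs
  attr(out, "cdf_grid") <- grid
  out
}

#' Select the number of clusters by the relative delta-AUC elbow
#'
#' The selected k is the largest k whose relative delta-AUC exceeds
#' `threshold`; if none does, the smallest k is returned. Operationalizes
#' the usual "CDF plus consensus matrix" visual rule as a reproducible
#' criterion.
#'
#' @param stats data.frame from [cdf_delta_auc()].
#' @param threshold relative delta-AUC cutoff (default 0.05).
#' @return integer selected k.
#' @export
select_k <- function(stats, threshold = 0.05) {
  if (is.null(stats) || nrow(stats) == 0) stop("empty stats", call. = FALSE)
  ok <- stats$delta_auc > threshold
  if (any(ok)) max(stats$k[ok]) else min(stats$k)
}
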