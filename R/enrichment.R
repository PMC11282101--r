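#' Per-sample rank-weighted gene-set enrichment scores (ssGSEA-style)
#'
#' For each sample, genes are ranked by expression (average ranks for ties).
#' For each gene set the score is the sum over the ranking (walked from the
#' most to the least expressed gene, ties broken by row order) of the
#' difference between the weighted in-set empirical CDF, with gene weights
#' `rank^tau`, and the unweighted out-of-set CDF. With `normalize = TRUE`
#' each set's scores are min-max scaled across samples to [0, 1], which is
#' what downstream consensus clustering consumes (only relative per-sample
#' scores matter there).
#'
#' Sets with no member present in the matrix are recorded as all-`NA` rows
#' with a warning. A constant-expression sample degenerates to all-tied
#' ranks; the tie policy still applies and a warning is emitted.
#'
#' @param expr an [expression_matrix] (any transform state; scores depend on
#'   within-sample ranks only).
#' @param sets a [gene_set_collection].
#' @param tau non-negative rank-weighting exponent. `tau = 0` weights all
#'   in-set genes equally; larger values emphasize extreme ranks. Default
#'   0.25.
#' @param normalize min-max scale each set's scores across samples.
#' @return numeric matrix, sets x samples, with attribute `method = "ssgsea"`.
#' @export
ssgsea_scores <- function(expr, sets, tau = 0.25, normalize = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(sets, "gene_set_collection"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("'tau' must be a single non-negative number", call. = FALSE)
  genes <- rownames(expr)
  membership <- lapply(sets, function(s) which(genes %in% s))
  if (all(lengths(membership) == 0L))
    stop("no gene set overlaps the expression matrix", call. = FALSE)
  empty <- names(sets)[lengths(membership) == 0L]
  if (length(empty))
    warning("gene set(s) with zero overlap recorded as missing: ",
            paste(empty, collapse = ", "), call. = FALSE)

  n_genes <- nrow(expr)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  vals <- unclass(expr)
  for (j in seq_len(ncol(expr))) {
    x <- vals[, j]
    if (length(unique(x)) == 1L)
      warning(sprintf("sample '%s' has constant expression; all ranks tied",
                      colnames(expr)[j]), call. = FALSE)
    rk <- rank(x, ties.method = "average")
    ord <- order(-x, seq_along(x))   # walk from top expression; stable ties
    w <- rk[ord]^tau
    for (s in seq_along(sets)) {
      idx <- membership[[s]]
      if (length(idx) == 0L) next
      inset <- logical(n_genes)
      inset[idx] <- TRUE
      inset <- inset[ord]
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (n_genes - length(idx))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    for (s in seq_len(nrow(scores))) {
      v <- scores[s, ]
      if (all(is.na(v))) next
      rng <- range(v)
      scores[s, ] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
    }
  }
  attr(scores, "method") <- "ssgsea"
  scores
}

#' Marker-mean signature scores
#'
#' MCPcounter-style abundance scoring: the score of a signature in a sample
#' is the arithmetic mean of the log2 expression of its member genes present
#' in the matrix. Requires normalized log-scale input so means are
#' comparable across samples.
#'
#' @param expr an [expression_matrix] in `"LOG2_QNORM"` state.
#' @param sets a [gene_set_collection] (e.g. TME or CAF marker panels).
#' @return numeric matrix, sets x samples, attribute `method = "marker_mean"`.
#' @export
marker_signature_scores <- function(expr, sets) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(sets, "gene_set_collection"))
  if (transform_state(expr) != "LOG2_QNORM")
    stop("marker_signature_scores expects LOG2_QNORM input", call. = FALSE)
  genes <- rownames(expr)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  vals <- unclass(expr)
  for (s in seq_along(sets)) {
    idx <- which(genes %in% sets[[s]])
    if (length(idx) == 0L) {
      warning(sprintf("signature '%s' has no genes in the matrix",
                      names(sets)[s]), call. = FALSE)
      next
    }
    scores[s, ] <- colMeans(vals[idx, , drop = FALSE])
  }
  attr(scores, "method") <- "marker_mean"
  scores
}

#' Write an enrichment (set x sample) score matrix as TSV
#'
#' @param scores matrix from [ssgsea_scores()] or
#'   [marker_signature_scores()].
#' @param path output path.
#' @export
write_enrichment_tsv <- function(scores, path) {
  d <- data.frame(set_name = rownames(scores), scores, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
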