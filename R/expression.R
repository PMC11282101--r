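#' Expression matrix container
#'
#' A thin S3 wrapper around a genes-by-samples numeric matrix that tracks the
#' transform state of the values: raw `"FPKM"` (non-negative, linear scale)
#' or `"LOG2_QNORM"` (log2(FPKM + 1), quantile normalized across samples).
#' Downstream operations check the state so that, e.g., enrichment scoring is
#' never run on un-normalized data by accident.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty rownames (gene IDs) and colnames (sample IDs).
#' @param transform_state `"FPKM"` or `"LOG2_QNORM"`.
#' @return an `expression_matrix` object (a classed matrix with a
#'   `transform_state` attribute).
#' @examples
#' m <- matrix(rexp(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' e <- expression_matrix(m)
#' transform_state(e)
#' @export
expression_matrix <- function(values, transform_state = c("FPKM", "LOG2_QNORM")) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (transform_state == "FPKM" && any(values < 0))
    stop("FPKM values must be non-negative", call. = FALSE)
  structure(values, transform_state = transform_state,
            class = c("expression_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
transform_state <- function(x) attr(x, "transform_state")

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), transform_state(x)))
  invisible(x)
}

#' Log-transform and quantile normalize an FPKM matrix
#'
#' Takes log2(FPKM + 1) and quantile normalizes the columns: every sample's
#' empirical distribution is replaced by the across-sample mean of the sorted
#' values (the reference distribution). Ties within a column receive the mean
#' of the reference values their rank range spans, so tied inputs stay tied.
#' The step is idempotent: normalizing an already-normalized matrix returns
#' it unchanged (up to the log transform, which is only applied once).
#'
#' @param expr an [expression_matrix] in `"FPKM"` state.
#' @return an [expression_matrix] in `"LOG2_QNORM"` state.
#' @export
log_quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (transform_state(expr) != "FPKM")
    stop("log_quantile_normalize expects an FPKM-state matrix", call. = FALSE)
  lg <- log2(unclass(expr) + 1)
  out <- quantile_normalize_columns(lg)
  expression_matrix(out, "LOG2_QNORM")
}

# Column quantile normalization with mean-of-reference tie handling.
quantile_normalize_columns <- function(m) {
  n <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    # a tie block spanning ranks lo..hi gets the mean of ref[lo..hi]
    lo <- rank(m[, j], ties.method = "min")
    hi <- rank(m[, j], ties.method = "max")
    cum <- cumsum(ref)
    out[, j] <- (cum[hi] - c(0, cum)[lo]) / (hi - lo + 1)
  }
  out
}

#' Read / write an expression matrix as TSV
#'
#' Plain tab-separated interchange: genes in rows (first column `gene_id`),
#' samples in columns, header row of sample IDs.
#'
#' @param path file path.
#' @param transform_state state flag recorded on read.
#' @return [expression_matrix] for the reader; invisible path for the writer.
#' @export
read_expression_tsv <- function(path, transform_state = "FPKM") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- genes
  expression_matrix(m, transform_state)
}

#' @rdname read_expression_tsv
#' @param expr an [expression_matrix].
#' @export
write_expression_tsv <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr), unclass(expr),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
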