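# Mutational-signature refitting on 96-trinucleotide-context profiles.

#' COSMIC 96-context labels
#'
#' The standard single-base-substitution context ordering:
#' `A[C>A]A, A[C>A]C, ..., T[T>G]T` — six pyrimidine substitution classes,
#' each with 16 flanking-base combinations, alphabetical throughout.
#'
#' @return character vector of length 96.
#' @export
cosmic_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f, r)
      paste0(f, "[", s, "]", r))))
  }))
}

# Lawson-Hanson active-set non-negative least squares: minimize
# ||A x - b||^2 subject to x >= 0. Small problems only (96 x <= 30).
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!passive & w > tol) && iter < 30 * n) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- drop(solve(crossprod(Ap) + 1e-12 * diag(sum(passive)),
                               crossprod(Ap, b)))
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Refit mutational-signature exposures by non-negative least squares
#'
#' Decomposes an observed 96-context mutation count profile over a signature
#' catalog: exposures minimize the squared reconstruction error subject to
#' non-negativity and are then normalized to sum to one. The cosine
#' similarity between the observed profile and its reconstruction is
#' reported as the quality-of-fit summary.
#'
#' @param profile numeric vector of 96 non-negative context counts (named
#'   by context or in COSMIC order).
#' @param catalog numeric matrix, 96 contexts x signatures; each column a
#'   probability distribution over contexts (sums to 1).
#' @return list with `exposures` (non-negative, sum 1, named by signature),
#'   `cosine` (reconstruction similarity), `reconstruction` (unit-sum
#'   96-vector).
#' @export
refit_signatures <- function(profile, catalog) {
  profile <- as.numeric(profile)
  catalog <- as.matrix(catalog)
  if (length(profile) != nrow(catalog))
    stop("profile length must match catalog rows", call. = FALSE)
  if (any(profile < 0) || any(!is.finite(profile)))
    stop("profile must be finite and non-negative", call. = FALSE)
  if (sum(profile) == 0) stop("all-zero mutation profile", call. = FALSE)
  colsums <- colSums(catalog)
  if (any(abs(colsums - 1) > 1e-6))
    stop("catalog columns must sum to 1", call. = FALSE)
  p <- profile / sum(profile)
  x <- nnls_fit(catalog, p)
  if (sum(x) == 0) stop("degenerate refit: all exposures zero", call. = FALSE)
  exposures <- x / sum(x)
  names(exposures) <- colnames(catalog)
  recon <- drop(catalog %*% exposures)
  recon <- recon / sum(recon)
  cosine <- sum(p * recon) / sqrt(sum(p^2) * sum(recon^2))
  list(exposures = exposures, cosine = cosine, reconstruction = recon)
}

#' Read / write 96-context mutation profiles as TSV
#'
#' Two columns: `context` (COSMIC ordering `A[C>A]A ... T[T>G]T`) and
#' `count`. The reader reorders rows into canonical COSMIC order.
#'
#' @param path file path.
#' @export
read_profile_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ctx <- cosmic_contexts()
  if (!all(ctx %in% d$context))
    stop("profile TSV must contain all 96 COSMIC contexts", call. = FALSE)
  stats::setNames(d$count[match(ctx, d$context)], ctx)
}

#' @rdname read_profile_tsv
#' @param profile named 96-vector of counts.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(context = names(profile), count = as.numeric(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
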