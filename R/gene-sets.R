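#' Gene set collection
#'
#' Named gene sets with a provenance label per set (`pathway`,
#' `TME-signature` or `CAF-signature`). Stored as a named list of character
#' vectors plus a parallel `source` attribute.
#'
#' @param sets named list of character vectors (member gene IDs).
#' @param source character vector of provenance labels, recycled to
#'   `length(sets)`.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets,
                                source = "pathway") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names", call. = FALSE)
  sets <- lapply(sets, function(s) {
    s <- as.character(s)
    if (length(s) == 0) stop("empty gene set", call. = FALSE)
    if (anyDuplicated(s)) stop("duplicate members within a set", call. = FALSE)
    s
  })
  source <- rep_len(as.character(source), length(sets))
  names(source) <- names(sets)
  structure(sets, source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "source")[i])
}

#' Read and write GMT gene-set files
#'
#' The GMT format is one set per line: name, description, then member genes,
#' tab-separated. The description field carries the provenance label.
#'
#' @param path file path.
#' @return [gene_set_collection] for the reader; invisible path for the
#'   writer.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  src <- vapply(parts, `[[`, "", 2L)
  src[!nzchar(src)] <- "pathway"
  gene_set_collection(sets, src)
}

#' @rdname read_gmt
#' @param sets a [gene_set_collection].
#' @export
write_gmt <- function(sets, path) {
  src <- attr(sets, "source")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], src[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
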