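#' Somatic variant filtering
#'
#' Applies the four-step functional-variant filter used for panel
#' sequencing calls. A record is kept iff it passes all of:
#' \enumerate{
#'   \item at least 5 variant-supporting reads AND variant allele frequency
#'     at least 5\% (both inclusive),
#'   \item population frequency (the pre-annotated maximum over
#'     1000 Genomes / ExAC / GnomAD) at most 2\% (records with frequency
#'     strictly above 2\% are filtered),
#'   \item located in a coding (CDS) region,
#'   \item annotated as (likely/predicted) oncogenic.
#' }
#' A rejected record is attributed to the first criterion it fails, in the
#' order (i) to (iv), so the per-criterion tally is deterministic.
#'
#' @param records data.frame with columns `sample_id`, `gene`,
#'   `alt_read_count`, `vaf`, `population_frequency`, `in_cds`, `oncogenic`
#'   (extra columns pass through).
#' @return list with `kept` (data.frame of passing records), `rejected`
#'   (data.frame with a `rejected_by` column), and `tally` (named counts for
#'   criteria i-iv plus `kept`).
#' @export
filter_variants <- function(records) {
  req <- c("sample_id", "gene", "alt_read_count", "vaf",
           "population_frequency", "in_cds", "oncogenic")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing variant columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(records$alt_read_count) |
                 records$alt_read_count < 0 |
                 records$alt_read_count != round(records$alt_read_count) |
                 !is.finite(records$vaf) | records$vaf < 0 | records$vaf > 1 |
                 !is.finite(records$population_frequency) |
                 records$population_frequency < 0 |
                 records$population_frequency > 1 |
                 is.na(records$in_cds) | is.na(records$oncogenic))
  if (length(bad))
    stop("malformed variant record(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)

  fail_i <- records$alt_read_count < 5 | records$vaf < 0.05
  fail_ii <- records$population_frequency > 0.02
  fail_iii <- !records$in_cds
  fail_iv <- !records$oncogenic
  rejected_by <- rep(NA_character_, nrow(records))
  rejected_by[fail_iv] <- "iv"
  rejected_by[fail_iii] <- "iii"
  rejected_by[fail_ii] <- "ii"
  rejected_by[fail_i] <- "i"

  keep <- is.na(rejected_by)
  tally <- c(i = sum(rejected_by == "i", na.rm = TRUE),
             ii = sum(rejected_by == "ii", na.rm = TRUE),
             iii = sum(rejected_by == "iii", na.rm = TRUE),
             iv = sum(rejected_by == "iv", na.rm = TRUE),
             kept = sum(keep))
  rej <- records[!keep, , drop = FALSE]
  if (nrow(rej)) rej$rejected_by <- rejected_by[!keep]
  else rej$rejected_by <- character(0)
  list(kept = records[keep, , drop = FALSE], rejected = rej, tally = tally)
}

#' Read a variant table from a VCF-export-style TSV
#'
#' Tolerant reader for tab-separated variant tables: a `column_map` renames
#' arbitrary source columns onto the canonical fields expected by
#' [filter_variants()]. Logical fields accept 0/1, TRUE/FALSE, yes/no.
#'
#' @param path TSV path.
#' @param column_map named character vector, `canonical = source`;
#'   canonical names already present pass through unmapped.
#' @return data.frame of variant records.
#' @export
read_variant_tsv <- function(path, column_map = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(d))
        stop("mapped column not found: ", src, call. = FALSE)
      names(d)[names(d) == src] <- canon
    }
  }
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    tolower(as.character(x)) %in% c("1", "true", "yes", "y")
  }
  for (cl in c("in_cds", "oncogenic"))
    if (cl %in% names(d)) d[[cl]] <- to_logical(d[[cl]])
  d
}
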