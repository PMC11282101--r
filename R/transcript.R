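# Exon-skipping transcript utilities and in-silico PCR. Used for the
# METex14 sanity check: RT-PCR across the exon-13/15 junction yields a
# shorter amplicon when exon 14 is skipped (246 bp wild-type vs 106 bp
# skipped for the canonical primer pair).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param seq character scalar of A/C/G/T.
#' @return character scalar.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Transcript model for an exon-skipping event
#'
#' Describes a spliced transcript as an ordered run of exons, the index of
#' the exon subject to skipping, and a primer pair anchored in the flanking
#' exons (forward primer in an exon upstream of the skipped one, reverse
#' primer downstream, given 5'->3' on the opposite strand). Exon sequences
#' are generated at construction (deterministic given `seed`) unless
#' supplied.
#'
#' @param exon_lengths integer vector of exon lengths (nt), in order.
#' @param skipped_exon_index which exon is skipped (strictly between the
#'   primer exons).
#' @param fwd_exon,rev_exon exon indices carrying the primers (defaults:
#'   immediately flanking exons).
#' @param fwd_offset 0-based offset of the forward primer start within its
#'   exon; the reverse primer binding site ends `rev_margin` nt before its
#'   exon's 3' end.
#' @param primer_length forward/reverse primer lengths (nt), recycled to 2.
#' @param rev_margin nt between the reverse primer site end and its exon
#'   end.
#' @param exon_seqs optional character vector of explicit exon sequences
#'   (overrides `exon_lengths`).
#' @param seed seed for random exon sequence generation.
#' @return a `transcript_model` list with `exon_seqs`, `exon_lengths`,
#'   `skipped_exon_index`, `primer_fwd`, `primer_rev`.
#' @export
transcript_model <- function(exon_lengths, skipped_exon_index,
                             fwd_exon = skipped_exon_index - 1L,
                             rev_exon = skipped_exon_index + 1L,
                             fwd_offset = 0L, primer_length = c(21L, 20L),
                             rev_margin = 0L, exon_seqs = NULL, seed = 1) {
  if (!is.null(exon_seqs)) exon_lengths <- nchar(exon_seqs)
  n_exon <- length(exon_lengths)
  if (any(exon_lengths < 0)) stop("negative exon length", call. = FALSE)
  if (skipped_exon_index < 1 || skipped_exon_index > n_exon)
    stop("skipped exon outside transcript", call. = FALSE)
  if (!(fwd_exon < skipped_exon_index && skipped_exon_index < rev_exon))
    stop("skipped exon must lie strictly between the primer exons",
         call. = FALSE)
  if (fwd_exon < 1 || rev_exon > n_exon)
    stop("primer exon outside transcript", call. = FALSE)
  primer_length <- rep_len(as.integer(primer_length), 2L)
  if (fwd_offset + primer_length[1] > exon_lengths[fwd_exon])
    stop("forward primer does not fit inside its exon", call. = FALSE)
  if (rev_margin + primer_length[2] > exon_lengths[rev_exon])
    stop("reverse primer does not fit inside its exon", call. = FALSE)
  if (is.null(exon_seqs)) {
    exon_seqs <- with_local_seed(seed,
      vapply(exon_lengths, random_dna, ""))
  }
  fwd_site <- substr(exon_seqs[fwd_exon], fwd_offset + 1L,
                     fwd_offset + primer_length[1])
  rev_site_start <- exon_lengths[rev_exon] - rev_margin - primer_length[2] + 1L
  rev_site <- substr(exon_seqs[rev_exon], rev_site_start,
                     rev_site_start + primer_length[2] - 1L)
  structure(list(exon_seqs = exon_seqs,
                 exon_lengths = as.integer(exon_lengths),
                 skipped_exon_index = as.integer(skipped_exon_index),
                 fwd_exon = as.integer(fwd_exon),
                 rev_exon = as.integer(rev_exon),
                 primer_fwd = fwd_site,
                 primer_rev = reverse_complement(rev_site)),
            class = "transcript_model")
}

#' Wild-type and exon-skipped transcript sequences
#'
#' @param model a [transcript_model].
#' @return list with `wildtype` and `skipped` sequences; `skipped` is the
#'   wild-type with the skipped exon excised.
#' @export
build_skipping_pair <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  wt <- paste(model$exon_seqs, collapse = "")
  sk <- paste(model$exon_seqs[-model$skipped_exon_index], collapse = "")
  list(wildtype = wt, skipped = sk)
}

#' In-silico PCR amplicon length
#'
#' Locates the forward primer on the template's forward strand and the
#' reverse primer's binding site (its reverse complement) downstream, and
#' returns the amplicon length: the count of bases from the first base of
#' the forward primer match through the last base of the reverse primer
#' binding site, inclusive — the standard amplicon-size convention with
#' both primer footprints counted.
#'
#' @param template nucleotide string (forward sense, 5'->3').
#' @param fwd forward primer (5'->3', matches the template verbatim).
#' @param rev reverse primer (5'->3' on the opposite strand; its reverse
#'   complement is matched on the template).
#' @return integer amplicon length in bp, or `NA` (with a warning) when a
#'   primer site is absent.
#' @export
insilico_pcr <- function(template, fwd, rev) {
  find_all <- function(pattern) {
    m <- gregexpr(pattern, template, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  fpos <- find_all(fwd)
  if (length(fpos) == 0L) {
    warning("forward primer not found: no amplicon", call. = FALSE)
    return(NA_integer_)
  }
  if (length(fpos) > 1L)
    stop("forward primer matches the template more than once", call. = FALSE)
  rsite <- reverse_complement(rev)
  rpos <- find_all(rsite)
  rpos <- rpos[rpos >= fpos]          # only sites downstream of fwd
  if (length(rpos) == 0L) {
    warning("reverse primer site not found downstream: no amplicon",
            call. = FALSE)
    return(NA_integer_)
  }
  if (length(rpos) > 1L)
    stop("reverse primer site matches more than once downstream",
         call. = FALSE)
  end <- rpos + nchar(rsite) - 1L
  as.integer(end - fpos + 1L)
}

#' Default METex14-style three-exon fixture
#'
#' A synthetic exon-13/14/15 transcript model whose wild-type amplicon is
#' 246 bp with a 140-nt internal (skipped) exon, so the skipped isoform
#' amplicon is 106 bp. The 140-nt internal exon length is implied by the
#' amplicon arithmetic (246 - 106); primer lengths match the published
#' assay (21-nt forward, 20-nt reverse).
#'
#' @param seed seed for exon sequence generation.
#' @return a [transcript_model].
#' @export
metex14_transcript_model <- function(seed = 1) {
  # amplicon = fwd-exon tail (56) + internal exon (140) + rev-exon head (50)
  transcript_model(exon_lengths = c(80L, 140L, 50L),
                   skipped_exon_index = 2L,
                   fwd_offset = 80L - 56L,
                   primer_length = c(21L, 20L),
                   rev_margin = 0L, seed = seed)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
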