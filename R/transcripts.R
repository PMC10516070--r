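#' Construct a transcript model
#'
#' A transcript model records the exon geometry, coding span and strand of a
#' single (MANE-like) transcript. All coordinates are genomic, 0-based
#' half-open. The transcription start site (TSS) is derived from the exon
#' list: the 5'-most transcribed base for the strand.
#'
#' @param transcript_id,gene_symbol identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with integer columns `start`, `end` (0-based
#'   half-open), sorted, non-overlapping.
#' @param cds_start,cds_end genomic coordinates bounding the coding span
#'   (half-open). Use `NA` for a non-coding transcript.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand,
                             exons, cds_start = NA, cds_end = NA) {
  .stopifnot_scalar_chr(transcript_id, "transcript_id")
  .stopifnot_scalar_chr(chrom, "chrom")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) stop("empty exon interval")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons must be sorted and non-overlapping")
  }
  has_cds <- !is.na(cds_start) && !is.na(cds_end)
  if (has_cds) {
    cds_start <- as.integer(cds_start)
    cds_end <- as.integer(cds_end)
    if (cds_end <= cds_start) stop("empty CDS span")
    if (cds_start < exons$start[1] || cds_end > exons$end[nrow(exons)]) {
      stop("CDS span outside transcript span")
    }
  } else {
    cds_start <- NA_integer_
    cds_end <- NA_integer_
  }
  tss <- if (strand == "+") exons$start[1] else exons$end[nrow(exons)] - 1L
  structure(
    list(
      transcript_id = transcript_id, gene_symbol = gene_symbol,
      chrom = chrom, strand = strand, exons = exons,
      cds_start = cds_start, cds_end = cds_end, tss = tss
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else {
    sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  }
  cat(sprintf(
    "<transcript_model> %s (%s) %s:%s %d exon(s), %s, TSS %d\n",
    x$transcript_id, x$gene_symbol, x$chrom, x$strand, nrow(x$exons), cds,
    x$tss
  ))
  invisible(x)
}

# Genomic positions (0-based) of transcribed bases in transcription order.
.tx_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
    seq.int(tx$exons$start[i], tx$exons$end[i] - 1L)
  }), use.names = FALSE)
  if (tx$strand == "-") pos <- rev(pos)
  pos
}

#' Spliced transcript sequence
#'
#' Splices the exons of a transcript out of a genome and returns the mRNA
#' sequence in 5'->3' orientation (reverse-complemented for minus-strand
#' transcripts), together with the 0-based offset of the CDS start codon
#' within the spliced sequence and a per-base map back to genomic
#' coordinates.
#'
#' @param tx a [transcript_model()].
#' @param genome named character vector of chromosome sequences (DNA).
#' @return object of class `spliced_tx` with elements `sequence`,
#'   `cds_offset`, `cds_length`, `genomic_pos` (integer vector, one genomic
#'   coordinate per transcript base), `transcript_id`, `chrom`, `strand`.
#' @export
spliced_transcript <- function(tx, genome) {
  stopifnot(inherits(tx, "transcript_model"))
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", tx$chrom, " not in genome")
  chrom_seq <- .norm_dna(chrom_seq)
  pos <- .tx_positions(tx)
  bases <- substring(chrom_seq, pos + 1L, pos + 1L)
  if (tx$strand == "-") {
    bases <- chartr("ACGT", "TGCA", bases)
  }
  seq <- paste(bases, collapse = "")
  cds_offset <- NA_integer_
  cds_length <- NA_integer_
  if (!is.na(tx$cds_start)) {
    cds_first_genomic <- if (tx$strand == "+") tx$cds_start else tx$cds_end - 1L
    cds_offset <- match(cds_first_genomic, pos) - 1L
    if (is.na(cds_offset)) stop("CDS start is not an exonic base")
    ov <- pmin(tx$exons$end, tx$cds_end) - pmax(tx$exons$start, tx$cds_start)
    cds_length <- sum(ov[ov > 0])
  }
  structure(
    list(
      sequence = seq, cds_offset = cds_offset, cds_length = cds_length,
      genomic_pos = pos, transcript_id = tx$transcript_id,
      chrom = tx$chrom, strand = tx$strand
    ),
    class = "spliced_tx"
  )
}

#' Map a genomic position to a transcript index
#'
#' @param stx a [spliced_transcript()] object.
#' @param gpos genomic position (0-based).
#' @return 0-based index into `stx$sequence`, or `NA` if the position is not
#'   exonic for this transcript.
#' @export
genomic_to_transcript <- function(stx, gpos) {
  match(as.integer(gpos), stx$genomic_pos) - 1L
}
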