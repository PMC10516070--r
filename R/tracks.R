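# Overlay-based annotations: IRES / miRNA-site / dORF overlap, RBP
# binding-loss calls, TFBS footprint filtering and per-TF binding-change
# score aggregation.

.TRACKS <- c("IRES", "miRNA", "dORF", "RBP", "TFBS")

#' Elements of one functional track overlapping a variant
#'
#' Any-overlap rule: an element is reported when its interval overlaps the
#' variant's reference span (for indels, any reference base).
#'
#' @param chrom,pos,ref variant chromosome, 0-based position and reference
#'   allele.
#' @param elements data frame of track elements with columns `chrom`,
#'   `start`, `end` (0-based half-open), `track`, plus any attribute
#'   columns.
#' @param track track name to restrict to (one of IRES, miRNA, dORF, RBP,
#'   TFBS), or `NULL` for all tracks.
#' @return the overlapping rows of `elements`.
#' @export
overlap_track <- function(chrom, pos, ref, elements, track = NULL) {
  pos <- as.integer(pos)
  span_end <- pos + max(1L, nchar(ref))
  keep <- elements$chrom == chrom &
    elements$start < span_end & pos < elements$end
  if (!is.null(track)) keep <- keep & elements$track == track
  elements[keep, , drop = FALSE]
}

#' Benign-score exclusion for IRES and miRNA overlaps
#'
#' Overlap with an IRES or miRNA site is common, so overlapping variants
#' whose scores support a benign classification are excluded: CADD PHRED
#' <= 22.7 or PhyloP <= 1.879. A missing score cannot trigger its
#' comparison (exclusion requires positive evidence of benignity).
#'
#' @param cadd,phylop scores (may be `NA`).
#' @param benign_cadd,benign_phylop thresholds.
#' @return `TRUE` when the variant should be excluded.
#' @export
benign_score_exclusion <- function(cadd, phylop,
                                   benign_cadd = 22.7,
                                   benign_phylop = 1.879) {
  (!is.na(cadd) & cadd <= benign_cadd) |
    (!is.na(phylop) & phylop <= benign_phylop)
}

#' RNA-binding-protein binding-loss call
#'
#' A site qualifies as a binding loss when its reference-allele affinity is
#' at least 0.1 and the alternate/reference affinity ratio falls below 1/3.
#' A reference affinity of exactly 0 leaves the ratio undefined and the
#' site is treated as inactive (no loss).
#'
#' @param ref_affinity,alt_affinity unitless affinities in \[0, 1\].
#' @return list with `ref_affinity`, `alt_affinity`, `loss`.
#' @export
rbp_loss <- function(ref_affinity, alt_affinity) {
  stopifnot(ref_affinity >= 0, ref_affinity <= 1,
            alt_affinity >= 0, alt_affinity <= 1)
  loss <- ref_affinity >= 0.1 &&
    ref_affinity > 0 &&
    alt_affinity / ref_affinity < 1 / 3
  list(ref_affinity = ref_affinity, alt_affinity = alt_affinity,
       loss = loss)
}

#' Aggregate per-model TF binding-change predictions for one variant
#'
#' For each transcription factor the per-model predicted binding changes
#' are averaged into one score, Score = (Sigma A_1..A_N) / N. Scores
#' >= `gain_cutoff` (0.04) are classed as predicted gains and <=
#' `-gain_cutoff` as predicted losses. Mean scores over the loss-classified,
#' gain-classified and all TFs are reported; the variant is retained when
#' the mean loss score is <= `retain_cutoff` (-0.4).
#'
#' @param predictions data frame with columns `tf_name` and `value` (one
#'   row per model prediction).
#' @param gain_cutoff,loss_cutoff classification thresholds (default
#'   +/-0.04).
#' @param retain_cutoff retention threshold on the mean loss score
#'   (default -0.4).
#' @return list with `per_tf_score` (named numeric), `losses`, `gains`
#'   (named numeric subsets), `mean_loss_score`, `mean_gain_score`,
#'   `mean_total_score`, and `retained`.
#' @export
fabian_aggregate <- function(predictions, gain_cutoff = 0.04,
                             loss_cutoff = -0.04, retain_cutoff = -0.4) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    return(list(per_tf_score = numeric(), losses = numeric(),
                gains = numeric(), mean_loss_score = NA_real_,
                mean_gain_score = NA_real_, mean_total_score = NA_real_,
                retained = FALSE))
  }
  per_tf <- vapply(split(predictions$value, predictions$tf_name),
                   mean, numeric(1))
  losses <- per_tf[per_tf <= loss_cutoff]
  gains <- per_tf[per_tf >= gain_cutoff]
  mean_loss <- if (length(losses)) mean(losses) else NA_real_
  list(
    per_tf_score = per_tf,
    losses = losses,
    gains = gains,
    mean_loss_score = mean_loss,
    mean_gain_score = if (length(gains)) mean(gains) else NA_real_,
    mean_total_score = mean(per_tf),
    retained = !is.na(mean_loss) && mean_loss <= retain_cutoff
  )
}

#' Core-DHS footprint filter for promoter variants
#'
#' A promoter variant is kept for TF binding-change scoring only when it
#' lies inside at least one TF-binding footprint flagged as falling within
#' the core region of a DNase I hypersensitive peak.
#'
#' @param chrom,pos,ref variant fields.
#' @param footprints element data frame with a logical `in_core_dhs`
#'   column.
#' @return `TRUE` to keep the variant.
#' @export
tfbs_core_dhs_filter <- function(chrom, pos, ref, footprints) {
  hit <- overlap_track(chrom, pos, ref, footprints, track = NULL)
  nrow(hit) > 0 && any(as.logical(hit$in_core_dhs))
}

#' Does a variant hit the start or stop codon of a dORF?
#'
#' Downstream ORFs (3'UTR ORFs with translational evidence) are only
#' flagged when the variant disrupts their start or stop codon
#' sub-interval. When the element carries no sub-interval annotation the
#' whole interval is used, with a warning.
#'
#' @param chrom,pos,ref variant fields.
#' @param dorf one-row element data frame; sub-intervals are read from
#'   columns `start_codon_start`, `start_codon_end`, `stop_codon_start`,
#'   `stop_codon_end` (0-based half-open).
#' @return logical.
#' @export
dorf_boundary_hit <- function(chrom, pos, ref, dorf) {
  pos <- as.integer(pos)
  span_end <- pos + max(1L, nchar(ref))
  if (dorf$chrom != chrom) return(FALSE)
  has_sub <- all(c("start_codon_start", "start_codon_end",
                   "stop_codon_start", "stop_codon_end") %in% names(dorf)) &&
    !any(is.na(c(dorf$start_codon_start, dorf$stop_codon_start)))
  if (!has_sub) {
    warning("dORF element without start/stop sub-intervals; ",
            "falling back to whole-interval overlap")
    return(dorf$start < span_end && pos < dorf$end)
  }
  (dorf$start_codon_start < span_end && pos < dorf$start_codon_end) ||
    (dorf$stop_codon_start < span_end && pos < dorf$stop_codon_end)
}
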