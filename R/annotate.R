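# End-to-end annotation: region assignment + sequence effects + track
# overlays, producing the flat annotated-variant table consumed by
# prioritize_variants().

# Transcript-space view of a (VCF-style, anchored) genomic variant:
# position of the first reference base mapped into the spliced sequence,
# alleles reverse-complemented for minus-strand transcripts. Returns NULL
# when any reference base is not exonic for the transcript.
.tx_space_variant <- function(stx, pos, ref, alt) {
  lr <- nchar(ref)
  gpos <- seq.int(pos, pos + lr - 1L)
  tp <- genomic_to_transcript(stx, gpos)
  if (any(is.na(tp))) return(NULL)
  if (stx$strand == "+") {
    list(pos = tp[1], ref = .norm_dna(ref), alt = .norm_dna(alt))
  } else {
    list(pos = tp[lr], ref = .revcomp(ref), alt = .revcomp(alt))
  }
}

#' Annotate a variant table against regions, sequences and tracks
#'
#' Runs the full annotation layer for each variant: region classification
#' (including deep-intronic status), 5'UTR translational consequences and
#' Kozak -3 disruption on the spliced transcript sequence, 3'UTR
#' polyA-signal scanning, overlap with IRES/miRNA/dORF/RBP tracks (with
#' their track-specific sub-filters), and TFBS core-DHS filtering plus
#' per-TF binding-change aggregation. Scores already present on the input
#' (`spliceai_max`, `cadd_phred`, `phylop`, `clinvar_status`, frequency
#' fields) are carried through untouched.
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#'   (0-based), `ref`, `alt` plus optional score columns.
#' @param transcripts list of [transcript_model()] objects.
#' @param regions near-coding region data frame (from
#'   [build_near_coding_regions()]).
#' @param genome named character vector of chromosome sequences.
#' @param track_elements data frame of functional track elements (column
#'   `track` in IRES/miRNA/dORF/RBP/TFBS; RBP rows carry `ref_affinity`,
#'   `alt_affinity`; TFBS rows carry `in_core_dhs`; dORF rows carry codon
#'   sub-intervals), or `NULL`.
#' @param tf_predictions data frame (`variant_id`, `tf_name`, `value`)
#'   of per-model TF binding-change predictions, or `NULL`.
#' @return annotated-variant data frame ready for [prioritize_variants()].
#' @export
annotate_variants <- function(variants, transcripts, regions, genome,
                              track_elements = NULL,
                              tf_predictions = NULL) {
  tx_by_id <- stats::setNames(transcripts,
                              vapply(transcripts, `[[`, "", "transcript_id"))
  stx_cache <- new.env(parent = emptyenv())
  get_stx <- function(tid) {
    if (is.null(stx_cache[[tid]])) {
      stx_cache[[tid]] <- spliced_transcript(tx_by_id[[tid]], genome)
    }
    stx_cache[[tid]]
  }
  n <- nrow(variants)
  out <- variants
  out$region_classes <- character(n)
  out$deep_intronic <- logical(n)
  out$transcript_id <- character(n)
  out$gene_symbol <- if ("gene_symbol" %in% names(variants)) {
    variants$gene_symbol
  } else {
    character(n)
  }
  flags <- c("uorf_high_impact", "kozak_hit", "polya_hit", "ires_hit",
             "mirna_hit", "rbp_loss_hit", "dorf_hit", "tfbs_loss_hit")
  for (f in flags) out[[f]] <- logical(n)

  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]
    pos <- as.integer(variants$pos[i])
    ref <- .norm_dna(variants$ref[i])
    alt <- .norm_dna(variants$alt[i])
    ra <- assign_region(chrom, pos, ref, regions)
    out$region_classes[i] <- paste(ra$region_classes, collapse = ",")
    out$deep_intronic[i] <- ra$deep_intronic
    if (length(ra$transcript_ids) > 0) {
      out$transcript_id[i] <- ra$transcript_ids[1]
      out$gene_symbol[i] <- ra$hits$gene_symbol[1]
    }
    if (length(ra$region_classes) == 0L) next

    # 5'UTR sequence effects on the spliced transcript of the first
    # transcript carrying a five_utr hit
    if ("five_utr" %in% ra$region_classes) {
      tid <- ra$hits$transcript_id[ra$hits$region_class == "five_utr"][1]
      stx <- get_stx(tid)
      tv <- .tx_space_variant(stx, pos, ref, alt)
      if (!is.null(tv)) {
        cons <- annotate_five_prime(stx, tv$pos, tv$ref, tv$alt)
        out$uorf_high_impact[i] <- any(high_impact_utr_filter(cons))
        out$kozak_hit[i] <-
          kozak_minus3_disruption(stx, tv$pos, tv$ref, tv$alt)
      }
    }
    # 3'UTR polyA scan
    if ("three_utr" %in% ra$region_classes) {
      tid <- ra$hits$transcript_id[ra$hits$region_class == "three_utr"][1]
      stx <- get_stx(tid)
      tv <- .tx_space_variant(stx, pos, ref, alt)
      if (!is.null(tv)) {
        utr3_offset <- stx$cds_offset + stx$cds_length
        upos <- tv$pos - utr3_offset
        if (upos >= 0) {
          utr3 <- substr(stx$sequence, utr3_offset + 1L,
                         nchar(stx$sequence))
          pa <- polya_disruption(utr3, upos, tv$ref, tv$alt)
          out$polya_hit[i] <- pa$disrupted
        }
      }
    }
    # track overlays
    if (!is.null(track_elements) && nrow(track_elements) > 0) {
      if ("five_utr" %in% ra$region_classes) {
        out$ires_hit[i] <-
          nrow(overlap_track(chrom, pos, ref, track_elements, "IRES")) > 0
      }
      if ("three_utr" %in% ra$region_classes) {
        out$mirna_hit[i] <-
          nrow(overlap_track(chrom, pos, ref, track_elements, "miRNA")) > 0
        rbp <- overlap_track(chrom, pos, ref, track_elements, "RBP")
        if (nrow(rbp) > 0) {
          out$rbp_loss_hit[i] <- any(vapply(seq_len(nrow(rbp)), function(j) {
            rbp_loss(rbp$ref_affinity[j], rbp$alt_affinity[j])$loss
          }, logical(1)))
        }
        dorfs <- overlap_track(chrom, pos, ref, track_elements, "dORF")
        if (nrow(dorfs) > 0) {
          out$dorf_hit[i] <- any(vapply(seq_len(nrow(dorfs)), function(j) {
            dorf_boundary_hit(chrom, pos, ref, dorfs[j, , drop = FALSE])
          }, logical(1)))
        }
      }
      if ("promoter" %in% ra$region_classes) {
        fp <- track_elements[track_elements$track == "TFBS", , drop = FALSE]
        in_core <- tfbs_core_dhs_filter(chrom, pos, ref, fp)
        if (in_core && !is.null(tf_predictions)) {
          preds <- tf_predictions[
            tf_predictions$variant_id == variants$variant_id[i], ,
            drop = FALSE
          ]
          out$tfbs_loss_hit[i] <- fabian_aggregate(preds)$retained
        }
      }
    }
  }
  out
}
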