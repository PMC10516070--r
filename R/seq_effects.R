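# 5'UTR translational-effect annotation and 3'UTR polyadenylation-signal
# scanning. All sequence logic runs on the spliced transcript sequence in
# the DNA alphabet (U is normalised to T), 5'->3'.

#' Kozak context strength of an AUG
#'
#' Classified from positions -3 and +4 relative to the AUG (the A of AUG is
#' +1): strong when -3 is a purine (A/G) AND +4 is G; moderate when exactly
#' one of the two holds; weak otherwise. A position that falls off either
#' end of the sequence counts as failing its condition.
#'
#' @param seq nucleotide string.
#' @param aug_index 0-based index of the A of an AUG within `seq`.
#' @return one of `"strong"`, `"moderate"`, `"weak"`.
#' @export
kozak_strength <- function(seq, aug_index) {
  seq <- .norm_dna(seq)
  aug_index <- as.integer(aug_index)
  if (aug_index < 0 ||
      substr(seq, aug_index + 1L, aug_index + 3L) != "ATG") {
    stop("no AUG at index ", aug_index)
  }
  m3 <- if (aug_index >= 3L) {
    substr(seq, aug_index - 2L, aug_index - 2L)
  } else {
    ""
  }
  p4 <- substr(seq, aug_index + 4L, aug_index + 4L)
  ok_m3 <- m3 %in% c("A", "G")
  ok_p4 <- identical(p4, "G")
  if (ok_m3 && ok_p4) "strong" else if (ok_m3 || ok_p4) "moderate" else "weak"
}

# First in-frame stop codon of an ORF starting at `i` (0-based) that lies
# entirely 5' of `cds_offset`. Returns the 0-based codon start, or NA.
.first_utr_stop <- function(seq, i, cds_offset) {
  j <- i + 3L
  while (j + 3L <= cds_offset) {
    if (substr(seq, j + 1L, j + 3L) %in% .STOP_CODONS) return(j)
    j <- j + 3L
  }
  NA_integer_
}

# Classify the ORF opened by an AUG at `i` relative to the CDS start:
# uORF (terminates before the CDS), or an overlapping ORF (in/out of frame).
.classify_uaug <- function(seq, i, cds_offset) {
  stop_j <- .first_utr_stop(seq, i, cds_offset)
  if (!is.na(stop_j)) {
    list(outcome = "uORF", stop = stop_j)
  } else if ((cds_offset - i) %% 3L == 0L) {
    list(outcome = "inFrame_oORF", stop = NA_integer_)
  } else {
    list(outcome = "outOfFrame_oORF", stop = NA_integer_)
  }
}

# All AUG start positions (0-based) strictly 5' of cds_offset.
.find_uaugs <- function(seq, cds_offset) {
  if (cds_offset == 0L) return(integer())
  hits <- gregexpr("(?=ATG)", substr(seq, 1L, cds_offset + 2L),
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  hits <- as.integer(hits) - 1L
  hits[hits < cds_offset]
}

# Position correspondence across an edit replacing ref (length lr) at `pos`
# with alt (length la). Returns NA for positions inside the edited window.
.ref2alt <- function(p, pos, lr, la) {
  ifelse(p < pos, p, ifelse(p >= pos + lr, p + la - lr, NA_integer_))
}
.alt2ref <- function(p, pos, lr, la) {
  ifelse(p < pos, p, ifelse(p >= pos + la, p - la + lr, NA_integer_))
}

#' Annotate the 5'UTR translational consequences of a variant
#'
#' Compares the full complement of upstream AUGs, their reading frames and
#' in-frame stops between the reference and alternate spliced sequences and
#' reports:
#' \describe{
#'   \item{uAUG_gain}{an AUG present only in the alternate sequence;
#'     Kozak strength taken from the alternate context.}
#'   \item{uAUG_loss}{an AUG present only in the reference; Kozak strength
#'     from the reference context.}
#'   \item{uSTOP_loss}{the stop codon of a reference uORF is disrupted by
#'     the variant; the outcome records whether another in-frame stop
#'     before the CDS remains (still a uORF) or not (now an overlapping
#'     ORF).}
#'   \item{uFrameshift}{a non-3n indel strictly inside the body of a
#'     reference uORF; the outcome is recomputed on the alternate
#'     sequence.}
#' }
#' Each consequence carries `orf_outcome` (`uORF`, `inFrame_oORF`,
#' `outOfFrame_oORF`), the `kozak` strength of the relevant AUG, and
#' `uaug_position` (0-based index within the respective sequence).
#'
#' @param stx a [spliced_transcript()]-style object (any list with
#'   `sequence` and `cds_offset`).
#' @param pos 0-based index of the variant within the spliced sequence.
#' @param ref,alt reference/alternate alleles (transcript orientation).
#' @return data frame with columns `effect_class`, `orf_outcome`, `kozak`,
#'   `uaug_position`; zero rows when the variant does not touch the 5'UTR.
#' @export
annotate_five_prime <- function(stx, pos, ref, alt) {
  seq <- .norm_dna(stx$sequence)
  cds_offset <- stx$cds_offset
  if (is.na(cds_offset)) stop("transcript has no CDS")
  ref <- .norm_dna(ref)
  alt <- .norm_dna(alt)
  pos <- as.integer(pos)
  lr <- nchar(ref)
  la <- nchar(alt)
  empty <- data.frame(
    effect_class = character(), orf_outcome = character(),
    kozak = character(), uaug_position = integer(),
    stringsAsFactors = FALSE
  )
  # scope: variant must start in the 5'UTR and not disturb the CDS AUG
  if (pos < 0 || pos >= cds_offset || pos + lr > cds_offset) return(empty)
  if (substr(seq, pos + 1L, pos + lr) != ref && lr > 0) {
    stop("reference allele does not match the transcript sequence")
  }
  alt_seq <- paste0(
    substr(seq, 1L, pos), alt,
    substr(seq, pos + lr + 1L, nchar(seq))
  )
  cds_offset_alt <- cds_offset + la - lr

  ref_augs <- .find_uaugs(seq, cds_offset)
  alt_augs <- .find_uaugs(alt_seq, cds_offset_alt)

  res <- list()
  add <- function(cls, outcome, kozak, at) {
    res[[length(res) + 1L]] <<- data.frame(
      effect_class = cls, orf_outcome = outcome, kozak = kozak,
      uaug_position = at, stringsAsFactors = FALSE
    )
  }

  # gains: alt AUGs with no AUG at the corresponding reference position
  for (a in alt_augs) {
    r <- .alt2ref(a, pos, lr, la)
    is_new <- is.na(r) || !(r %in% ref_augs)
    if (is_new) {
      cl <- .classify_uaug(alt_seq, a, cds_offset_alt)
      add("uAUG_gain", cl$outcome, kozak_strength(alt_seq, a), a)
    }
  }
  # losses: ref AUGs with no AUG at the corresponding alternate position
  for (r in ref_augs) {
    a <- .ref2alt(r, pos, lr, la)
    lost <- is.na(a) || !(a %in% alt_augs)
    if (lost) {
      cl <- .classify_uaug(seq, r, cds_offset)
      add("uAUG_loss", cl$outcome, kozak_strength(seq, r), r)
    }
  }
  frameshifting <- (la - lr) %% 3L != 0L
  # stop-loss / frameshift over conserved reference uORFs
  for (r in ref_augs) {
    a <- .ref2alt(r, pos, lr, la)
    if (is.na(a) || !(a %in% alt_augs)) next
    cl_ref <- .classify_uaug(seq, r, cds_offset)
    if (cl_ref$outcome != "uORF") next
    s <- cl_ref$stop
    overlaps_stop <- pos < s + 3L && pos + max(1L, lr) > s
    if (overlaps_stop) {
      cl_alt <- .classify_uaug(alt_seq, a, cds_offset_alt)
      # disrupted only if the corresponding alternate codon is no longer
      # the terminating stop of this uORF
      still_same_stop <- !is.na(cl_alt$stop) &&
        identical(.alt2ref(cl_alt$stop, pos, lr, la), s)
      if (!still_same_stop) {
        add("uSTOP_loss", cl_alt$outcome, kozak_strength(alt_seq, a), a)
      }
    } else if (frameshifting && pos >= r + 3L && pos + lr <= s) {
      # non-3n indel strictly inside the uORF body
      cl_alt <- .classify_uaug(alt_seq, a, cds_offset_alt)
      add("uFrameshift", cl_alt$outcome, kozak_strength(alt_seq, a), a)
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' High-impact filter for 5'UTR consequences
#'
#' Retains the consequence classes with the highest likelihood of disrupting
#' translation of the main ORF:
#' uAUG gain creating an overlapping ORF with a strong or moderate Kozak;
#' uSTOP loss with no remaining stop before the CDS (an overlapping ORF) and
#' strong or moderate Kozak; uAUG loss with a strong Kozak; uFrameshift
#' resulting in an overlapping ORF with strong or moderate Kozak.
#'
#' @param consequences data frame from [annotate_five_prime()].
#' @return logical vector, one element per row.
#' @export
high_impact_utr_filter <- function(consequences) {
  if (nrow(consequences) == 0L) return(logical())
  oorf <- consequences$orf_outcome %in% c("inFrame_oORF", "outOfFrame_oORF")
  sm <- consequences$kozak %in% c("strong", "moderate")
  (consequences$effect_class == "uAUG_gain" & oorf & sm) |
    (consequences$effect_class == "uSTOP_loss" & oorf & sm) |
    (consequences$effect_class == "uAUG_loss" &
       consequences$kozak == "strong") |
    (consequences$effect_class == "uFrameshift" & oorf & sm)
}

#' Kozak -3 position disruption
#'
#' `TRUE` when a substitution changes the base exactly 3 positions 5' of the
#' CDS AUG (the R of the gccRccAUGG motif) from a purine (A/G) to a
#' pyrimidine (C/T). The rule covers single-base substitutions only.
#'
#' @param stx spliced transcript object (`sequence`, `cds_offset`).
#' @param pos 0-based transcript index of the variant.
#' @param ref,alt alleles (transcript orientation).
#' @return logical.
#' @export
kozak_minus3_disruption <- function(stx, pos, ref, alt) {
  if (is.na(stx$cds_offset)) return(FALSE)
  ref <- .norm_dna(ref)
  alt <- .norm_dna(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) return(FALSE)
  as.integer(pos) == stx$cds_offset - 3L &&
    ref %in% c("A", "G") && alt %in% c("C", "T")
}

.PAS_CANONICAL <- c("AATAAA", "ATTAAA")
.PAS_RESCUE <- c(
  "AATAAA", "ATTAAA", "AGTAAA", "TATAAA", "CATAAA", "GATAAA",
  "AATATA", "AATACA", "AATAGA", "AAAAAG", "ACTAAA", "AAAAAA"
)

# All start positions (0-based) of canonical polyA signal hexamers.
.pas_sites <- function(seq) {
  out <- integer()
  for (m in .PAS_CANONICAL) {
    h <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
    if (h[1] != -1L) out <- c(out, as.integer(h) - 1L)
  }
  sort(unique(out))
}

#' Polyadenylation-signal disruption in a 3'UTR
#'
#' Scans the 3'UTR sequence for canonical polyA signal hexamers (AATAAA,
#' ATTAAA in the DNA alphabet). A variant overlapping a signal is called
#' disrupting unless the altered sequence still carries one of the 12 known
#' alternative motifs at an offset overlapping the edited hexamer (AAUAAA,
#' AUUAAA, AGUAAA, UAUAAA, CAUAAA, GAUAAA, AAUAUA, AAUACA, AAUAGA, AAAAAG,
#' ACUAAA, AAAAAA, written here as DNA); such a rescuing motif is reported.
#'
#' @param utr3_seq 3'UTR nucleotide sequence (5'->3').
#' @param pos 0-based position of the variant within `utr3_seq`.
#' @param ref,alt alleles.
#' @return list with `disrupted` (logical), `motif_interval` (0-based
#'   half-open interval of the reference hexamer hit, or `NULL`),
#'   `rescue_motif` (the created alternative motif when a hit signal is not
#'   disrupted, else `NA`).
#' @export
polya_disruption <- function(utr3_seq, pos, ref, alt) {
  seq <- .norm_dna(utr3_seq)
  ref <- .norm_dna(ref)
  alt <- .norm_dna(alt)
  pos <- as.integer(pos)
  lr <- nchar(ref)
  la <- nchar(alt)
  sites <- .pas_sites(seq)
  span_end <- pos + max(1L, lr)
  hit <- sites[sites < span_end & pos < sites + 6L]
  if (length(hit) == 0L) {
    return(list(disrupted = FALSE, motif_interval = NULL,
                rescue_motif = NA_character_))
  }
  m <- hit[1]
  alt_seq <- paste0(
    substr(seq, 1L, pos), alt,
    substr(seq, pos + lr + 1L, nchar(seq))
  )
  # image of the reference hexamer in the alternate sequence
  img_lo <- min(m, pos)
  img_hi <- m + 6L + ifelse(m + 6L > pos, la - lr, 0L)
  rescue <- NA_character_
  for (p in seq.int(max(0L, img_lo - 5L), max(0L, img_hi - 1L))) {
    if (p + 6L > nchar(alt_seq)) break
    hex <- substr(alt_seq, p + 1L, p + 6L)
    if (hex %in% .PAS_RESCUE && p < img_hi && p + 6L > img_lo) {
      rescue <- hex
      break
    }
  }
  list(
    disrupted = is.na(rescue),
    motif_interval = c(m, m + 6L),
    rescue_motif = rescue
  )
}
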