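# Seeded synthetic-data generators. Every input the pipeline consumes can
# be generated here with planted ground truth, so the whole framework is
# testable without access-controlled cohort data.
#
# Design: toy transcripts share a fixed geometry (three exons, two UTR
# introns, a 60 bp CDS) written onto a C/G-only background. Because the
# background contains no A or T, it can harbour no start codons, stop
# codons or polyA signals; every translational or signal feature is a
# deliberately written "island", which makes planted truth unambiguous.

.SLOT <- 2000L      # genomic spacing between transcript templates
.SPAN <- 510L       # unspliced template length
# template span layout (transcript orientation, 0-based):
#   exon1 [0,80) 5'UTR | intron1 [80,180) | exon2 [180,330)
#   (5'UTR 40 + CDS 60 + 3'UTR 50) | intron2 [330,430) | exon3 [430,510)
.EXONS_SPAN <- data.frame(start = c(0L, 180L, 430L),
                          end = c(80L, 330L, 510L))
.CDS_SPAN <- c(220L, 280L)
.CDS_OFFSET <- 120L   # spliced index of the CDS A(TG)
.UTR3_OFFSET <- 180L  # spliced index of the first 3'UTR base

# spliced transcript index -> span coordinate
.t2span <- function(t) {
  ifelse(t < 80L, t, ifelse(t < 230L, t + 100L, t + 200L))
}

.effect_levels <- c("uAUG_gain_oORF", "uSTOP_loss", "uAUG_loss",
                    "uFrameshift", "polyA_disrupt", "kozak_minus3",
                    "spliceai_high", "tfbs_loss", "rbp_loss",
                    "benign_background")

#' Specification of a synthetic fixture
#'
#' Bundles the knobs of the generators. The defaults are the study
#' conditions used throughout the test-suite: a handful of planted
#' variants per effect class, and a cohort of 2,000 cases and 2,000
#' controls with carrier probabilities 0.10 (cases) versus 0.05
#' (controls) drawn from a two-ancestry mix.
#'
#' @param seed integer seed; every generated artefact is a pure function
#'   of `seed` and the other fields.
#' @param n_transcripts number of toy transcripts (must be at least the
#'   number of non-background planted effects).
#' @param fraction_with_ccre fraction of TSSs covered by a cCRE.
#' @param planted_effects named integer vector of planted variant counts
#'   per effect class.
#' @param cohort list: `n_cases`, `n_controls`, `carrier_p_case`,
#'   `carrier_p_control`, `ancestry_mix` (named probabilities),
#'   `related_pairs`.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_transcripts = 20L,
                         fraction_with_ccre = 0.5,
                         planted_effects = c(
                           uAUG_gain_oORF = 2L, uSTOP_loss = 2L,
                           uAUG_loss = 2L, uFrameshift = 2L,
                           polyA_disrupt = 2L, kozak_minus3 = 2L,
                           spliceai_high = 2L, tfbs_loss = 2L,
                           rbp_loss = 2L, benign_background = 6L
                         ),
                         cohort = list(
                           n_cases = 2000L, n_controls = 2000L,
                           carrier_p_case = 0.10,
                           carrier_p_control = 0.05,
                           ancestry_mix = c(EUR = 0.8, SAS = 0.2),
                           related_pairs = 5L
                         )) {
  stopifnot(all(planted_effects >= 0),
            all(names(planted_effects) %in% .effect_levels))
  n_planted <- sum(planted_effects[setdiff(names(planted_effects),
                                           "benign_background")])
  if (n_transcripts < n_planted) {
    stop("need at least ", n_planted, " transcripts to host the planted ",
         "effects (one per transcript)")
  }
  structure(
    list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
         fraction_with_ccre = fraction_with_ccre,
         planted_effects = planted_effects, cohort = cohort),
    class = "fixture_spec"
  )
}

# Sequence islands written into the template (span coordinates; all in
# exon1 / exon2 / exon3 as appropriate). Spliced-index anchors:
#   uAUG context at t=20..26  "ACCAAGG"   (SNV t24 A>T  -> ACCATGG)
#   uSTOP uORF at t=20..34    "ACCATGGCCCCCTAA" (SNV t34 A>C kills stop)
#   uAUG_loss  at t=20..26    "ACCATGG"   (SNV t24 T>C  -> ACCACGG)
#   uFrameshift uORF t=20..37 "ACCATGGCCCCCCCCTAA" (ins C after t28)
#   kozak -3   t=117..119     "GCC" before the CDS ATG (SNV t117 G>T)
#   polyA      t=190..199     "CCAATAAACC" (SNV t194 T>C -> AACAAA)
.island_for <- function(effect) {
  switch(effect,
    uAUG_gain_oORF = list(at = 20L, seq = "ACCAAGG"),
    uSTOP_loss = list(at = 20L, seq = "ACCATGGCCCCCTAA"),
    uAUG_loss = list(at = 20L, seq = "ACCATGG"),
    uFrameshift = list(at = 20L, seq = "ACCATGGCCCCCCCCTAA"),
    polyA_disrupt = list(at = 190L, seq = "CCAATAAACC"),
    NULL
  )
}

# The planted variant for an effect, in spliced-transcript coordinates
# (VCF-style anchored alleles, transcript orientation).
.planted_tx_variant <- function(effect) {
  switch(effect,
    uAUG_gain_oORF = list(t = 24L, ref = "A", alt = "T"),
    uSTOP_loss = list(t = 34L, ref = "A", alt = "C"),
    uAUG_loss = list(t = 24L, ref = "T", alt = "C"),
    uFrameshift = list(t = 28L, ref = "C", alt = "CC"),
    kozak_minus3 = list(t = 117L, ref = "G", alt = "T"),
    polyA_disrupt = list(t = 194L, ref = "T", alt = "C"),
    NULL
  )
}

.expected_annotation <- c(
  uAUG_gain_oORF = "uorf_high_impact", uSTOP_loss = "uorf_high_impact",
  uAUG_loss = "uorf_high_impact", uFrameshift = "uorf_high_impact",
  polyA_disrupt = "polya", kozak_minus3 = "kozak",
  spliceai_high = "spliceai", tfbs_loss = "tfbs_loss",
  rbp_loss = "rbp_loss"
)

#' Generate a toy genome, transcript models and a cCRE track
#'
#' Builds `n_transcripts` non-overlapping three-exon transcripts on
#' alternating strands of one synthetic chromosome, each with a 5'UTR
#' (two exons), a 60 bp CDS and a 3'UTR (two exons), over a C/G-only
#' background. A seeded fraction of TSSs receives a promoter-like cCRE
#' whose extents are randomised across sufficient and deficient cases.
#' Transcripts designated to host a given planted effect carry the
#' corresponding reference sequence island (and indel hosts are forced
#' onto the plus strand so anchored alleles stay simple).
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (named character vector), `transcripts`
#'   (list of [transcript_model()]), `ccres` (data frame), and
#'   `tx_effects` (character vector: the effect hosted by each
#'   transcript, `NA` for none).
#' @export
make_genome_and_transcripts <- function(spec = fixture_spec()) {
  n <- spec$n_transcripts
  pe <- spec$planted_effects
  hosts <- rep(names(pe)[names(pe) != "benign_background"],
               pe[names(pe) != "benign_background"])
  tx_effects <- c(hosts, rep(NA_character_, n - length(hosts)))
  .with_seed(spec$seed, {
    chrom_len <- 1000L + n * .SLOT
    bg <- sample(c("C", "G"), chrom_len, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    # indel hosts are planted on the plus strand (anchored alleles)
    strands[!is.na(tx_effects) & tx_effects == "uFrameshift"] <- "+"
    has_ccre <- stats::runif(n) < spec$fraction_with_ccre
    ccre_up <- sample(100:250, n, replace = TRUE)
    ccre_down <- sample(30:120, n, replace = TRUE)

    transcripts <- vector("list", n)
    ccres <- list()
    for (i in seq_len(n)) {
      o <- 1000L + (i - 1L) * .SLOT
      span <- sample(c("C", "G"), .SPAN, replace = TRUE)
      # CDS: ATG + 18x GCC + TAA (no internal starts or stops)
      cds_seq <- paste0("ATG", strrep("GCC", 18L), "TAA")
      span[(.CDS_SPAN[1] + 1L):.CDS_SPAN[2]] <-
        strsplit(cds_seq, "")[[1]]
      # Kozak -3 context: GCC directly 5' of the CDS ATG
      span[(.t2span(117L) + 1L):(.t2span(119L) + 1L)] <- c("G", "C", "C")
      eff <- tx_effects[i]
      if (!is.na(eff)) {
        isl <- .island_for(eff)
        if (!is.null(isl)) {
          sp <- .t2span(isl$at)
          span[(sp + 1L):(sp + nchar(isl$seq))] <-
            strsplit(isl$seq, "")[[1]]
        }
      }
      span_seq <- paste(span, collapse = "")
      if (strands[i] == "+") {
        bg[(o + 1L):(o + .SPAN)] <- strsplit(span_seq, "")[[1]]
        exons <- data.frame(start = o + .EXONS_SPAN$start,
                            end = o + .EXONS_SPAN$end)
        cds_start <- o + .CDS_SPAN[1]
        cds_end <- o + .CDS_SPAN[2]
      } else {
        bg[(o + 1L):(o + .SPAN)] <- strsplit(.revcomp(span_seq), "")[[1]]
        exons <- data.frame(start = o + .SPAN - rev(.EXONS_SPAN$end),
                            end = o + .SPAN - rev(.EXONS_SPAN$start))
        cds_start <- o + .SPAN - .CDS_SPAN[2]
        cds_end <- o + .SPAN - .CDS_SPAN[1]
      }
      transcripts[[i]] <- transcript_model(
        transcript_id = sprintf("TX%03d", i),
        gene_symbol = sprintf("GENE%03d", i),
        chrom = "chrS", strand = strands[i], exons = exons,
        cds_start = cds_start, cds_end = cds_end
      )
      if (has_ccre[i]) {
        tss <- transcripts[[i]]$tss
        if (strands[i] == "+") {
          cc <- c(tss - ccre_up[i], tss + ccre_down[i])
        } else {
          cc <- c(tss - ccre_down[i] + 1L, tss + ccre_up[i] + 1L)
        }
        ccres[[length(ccres) + 1L]] <- data.frame(
          chrom = "chrS", start = cc[1], end = cc[2],
          label = "promoter-like", stringsAsFactors = FALSE
        )
      }
    }
    ccres <- if (length(ccres)) do.call(rbind, ccres) else
      data.frame(chrom = character(), start = integer(),
                 end = integer(), label = character())
    list(
      genome = c(chrS = paste(bg, collapse = "")),
      transcripts = transcripts,
      ccres = ccres,
      tx_effects = tx_effects
    )
  })
}

#' Plant variants with known truth into a synthetic genome
#'
#' For each planted effect class the generator emits a variant whose
#' sequence context (written at genome construction) provably produces
#' that effect, synthesises score columns consistent with the intended
#' truth (SpliceAI deltas, TF model predictions, RBP affinities, benign
#' CADD/PhyloP for backgrounds), and records the expected triggered
#' annotation and retention per analysis arm in a truth table. Background
#' variants are planted to trigger nothing; one background carries a
#' ClinVar benign status together with a high SpliceAI delta, so the
#' ClinVar exclusion is exercised. Every planted variant is verified
#' in-process against the package's own annotators before being emitted.
#'
#' @param spec a [fixture_spec()].
#' @param gt output of [make_genome_and_transcripts()] for the same spec.
#' @return list with `variants` (data frame: VCF-style fields plus score
#'   columns), `track_elements`, `tf_predictions`, and `truth` (data
#'   frame: `variant_id`, `effect_class`, `expected_annotation`,
#'   `retained_de_novo`, `retained_burden`).
#' @export
plant_variants <- function(spec, gt) {
  transcripts <- gt$transcripts
  genome <- gt$genome
  chrom_seq <- genome[["chrS"]]
  rows <- list()
  tracks <- list()
  preds <- list()
  truth <- list()
  vid <- 0L

  add_variant <- function(gpos, ref, alt, effect, expected_annotation,
                          ret_dn, ret_b, spliceai = NA_real_,
                          cadd = NA_real_, phylop = NA_real_,
                          clinvar = NA_character_) {
    vid <<- vid + 1L
    id <- sprintf("synv%03d", vid)
    rows[[length(rows) + 1L]] <<- data.frame(
      variant_id = id, chrom = "chrS", pos = gpos, ref = ref, alt = alt,
      spliceai_max = spliceai, cadd_phred = cadd, phylop = phylop,
      clinvar_status = clinvar, af_internal = 0, ac_internal = 1L,
      af_gnomad_popmax = 0, stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <<- data.frame(
      variant_id = id, effect_class = effect,
      expected_annotation = expected_annotation,
      retained_de_novo = ret_dn, retained_burden = ret_b,
      stringsAsFactors = FALSE
    )
    id
  }
  genomic_of <- function(tx, t) {
    sp <- .t2span(t)
    if (tx$strand == "+") tx$exons$start[1] + sp
    else tx$exons$start[1] + (.SPAN - 1L) - sp
  }
  ref_at <- function(gpos, len = 1L) {
    substr(chrom_seq, gpos + 1L, gpos + len)
  }
  other_cg <- function(b) if (b == "C") "G" else "C"

  for (i in seq_along(transcripts)) {
    eff <- gt$tx_effects[i]
    if (is.na(eff)) next
    tx <- transcripts[[i]]
    if (eff %in% c("uAUG_gain_oORF", "uSTOP_loss", "uAUG_loss",
                   "uFrameshift", "kozak_minus3", "polyA_disrupt")) {
      tv <- .planted_tx_variant(eff)
      if (tx$strand == "+") {
        g <- genomic_of(tx, tv$t)
        ref <- tv$ref
        alt <- tv$alt
      } else {
        g <- genomic_of(tx, tv$t + nchar(tv$ref) - 1L)
        ref <- .revcomp(tv$ref)
        alt <- .revcomp(tv$alt)
      }
      stopifnot(identical(ref_at(g, nchar(ref)), ref))
      add_variant(g, ref, alt, eff, .expected_annotation[[eff]],
                  TRUE, TRUE)
    } else if (eff == "spliceai_high") {
      # intron1, 5 bases in from the exon1 donor (not deep-intronic)
      sp <- 85L
      g <- if (tx$strand == "+") tx$exons$start[1] + sp
           else tx$exons$start[1] + (.SPAN - 1L) - sp
      b <- ref_at(g)
      add_variant(g, b, other_cg(b), eff, "spliceai", TRUE, TRUE,
                  spliceai = 0.8)
    } else if (eff == "tfbs_loss") {
      tss <- tx$tss
      g <- if (tx$strand == "+") tss - 10L else tss + 10L
      b <- ref_at(g)
      id <- add_variant(g, b, other_cg(b), eff, "tfbs_loss", TRUE, TRUE)
      tracks[[length(tracks) + 1L]] <- data.frame(
        chrom = "chrS", start = g - 5L, end = g + 6L, track = "TFBS",
        in_core_dhs = TRUE, ref_affinity = NA_real_,
        alt_affinity = NA_real_, stringsAsFactors = FALSE
      )
      preds[[length(preds) + 1L]] <- data.frame(
        variant_id = id, tf_name = "TF1", model_id = c("m1", "m2"),
        value = c(-0.5, -0.7), stringsAsFactors = FALSE
      )
    } else if (eff == "rbp_loss") {
      g <- genomic_of(tx, 250L)  # 3'UTR exon3
      b <- ref_at(g)
      add_variant(g, b, other_cg(b), eff, "rbp_loss", TRUE, TRUE)
      tracks[[length(tracks) + 1L]] <- data.frame(
        chrom = "chrS", start = g - 3L, end = g + 4L, track = "RBP",
        in_core_dhs = NA, ref_affinity = 0.5, alt_affinity = 0.05,
        stringsAsFactors = FALSE
      )
    }
  }

  # background variants: planted to trigger nothing
  n_bg <- spec$planted_effects[["benign_background"]]
  if (is.na(n_bg)) n_bg <- 0L
  bg_spots <- c(60L, 300L, 50L)  # exon1 5'UTR, exon3 3'UTR, exon1 5'UTR
  for (j in seq_len(n_bg)) {
    tx <- transcripts[[1L + (j - 1L) %% length(transcripts)]]
    t <- bg_spots[1L + (j - 1L) %% length(bg_spots)]
    g <- genomic_of(tx, t)
    b <- ref_at(g)
    if (j == 1L) {
      # benign ClinVar status with a high splice delta: excluded outright
      add_variant(g, b, other_cg(b), "benign_background", "", FALSE, FALSE,
                  spliceai = 0.9, cadd = 20, phylop = 1.0,
                  clinvar = "Benign")
    } else {
      add_variant(g, b, other_cg(b), "benign_background", "", FALSE, FALSE,
                  cadd = 20, phylop = 1.0)
    }
  }

  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  track_elements <- if (length(tracks)) do.call(rbind, tracks) else NULL
  tf_predictions <- if (length(preds)) do.call(rbind, preds) else NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # in-process verification: the planted truths must hold
  regions <- build_near_coding_regions(transcripts, gt$ccres)
  ann <- annotate_variants(variants, transcripts, regions, genome,
                           track_elements, tf_predictions)
  dec <- prioritize_variants(ann, arm = "de_novo")
  ok <- dec$retained == truth$retained_de_novo
  if (!all(ok)) {
    stop("internal check failed: planted truth not recovered for ",
         paste(truth$variant_id[!ok], collapse = ", "))
  }
  list(variants = variants, track_elements = track_elements,
       tf_predictions = tf_predictions, truth = truth)
}

#' Simulate a matched-cohort dataset
#'
#' Draws case and control participants with a configurable sex/ancestry
#' mix, Bernoulli carrier status at arm-specific probabilities, a noisy
#' near-coding variant count per participant (for Z-score filtering), and
#' a kinship table into which a configurable number of related pairs
#' (KING >= 0.0442) is injected.
#'
#' @param cohort list as in [fixture_spec()]'s `cohort`.
#' @param seed integer seed.
#' @return list with `participants` (data frame: `participant_id`,
#'   `family_id`, `role`, `affected`, `sex`, `ancestry`,
#'   `n_panel_genes`, `variant_count`, `carrier`) and `king_pairs`.
#' @export
simulate_cohort <- function(cohort = fixture_spec()$cohort, seed = 1L) {
  .with_seed(seed, {
    nc <- cohort$n_cases
    nk <- cohort$n_controls
    mix <- cohort$ancestry_mix
    n <- nc + nk
    ancestry <- sample(names(mix), n, replace = TRUE, prob = mix)
    sex <- sample(c("XX", "XY"), n, replace = TRUE)
    is_case <- rep(c(TRUE, FALSE), c(nc, nk))
    carrier <- stats::rbinom(n, 1L,
                             ifelse(is_case, cohort$carrier_p_case,
                                    cohort$carrier_p_control)) == 1L
    participants <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      family_id = sprintf("F%05d", seq_len(n)),
      role = ifelse(is_case, "proband",
                    sample(c("mother", "father"), n, replace = TRUE)),
      affected = is_case,
      sex = sex, ancestry = ancestry,
      n_panel_genes = sample(5:100, n, replace = TRUE),
      variant_count = stats::rpois(n, 460),
      carrier = carrier,
      stringsAsFactors = FALSE
    )
    rp <- cohort$related_pairs
    king <- NULL
    if (!is.null(rp) && rp > 0 && n >= 2 * rp) {
      idx <- sample(n, 2L * rp)
      king <- data.frame(
        id1 = participants$participant_id[idx[seq_len(rp)]],
        id2 = participants$participant_id[idx[rp + seq_len(rp)]],
        king = stats::runif(rp, 0.0442, 0.25),
        stringsAsFactors = FALSE
      )
    }
    bgp <- min(50L, n %/% 4L)
    if (bgp > 0) {
      i1 <- sample(n, bgp)
      i2 <- sample(n, bgp)
      keep <- i1 != i2
      king <- rbind(king, data.frame(
        id1 = participants$participant_id[i1[keep]],
        id2 = participants$participant_id[i2[keep]],
        king = stats::runif(sum(keep), 0, 0.02),
        stringsAsFactors = FALSE
      ))
    }
    list(participants = participants, king_pairs = king)
  })
}
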