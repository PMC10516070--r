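# The arm-aware, region-specific prioritisation cascade.
#
# Annotated variants are flat data frames (TSV-friendly). Region classes
# are stored as a comma-separated string in `region_classes`; annotation
# flags are logical columns produced by annotate_variants() or encoded
# directly.

#' Thresholds for one analysis arm
#'
#' The de novo arm uses a sensitive SpliceAI cutoff (0.2) and strict
#' internal frequency filters (exclude AF >= 5e-5 or AC >= 5 internally,
#' or gnomAD population-maximum AF >= 5e-4). The burden arm uses SpliceAI
#' 0.5 and requires AF <= 5e-5 for both internal and gnomAD population
#' frequencies, excluding AC >= 5. Both arms share the deleteriousness
#' flag thresholds (CADD PHRED 25.3, PhyloP 7.367) and the benign-score
#' exclusion thresholds (CADD 22.7, PhyloP 1.879).
#'
#' @param arm `"de_novo"` or `"burden"`.
#' @return named list of thresholds.
#' @export
arm_thresholds <- function(arm = c("de_novo", "burden")) {
  arm <- match.arg(arm)
  base <- list(
    arm = arm,
    cadd_flag = 25.3, phylop_flag = 7.367,
    benign_cadd = 22.7, benign_phylop = 1.879
  )
  if (arm == "de_novo") {
    c(base, list(spliceai_cutoff = 0.2,
                 af_max = 5e-5, ac_max = 5, af_gnomad_max = 5e-4))
  } else {
    c(base, list(spliceai_cutoff = 0.5,
                 af_max = 5e-5, ac_max = 5, af_gnomad_max = 5e-5))
  }
}

#' ClinVar benign/protective exclusion
#'
#' @param status ClinVar clinical significance strings (`NA` allowed).
#' @return logical: `TRUE` when the variant must be excluded (status is
#'   one of benign, likely benign, benign/likely benign, protective;
#'   case-insensitive, `_` and space equivalent).
#' @export
clinvar_benign_exclusion <- function(status) {
  norm <- tolower(gsub("[ _]+", " ", as.character(status)))
  excl <- c("benign", "likely benign", "benign/likely benign", "protective")
  !is.na(status) & norm %in% excl
}

#' Pre-filter for the de novo arm
#'
#' @param af_internal,ac_internal,af_gnomad_popmax frequency/count fields;
#'   missing frequencies are treated as 0 with a warning.
#' @param pass_filter call passed the cohort's strictest filter set.
#' @param in_panel_region variant lies in a near-coding region of a green
#'   dominant panel gene assigned to the proband.
#' @param proband_unsolved proband has no existing coding diagnosis.
#' @param parents_unaffected both parents unaffected and free of HPO terms.
#' @param thresholds an [arm_thresholds()]`("de_novo")` list.
#' @return logical: `TRUE` when the variant survives the pre-filter.
#' @export
dnv_prefilter <- function(af_internal, ac_internal, af_gnomad_popmax,
                          pass_filter = TRUE, in_panel_region = TRUE,
                          proband_unsolved = TRUE,
                          parents_unaffected = TRUE,
                          thresholds = arm_thresholds("de_novo")) {
  if (any(is.na(af_internal)) || any(is.na(af_gnomad_popmax))) {
    warning("missing allele frequency treated as 0")
  }
  af_internal[is.na(af_internal)] <- 0
  af_gnomad_popmax[is.na(af_gnomad_popmax)] <- 0
  ac_internal[is.na(ac_internal)] <- 0
  pass_filter & in_panel_region & proband_unsolved & parents_unaffected &
    af_internal < thresholds$af_max &
    ac_internal < thresholds$ac_max &
    af_gnomad_popmax < thresholds$af_gnomad_max
}

#' Pre-filter for the burden-testing arm
#'
#' @inheritParams dnv_prefilter
#' @param thresholds an [arm_thresholds()]`("burden")` list.
#' @return logical.
#' @export
burden_prefilter <- function(af_internal, ac_internal, af_gnomad_popmax,
                             thresholds = arm_thresholds("burden")) {
  if (any(is.na(af_internal)) || any(is.na(af_gnomad_popmax))) {
    warning("missing allele frequency treated as 0")
  }
  af_internal[is.na(af_internal)] <- 0
  af_gnomad_popmax[is.na(af_gnomad_popmax)] <- 0
  ac_internal[is.na(ac_internal)] <- 0
  af_internal <= thresholds$af_max &
    af_gnomad_popmax <= thresholds$af_gnomad_max &
    ac_internal < thresholds$ac_max
}

.split_classes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

.flag <- function(df, name) {
  if (name %in% names(df)) {
    v <- as.logical(df[[name]])
    v[is.na(v)] <- FALSE
    v
  } else {
    rep(FALSE, nrow(df))
  }
}

.num <- function(df, name) {
  if (name %in% names(df)) as.numeric(df[[name]]) else rep(NA_real_, nrow(df))
}

#' Run the region-specific prioritisation cascade
#'
#' Assembles, per variant, the set of triggered annotations allowed by its
#' region classes and decides retention:
#' \itemize{
#' \item 5'UTR exon: high-impact 5'UTR consequence (`uorf_high_impact`),
#'   IRES overlap (after benign-score exclusion), Kozak -3 disruption;
#' \item 3'UTR exon: polyA-signal disruption, miRNA-site overlap (after
#'   benign-score exclusion), RBP binding loss, dORF start/stop hit;
#' \item any UTR exon or UTR intron: SpliceAI maximum delta at or above the
#'   arm's cutoff;
#' \item promoter: predicted TF-binding loss (already restricted to
#'   core-DHS footprints);
#' \item all regions except deep-intronic positions: CADD PHRED >= 25.3
#'   and/or PhyloP >= 7.367 flags.
#' }
#' Variants with a ClinVar benign/protective status (column
#' `clinvar_status`, if present) are excluded outright. A variant is
#' retained iff at least one annotation triggers.
#'
#' @param variants annotated-variant data frame. Recognised columns:
#'   `region_classes` (comma-separated), `deep_intronic`, flag columns
#'   `uorf_high_impact`, `ires_hit`, `kozak_hit`, `polya_hit`,
#'   `mirna_hit`, `rbp_loss_hit`, `dorf_hit`, `tfbs_loss_hit`, scores
#'   `spliceai_max`, `cadd_phred`, `phylop`, and optional
#'   `clinvar_status`.
#' @param arm `"de_novo"` or `"burden"`.
#' @param thresholds an [arm_thresholds()] list.
#' @return the input with columns `retained` (logical) and
#'   `triggered_annotations` (comma-separated string) appended.
#' @export
prioritize_variants <- function(variants, arm = c("de_novo", "burden"),
                                thresholds = arm_thresholds(arm)) {
  arm <- match.arg(arm)
  n <- nrow(variants)
  uorf <- .flag(variants, "uorf_high_impact")
  ires <- .flag(variants, "ires_hit")
  kozak <- .flag(variants, "kozak_hit")
  polya <- .flag(variants, "polya_hit")
  mirna <- .flag(variants, "mirna_hit")
  rbp <- .flag(variants, "rbp_loss_hit")
  dorf <- .flag(variants, "dorf_hit")
  tfbs <- .flag(variants, "tfbs_loss_hit")
  deep <- .flag(variants, "deep_intronic")
  spliceai <- .num(variants, "spliceai_max")
  cadd <- .num(variants, "cadd_phred")
  phylop <- .num(variants, "phylop")
  clinvar_excl <- if ("clinvar_status" %in% names(variants)) {
    clinvar_benign_exclusion(variants$clinvar_status)
  } else {
    rep(FALSE, n)
  }
  benign <- benign_score_exclusion(cadd, phylop,
                                   thresholds$benign_cadd,
                                   thresholds$benign_phylop)
  triggered <- character(n)
  retained <- logical(n)
  for (i in seq_len(n)) {
    cls <- .split_classes(variants$region_classes[i])
    trig <- character()
    if (length(cls) > 0 && !clinvar_excl[i]) {
      if ("five_utr" %in% cls) {
        if (uorf[i]) trig <- c(trig, "uorf_high_impact")
        if (ires[i] && !benign[i]) trig <- c(trig, "ires")
        if (kozak[i]) trig <- c(trig, "kozak")
      }
      if ("three_utr" %in% cls) {
        if (polya[i]) trig <- c(trig, "polya")
        if (mirna[i] && !benign[i]) trig <- c(trig, "mirna")
        if (rbp[i]) trig <- c(trig, "rbp_loss")
        if (dorf[i]) trig <- c(trig, "dorf_boundary")
      }
      if (any(cls %in% c("five_utr", "three_utr",
                         "five_utr_intron", "three_utr_intron"))) {
        if (!is.na(spliceai[i]) &&
            spliceai[i] >= thresholds$spliceai_cutoff) {
          trig <- c(trig, "spliceai")
        }
      }
      if ("promoter" %in% cls && tfbs[i]) trig <- c(trig, "tfbs_loss")
      if (!deep[i]) {
        if (!is.na(cadd[i]) && cadd[i] >= thresholds$cadd_flag) {
          trig <- c(trig, "cadd_flag")
        }
        if (!is.na(phylop[i]) && phylop[i] >= thresholds$phylop_flag) {
          trig <- c(trig, "phylop_flag")
        }
      }
    }
    triggered[i] <- paste(trig, collapse = ",")
    retained[i] <- length(trig) > 0
  }
  stopifnot(identical(retained, nzchar(triggered)))
  variants$retained <- retained
  variants$triggered_annotations <- triggered
  variants
}

#' Bundled exemplar candidate de novo variants
#'
#' Eleven candidate de novo variants in well-known dominant disease genes
#' (SLC2A1, PAX6, MEF2C, NIPBL, SETD5, RPL26, GNAS, ZBTB18, SLC40A1,
#' MFRP), encoded with the region classes and annotation values under
#' which each was short-listed during clinical re-analysis. Useful as a
#' worked example for [prioritize_variants()]: all eleven are retained
#' under de novo-arm thresholds, while the stricter burden-arm SpliceAI
#' cutoff drops the weakest splice candidate.
#'
#' @return annotated-variant data frame.
#' @export
example_candidate_dnvs <- function() {
  path <- system.file("extdata", "candidate_dnvs.tsv",
                      package = "nearcoding", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
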