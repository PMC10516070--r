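---
title: "Prioritising promoter and UTR variants in dominant disease genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising promoter and UTR variants in dominant disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearcoding)
```

## The problem

Clinical genetic testing is heavily biased towards protein-coding exons,
yet the proximal promoter, the 5' and 3' untranslated regions (UTRs) and
the introns interrupting UTRs all carry sequence elements whose disruption
can abolish transcription or translation of a dominant disease gene.
`nearcoding` implements a complete desk-scale framework for this class of
analysis: it constructs the "near-coding" target territory around each
transcript, annotates variants with region-appropriate functional
evidence, applies a strict region-specific prioritisation cascade, and
quantifies cohort-level burden with matched case-control exact tests.

The package deliberately consumes upstream predictor output (SpliceAI
delta scores, CADD PHRED, PhyloP, ClinVar assertions, per-TF
binding-change model predictions, RBP affinities) as plain input columns:
computing those scores is the job of the respective predictors, while the
contribution here is the region logic, the sequence-level 5'UTR/3'UTR
annotation, the cascade, and the burden machinery.

## Region construction

Regions come in five classes: `promoter`, `five_utr`, `three_utr`,
`five_utr_intron`, `three_utr_intron`. UTR exon and intron coordinates
derive directly from the transcript model (MANE-like: one transcript per
gene, exons plus a coding span). Introns wholly 5' of the coding span are
5'UTR introns, those wholly 3' of it are 3'UTR introns; introns between
coding exons are not near-coding. An intron flanking the exon that
contains the CDS start still counts as a UTR intron provided it lies
wholly outside the coding span — the biologically interesting case of a
splice variant upstream of the start-codon exon.

Promoters are anchored on candidate cis-regulatory elements (cCREs).
Promoter-like cCREs have a characteristic size distribution around the
TSS; the package uses the 25th percentile extents (181 bp upstream, 67 bp
downstream) as a minimal promoter and the 75th percentiles (266/139 bp)
as the default when no cCRE overlaps the TSS:

* a TSS-overlapping cCRE meeting both minimal extents is used verbatim;
* a TSS-overlapping cCRE short on either side is extended to exactly the
  minimal extent on that side;
* with no overlapping cCRE, the 75th-percentile box around the TSS is
  used.

All four extents are `promoter_config()` arguments with those defaults.
Two conventions are fixed where the underlying definition is silent:
coordinates are 0-based half-open throughout (converted at the VCF/GFF3
boundary), and the "−181 to +67" box is realised as `[tss-181, tss+67)`
on the plus strand, i.e. the TSS base itself counts towards the
downstream span, mirrored on the minus strand. When several cCREs overlap
one TSS the largest is used, ties broken by leftmost start.

Finally every base that is a CDS exonic base of *any* transcript is
subtracted from every region (`subtract_cds()`), so no retained variant
can have a direct protein-coding interpretation. A position can remain in
several classes at once — promoter/5'UTR overlap is common by
construction — and region assignment returns the full set. Positions in a
UTR intron more than 20 bases from both flanking exon boundaries are
flagged *deep intronic* (the 21st base is the first deep one).

```{r regions}
tx <- transcript_model("TX1", "GENE1", "chr1", "+",
                       data.frame(start = c(1000, 1200),
                                  end = c(1100, 1500)),
                       cds_start = 1250, cds_end = 1450)
ccre <- data.frame(chrom = "chr1", start = 900, end = 1020)
derive_promoter(tx, ccre)
extract_utr_regions(tx)
```

## 5'UTR translational effects

`annotate_five_prime()` compares the full complement of upstream AUGs,
their reading frames and in-frame stops between the reference and
alternate spliced sequences and emits `uAUG_gain`, `uAUG_loss`,
`uSTOP_loss` and `uFrameshift` calls, each with an ORF outcome (`uORF`
when an in-frame stop lies wholly before the CDS start, otherwise an
in-frame or out-of-frame overlapping ORF) and the Kozak strength of the
relevant AUG. `high_impact_utr_filter()` retains the four configurations
with the highest prior of disrupting translation: uAUG gain into an oORF
with strong/moderate Kozak, uSTOP loss leaving an oORF with
strong/moderate Kozak, uAUG loss with strong Kozak, and a frameshift
producing an oORF with strong/moderate Kozak.

The Kozak classification rule is: strong when the −3 base is a purine
*and* the +4 base is G; moderate when exactly one condition holds; weak
otherwise; a position off the end of the sequence counts as failing.
Classes beyond −3/+4 contribute nothing, which the test-suite asserts as
an invariance property. Two further conventions: a `uFrameshift` is a
non-3n indel strictly inside the body of an existing reference uORF
(indels touching the stop codon are assessed as stop disruptions
instead), and the Kozak context for stop-loss/frameshift events is read
from the alternate sequence (the AUG itself is unchanged; its context
rarely is, but the alternate sequence is what the ribosome sees).

Separately, `kozak_minus3_disruption()` flags substitutions at exactly
the −3 position of the *main* CDS AUG that replace a purine with a
pyrimidine — the single most consequential Kozak position. The rule is
restricted to substitutions; an indel shifting the −3 base has no
unambiguous "the" −3 substitution to evaluate.

All of this runs on the spliced transcript sequence; intronic variants
never reach the sequence-level annotators.

## 3'UTR signals and overlay tracks

`polya_disruption()` scans the 3'UTR for canonical polyadenylation
signal hexamers (AAUAAA, AUUAAA; all motif logic is in the DNA alphabet,
U normalised to T) and calls a variant disrupting only when the altered
window no longer carries any of the 12 known functional variants of the
signal (AAUAAA, AUUAAA, AGUAAA, UAUAAA, CAUAAA, GAUAAA, AAUAUA, AAUACA,
AAUAGA, AAAAAG, ACUAAA, AAAAAA) at any offset overlapping the edited
hexamer — a "rescue" motif is reported instead of a disruption call.

Overlay annotations use any-overlap interval semantics
(`overlap_track()`): IRES elements (5'UTR), miRNA binding sites (3'UTR),
dORFs (3'UTR, flagged only when the variant hits the start- or
stop-codon sub-interval), RBP sites and TFBS footprints. Two
track-specific sub-filters apply:

* **IRES/miRNA**: because these tracks are broad, overlapping variants
  whose scores affirmatively support benignity (CADD ≤ 22.7 *or* PhyloP
  ≤ 1.879) are excluded. A missing score cannot trigger its comparison —
  exclusion requires positive evidence.
* **RBP**: a binding loss requires a reference affinity ≥ 0.1 and an
  alternate/reference affinity ratio below 1/3 (a zero reference
  affinity denotes an inactive site, never a loss).

For promoter variants, `tfbs_core_dhs_filter()` first requires the
variant to sit in a footprint within the core of a DNase I
hypersensitive peak; `fabian_aggregate()` then averages the per-model
binding-change predictions into one score per transcription factor,
classes scores ≥ 0.04 as gains and ≤ −0.04 as losses, and retains the
variant when the mean over loss-classified TFs is ≤ −0.4. The mean over
gains and over all TFs is computed and reported alongside, but only the
mean loss score gates retention — the retention sentence in the source
methodology reads most naturally on the loss mean, and both quantities
are exposed so the alternative reading costs one comparison.

## The prioritisation cascade

`prioritize_variants()` assembles the per-region annotation menu:

| region class | triggers |
|---|---|
| 5'UTR exon | high-impact UTR consequence, IRES (post benign filter), Kozak −3 |
| 3'UTR exon | polyA disruption, miRNA (post benign filter), RBP loss, dORF boundary |
| any UTR exon or intron | SpliceAI max delta ≥ arm cutoff |
| promoter | TF-binding loss (core-DHS footprints only) |
| all but deep-intronic | CADD ≥ 25.3 flag, PhyloP ≥ 7.367 flag |

Variants with a ClinVar benign/likely-benign/protective assertion are
excluded outright. CADD and PhyloP are not consulted in deep-intronic
positions (they were calibrated on and near coding sequence; deep
introns mostly contribute noise). Variants in promoter/UTR overlap
regions draw from the union of both menus. A variant is retained iff at
least one annotation triggers, and the decision record always carries
the triggering set, so retention is auditable.

Two arms share the cascade but not the thresholds
(`arm_thresholds()`): the de novo arm uses SpliceAI ≥ 0.2 and excludes
variants with internal AF ≥ 5e-5 *or* internal AC ≥ 5, or gnomAD
population-maximum AF ≥ 5e-4; the burden arm tightens SpliceAI to 0.5
and requires AF ≤ 5e-5 for internal *and* gnomAD frequencies with the
same AC exclusion. The internal AF/AC sentence is read as
exclude-if-either, consistent with the de novo set being described as
rare at AF ≤ 0.005%.

## Burden testing

Cohort construction mirrors standard matched-cohort practice:
genotype-level QC (`genotype_qc()`: GQ ≥ 20, DP ≥ 10, het AB in
[0.2, 0.8], hom AB ≤ 0.02; a variant is dropped at > 5% missingness or
when ≥ 25% of case calls fail), ancestry-wise variant-count Z-score
outlier removal (`zscore_filter()`, |z| ≥ 2 dropped — the cutoff is
read as inclusive and sample SD is used), random iterative relatedness
pruning at KING ≥ 0.0442 (`prune_related()`, seeded), and 1:1
sex/ancestry matching with control reuse and a family-ID exclusion
(`match_case_control()`). The matching mechanics — shuffle cases within
each stratum, assign each a uniformly random eligible control with
replacement — are the package's own choice; only the matching criteria
are inherited. Ancestry strata need more than 200 cases and 200 controls
(smaller strata are excluded wholesale) and cases with more than 100
assigned green dominant panel genes are dropped; both limits are
arguments.

`fisher_burden()` compares carrier counts in a 2×2 table. The two-sided
exact P is computed by direct hypergeometric enumeration — the sum of
probabilities of all tables with the observed margins at most as
probable as the observed one (with the conventional `1 + 1e-7` relative
tolerance) — and is cross-checked in the test-suite against an
independent closed-form oracle and against `stats::fisher.test()`,
exhaustively for small tables. The odds ratio is the sample odds ratio
(a·d)/(b·c), undefined (and flagged) on a zero margin; the 95% CI comes
from conditional-likelihood inversion. The per-test significance level
is Bonferroni-corrected for the 16 region/variant annotation tests:
0.05/16 = 0.003125, displayed as 0.0031.

`required_n()` estimates the cohort size needed for significance: both
cohorts grow by one participant per step, carrier counts are held at the
observed proportions (rounded at each size), and the exact P is
recomputed until it reaches the target alpha. Joint growth of cases and
controls is fixed by the estimator's definition; with equal carrier
proportions the procedure cannot terminate and a sentinel with a
diagnostic is returned instead.

## Synthetic data and what the tests do (and do not) show

`make_genome_and_transcripts()` builds toy transcripts with a fixed
three-exon geometry (two-exon 5'UTR, one 60 bp CDS, two-exon 3'UTR) on a
C/G-only background. The alphabet restriction is the key trick: with no
A or T in the background there can be no start codon, stop codon or
polyA signal anywhere except in the deliberately written sequence
"islands", so every planted effect is provable and every background
variant is provably inert. `plant_variants()` emits one variant per
planted effect class — uAUG gain into an oORF, uSTOP loss, uAUG loss,
uORF frameshift, polyA disruption, Kozak −3 disruption, a high splice
delta in a UTR intron, a TF-binding loss in a core-DHS footprint, an RBP
binding loss — plus inert backgrounds, one of which pairs a ClinVar
benign assertion with a high SpliceAI delta to exercise the exclusion.
Scores are drawn well clear of every threshold (e.g. CADD 20 vs the
25.3 flag), so the round-trip truth is unambiguous; threshold-boundary
behaviour is tested separately with hand-built cases.

The cohort simulator (`simulate_cohort()`) draws carriers as independent
Bernoulli variables at 10% (cases) versus 5% (controls) for 2,000
participants per arm — the conditions under which the test-suite
demonstrates ≥ 80% power at the adjusted alpha and ≤ 1% type-I rate
under the null over 200 seeded replicates.

These fixtures establish correctness of the logic, not performance on
real genomes: the toy genome has no GC heterogeneity, repeats,
alternative transcripts, overlapping genes, linkage or realistic
mutation spectra, and planted scores are noise-free stand-ins for real
predictor output. Passing the round trip therefore shows the pipeline
faithfully implements its rules — it cannot show that the rules have
high yield on patient data.

## Worked example

The package bundles eleven exemplar candidate de novo variants in known
dominant disease genes, encoded with the annotations under which each
was short-listed in clinical re-analysis:

```{r example}
dnvs <- example_candidate_dnvs()
dn <- prioritize_variants(dnvs, "de_novo")
dn[, c("gene_symbol", "region_classes", "triggered_annotations")]
sum(dn$retained)
# the stricter burden-arm splice threshold drops the weakest candidate
sum(prioritize_variants(dnvs, "burden")$retained)
```

## Numerical choices and problem sizes

* Interval arithmetic delegates to IRanges; all public coordinates are
  0-based half-open and converted exactly once at that boundary.
* Exact-test P-values use `dhyper` enumeration; agreement with the
  closed-form oracle is asserted to 1e-12, exhaustively for all 2×2
  tables with total at most 40 and by seeded sweep for totals up to 60.
* The 5'UTR annotator is checked against a brute-force ORF-enumeration
  oracle on 1,000 seeded random sequence/variant pairs (SNVs and 1–4 bp
  indels), plus mirrored gain/loss reversibility on SNVs.
* Region construction is checked against a per-base brute-force
  labeller on multi-kilobase toy genomes, including a per-base proof of
  zero CDS leakage.
* Ties and degenerate inputs: zero-variance Z-score groups keep all
  members (with a warning); zero-margin tables report P = 1 with an
  undefined-OR flag; empty region assignments are never retained;
  missing scores never trigger flags and never satisfy the benign
  exclusion.

## Known limitations

* Multi-transcript interactions are resolved per assigned transcript
  (first hit); a variant in the 5'UTR of one gene and the 3'UTR of an
  overlapping gene is annotated against both regions but sequence
  effects use one transcript at a time.
* The Kozak −3 rule covers substitutions only.
* The simulator does not model linkage, haplotypes or realistic
  mutation rates, and control reuse in matching is uniform rather than
  usage-balanced.
* Upstream predictor scores are trusted as given; no recalibration is
  attempted.
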