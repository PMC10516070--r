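#' Promoter sizing configuration
#'
#' Percentile extents (in bases) of promoter-like candidate cis-regulatory
#' elements (cCREs) around transcription start sites, used to size proximal
#' promoter regions. The 25th-percentile extents define the minimal promoter
#' (181 bp upstream / 67 bp downstream of the TSS); the 75th percentiles
#' (266 / 139 bp) are used when no cCRE overlaps the TSS.
#'
#' @param up_p25,down_p25 minimal extents upstream/downstream of the TSS.
#' @param up_p75,down_p75 default extents used without a TSS-overlapping cCRE.
#' @return a `promoter_config` list.
#' @export
promoter_config <- function(up_p25 = 181L, down_p25 = 67L,
                            up_p75 = 266L, down_p75 = 139L) {
  v <- c(up_p25 = up_p25, down_p25 = down_p25,
         up_p75 = up_p75, down_p75 = down_p75)
  if (any(v <= 0)) stop("promoter extents must be positive")
  if (up_p75 < up_p25 || down_p75 < down_p25) {
    stop("75th percentile extents must be >= 25th percentile extents")
  }
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "promoter_config")
}

.REGION_CLASSES <- c("promoter", "five_utr", "three_utr",
                     "five_utr_intron", "three_utr_intron")
.INTRON_CLASSES <- c("five_utr_intron", "three_utr_intron")

.region_df <- function(chrom = character(), start = integer(),
                       end = integer(), region_class = character(),
                       transcript_id = character(),
                       gene_symbol = character()) {
  data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    region_class = region_class, transcript_id = transcript_id,
    gene_symbol = gene_symbol, stringsAsFactors = FALSE
  )
}

#' Derive a proximal promoter interval for one transcript
#'
#' Sizing follows the cCRE-anchored rules: if a promoter-like cCRE overlaps
#' the TSS and spans at least the minimal (25th percentile) extent both
#' upstream and downstream, the cCRE interval is used unchanged; if it falls
#' short on either side, that side is extended to exactly the minimal
#' extent; if no cCRE overlaps the TSS, the 75th-percentile extents are used
#' around the TSS. All rules are strand-aware (upstream/downstream mirror on
#' the minus strand). On the plus strand the promoter realises
#' `[tss - up, tss + down)`, i.e. the TSS base itself counts towards the
#' downstream span; the minus strand mirrors this.
#'
#' When several cCREs overlap the TSS the one with the largest span is used
#' (ties: leftmost start). cCREs on other chromosomes are ignored.
#'
#' @param tx a [transcript_model()].
#' @param ccres data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param cfg a [promoter_config()].
#' @return data frame with one row: `chrom`, `start`, `end` (the promoter
#'   interval), plus `transcript_id`, `gene_symbol`, `region_class`.
#' @export
derive_promoter <- function(tx, ccres = NULL, cfg = promoter_config()) {
  stopifnot(inherits(tx, "transcript_model"))
  tss <- tx$tss
  up <- cfg$up_p75
  down <- cfg$down_p75
  chosen <- NULL
  if (!is.null(ccres) && nrow(ccres) > 0) {
    cc <- ccres[ccres$chrom == tx$chrom &
                  ccres$start <= tss & tss < ccres$end, , drop = FALSE]
    if (nrow(cc) > 0) {
      span <- cc$end - cc$start
      cc <- cc[order(-span, cc$start), , drop = FALSE]
      chosen <- cc[1, , drop = FALSE]
    }
  }
  if (is.null(chosen)) {
    if (tx$strand == "+") {
      start <- tss - up
      end <- tss + down
    } else {
      start <- tss - down + 1L
      end <- tss + up + 1L
    }
  } else {
    start <- chosen$start
    end <- chosen$end
    if (tx$strand == "+") {
      up_extent <- tss - start
      down_extent <- end - tss
      if (up_extent < cfg$up_p25) start <- tss - cfg$up_p25
      if (down_extent < cfg$down_p25) end <- tss + cfg$down_p25
    } else {
      up_extent <- end - 1L - tss
      down_extent <- tss - start + 1L
      if (up_extent < cfg$up_p25) end <- tss + cfg$up_p25 + 1L
      if (down_extent < cfg$down_p25) start <- tss - cfg$down_p25 + 1L
    }
  }
  .region_df(tx$chrom, start, end, "promoter", tx$transcript_id,
             tx$gene_symbol)
}

#' Extract UTR exon and UTR intron regions of a coding transcript
#'
#' Exonic bases 5' of the coding span are classed `five_utr`, those 3' of it
#' `three_utr` (strand-aware). Introns lying wholly on the 5' side of the
#' CDS are `five_utr_intron`; wholly on the 3' side, `three_utr_intron`.
#' Introns between coding exons are excluded.
#'
#' @param tx a coding [transcript_model()].
#' @return region data frame (`chrom`, `start`, `end`, `region_class`,
#'   `transcript_id`, `gene_symbol`).
#' @export
extract_utr_regions <- function(tx) {
  stopifnot(inherits(tx, "transcript_model"))
  if (is.na(tx$cds_start)) {
    stop("transcript ", tx$transcript_id,
         " is non-coding; UTRs are undefined")
  }
  out <- .region_df()
  exons <- tx$exons
  # exonic UTR pieces
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    left <- c(s, min(e, tx$cds_start))     # genomically left of CDS
    right <- c(max(s, tx$cds_end), e)      # genomically right of CDS
    if (left[2] > left[1]) {
      cls <- if (tx$strand == "+") "five_utr" else "three_utr"
      out <- rbind(out, .region_df(tx$chrom, left[1], left[2], cls,
                                   tx$transcript_id, tx$gene_symbol))
    }
    if (right[2] > right[1]) {
      cls <- if (tx$strand == "+") "three_utr" else "five_utr"
      out <- rbind(out, .region_df(tx$chrom, right[1], right[2], cls,
                                   tx$transcript_id, tx$gene_symbol))
    }
  }
  # introns wholly outside the CDS span
  if (nrow(exons) > 1) {
    for (i in seq_len(nrow(exons) - 1L)) {
      is_ <- exons$end[i]; ie <- exons$start[i + 1L]
      if (ie <= tx$cds_start) {
        cls <- if (tx$strand == "+") "five_utr_intron" else "three_utr_intron"
      } else if (is_ >= tx$cds_end) {
        cls <- if (tx$strand == "+") "three_utr_intron" else "five_utr_intron"
      } else {
        next
      }
      out <- rbind(out, .region_df(tx$chrom, is_, ie, cls,
                                   tx$transcript_id, tx$gene_symbol))
    }
  }
  rownames(out) <- NULL
  out
}

# Union of CDS exonic bases across a transcript set, per chromosome,
# as a list of IRanges.
.cds_union <- function(all_tx) {
  pieces <- list()
  for (tx in all_tx) {
    if (is.na(tx$cds_start)) next
    s <- pmax(tx$exons$start, tx$cds_start)
    e <- pmin(tx$exons$end, tx$cds_end)
    keep <- e > s
    if (!any(keep)) next
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = tx$chrom, start = s[keep], end = e[keep]
    )
  }
  if (length(pieces) == 0L) return(list())
  df <- do.call(rbind, pieces)
  lapply(split(df, df$chrom), function(d) {
    IRanges::reduce(.ir(d$start, d$end))
  })
}

#' Subtract all CDS bases from a region set
#'
#' Removes every base that is a CDS exonic base of any transcript in
#' `all_tx` from each region. Regions may be split into several intervals;
#' empty remnants are dropped; classification and transcript linkage are
#' preserved.
#'
#' @param regions region data frame (as returned by [extract_utr_regions()]
#'   or [derive_promoter()]).
#' @param all_tx list of [transcript_model()] objects whose CDS bases are
#'   excluded.
#' @return region data frame disjoint from every CDS base.
#' @export
subtract_cds <- function(regions, all_tx) {
  if (nrow(regions) == 0L) return(regions)
  cds <- .cds_union(all_tx)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    cd <- cds[[r$chrom]]
    if (is.null(cd)) {
      out[[i]] <- r
      next
    }
    kept <- IRanges::setdiff(.ir(r$start, r$end), cd)
    if (length(kept) == 0L) next
    kd <- .ir_df(kept)
    out[[i]] <- .region_df(r$chrom, kd$start, kd$end, r$region_class,
                           r$transcript_id, r$gene_symbol)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- .region_df()
  rownames(out) <- NULL
  out
}

#' Build the full near-coding region set
#'
#' Convenience wrapper: derives the promoter and UTR exon/intron regions for
#' every coding transcript and subtracts all CDS bases of all transcripts.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param ccres cCRE data frame (`chrom`, `start`, `end`), or `NULL`.
#' @param cfg a [promoter_config()].
#' @return region data frame.
#' @export
build_near_coding_regions <- function(transcripts, ccres = NULL,
                                      cfg = promoter_config()) {
  parts <- lapply(transcripts, function(tx) {
    rbind(derive_promoter(tx, ccres, cfg), extract_utr_regions(tx))
  })
  subtract_cds(do.call(rbind, parts), transcripts)
}

#' Assign region classes to a variant position
#'
#' Returns every region class whose interval overlaps the variant's
#' reference span (a position may lie in both a promoter and a UTR region
#' where the two overlap). `deep_intronic` is `TRUE` when the variant falls
#' in a UTR-intron region at a distance of more than 20 bases from both
#' flanking exon boundaries (so the 21st intronic base onward).
#'
#' @param chrom,pos,ref variant chromosome, 0-based position, reference
#'   allele (its length defines the affected span).
#' @param regions region data frame.
#' @return list with `region_classes` (character vector, possibly empty),
#'   `deep_intronic` (logical), `transcript_ids` (transcripts whose regions
#'   are hit), and `hits` (the overlapped region rows).
#' @export
assign_region <- function(chrom, pos, ref, regions) {
  pos <- as.integer(pos)
  span_end <- pos + max(1L, nchar(ref))
  hit <- regions[regions$chrom == chrom &
                   regions$start < span_end & pos < regions$end, ,
                 drop = FALSE]
  classes <- unique(hit$region_class)
  deep <- FALSE
  intr <- hit[hit$region_class %in% .INTRON_CLASSES, , drop = FALSE]
  if (nrow(intr) > 0) {
    # distance of the position from the closest exon edge, counting the
    # first intronic base as 1
    d <- pmin(pos - intr$start + 1L, intr$end - pos)
    deep <- any(d > 20L)
  }
  list(
    region_classes = classes,
    deep_intronic = deep,
    transcript_ids = unique(hit$transcript_id),
    hits = hit
  )
}

#' Total bases covered by a region set, per region class
#'
#' @param regions region data frame.
#' @return named numeric vector of base counts (duplicated bases within one
#'   class/transcript combination are counted once per row).
#' @export
region_base_counts <- function(regions) {
  if (nrow(regions) == 0L) return(c(total = 0))
  len <- regions$end - regions$start
  c(total = sum(len), tapply(len, regions$region_class, sum))
}
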