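# Plain-text I/O for the standard formats the pipeline touches. Writers
# emit the formats directly (they are fully specified line formats);
# GFF3/BED reading goes through rtracklayer when available.

#' Write a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @param width line width (default 70).
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits one `mRNA` feature per transcript with `exon` and `CDS`
#' children (1-based closed coordinates, per the format).
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output file.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (tx in transcripts) {
    span <- c(tx$exons$start[1] + 1L, tx$exons$end[nrow(tx$exons)])
    writeLines(sprintf(
      "%s\tnearcoding\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
      tx$chrom, span[1], span[2], tx$strand, tx$transcript_id,
      tx$gene_symbol
    ), con)
    for (i in seq_len(nrow(tx$exons))) {
      writeLines(sprintf(
        "%s\tnearcoding\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        tx$chrom, tx$exons$start[i] + 1L, tx$exons$end[i], tx$strand,
        tx$transcript_id
      ), con)
    }
    if (!is.na(tx$cds_start)) {
      s <- pmax(tx$exons$start, tx$cds_start)
      e <- pmin(tx$exons$end, tx$cds_end)
      keep <- e > s
      for (i in which(keep)) {
        writeLines(sprintf(
          "%s\tnearcoding\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
          tx$chrom, s[i] + 1L, e[i], tx$strand, tx$transcript_id
        ), con)
      }
    }
  }
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Parses `exon` and `CDS` features grouped by their `Parent` (or `ID`)
#' attribute into [transcript_model()] objects. Uses rtracklayer when
#' installed; otherwise falls back to a minimal tab parser sufficient for
#' files written by [write_transcripts_gff3()].
#'
#' @param path GFF3 file.
#' @return list of [transcript_model()] objects.
#' @export
read_transcript_models_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      type = as.character(gr$type),
      parent = vapply(as.list(gr$Parent), function(p) {
        if (length(p)) as.character(p[1]) else NA_character_
      }, character(1)),
      id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
      gene = if (!is.null(gr$gene_name)) as.character(gr$gene_name)
             else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    attr_get <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
      ifelse(lengths(regmatches(a, gregexpr(paste0(key, "=[^;]+"), a))) > 0,
             sub(paste0(key, "="), "", m), NA_character_)
    }
    df <- data.frame(
      chrom = raw$V1, start = raw$V4 - 1L, end = raw$V5,
      strand = raw$V7, type = raw$V3,
      parent = vapply(raw$V9, function(a) {
        m <- regmatches(a, regexpr("Parent=[^;]+", a))
        if (length(m)) sub("Parent=", "", m) else NA_character_
      }, character(1), USE.NAMES = FALSE),
      id = vapply(raw$V9, function(a) {
        m <- regmatches(a, regexpr("ID=[^;]+", a))
        if (length(m)) sub("ID=", "", m) else NA_character_
      }, character(1), USE.NAMES = FALSE),
      gene = vapply(raw$V9, function(a) {
        m <- regmatches(a, regexpr("gene_name=[^;]+", a))
        if (length(m)) sub("gene_name=", "", m) else NA_character_
      }, character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  genes <- stats::setNames(mrna$gene, mrna$id)
  feats <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  lapply(split(feats, feats$parent), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    tid <- d$parent[1]
    transcript_model(
      transcript_id = tid,
      gene_symbol = if (!is.na(genes[tid])) unname(genes[tid]) else tid,
      chrom = d$chrom[1], strand = d$strand[1],
      exons = ex[, c("start", "end")],
      cds_start = if (nrow(cds)) min(cds$start) else NA,
      cds_end = if (nrow(cds)) max(cds$end) else NA
    )
  })
}

#' Write a near-coding region set as BED
#'
#' The BED name field is `transcript_id|region_class`.
#'
#' @param regions region data frame.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s", regions$chrom, regions$start,
                   regions$end, regions$transcript_id,
                   regions$region_class)
  writeLines(lines, path)
  invisible(path)
}

#' Read a near-coding region BED file written by [write_regions_bed()]
#'
#' @param path BED file.
#' @return region data frame.
#' @export
read_regions_bed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)
  name <- strsplit(raw$V4, "|", fixed = TRUE)
  .region_df(raw$V1, raw$V2, raw$V3,
             vapply(name, `[`, "", 2L), vapply(name, `[`, "", 1L),
             gene_symbol = vapply(name, `[`, "", 1L))
}

#' Write a variant table as VCF
#'
#' Score and frequency columns are emitted as INFO keys (`SPLICEAI_MAX`,
#' `CADD_PHRED`, `PHYLOP`, `CLNSIG`, `AF_INT`, `AC_INT`,
#' `AF_GNOMAD_POPMAX`). Positions convert from the package's 0-based
#' convention to the format's 1-based one.
#'
#' @param variants variant data frame (`variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` + optional score columns).
#' @param path output file.
#' @param contigs optional named vector of contig lengths for the header.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  info_keys <- c(
    spliceai_max = "SPLICEAI_MAX", cadd_phred = "CADD_PHRED",
    phylop = "PHYLOP", clinvar_status = "CLNSIG", af_internal = "AF_INT",
    ac_internal = "AC_INT", af_gnomad_popmax = "AF_GNOMAD_POPMAX"
  )
  for (k in names(info_keys)) {
    if (k %in% names(variants)) {
      writeLines(sprintf(
        "##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
        info_keys[[k]],
        if (k == "clinvar_status") "String" else "Float", info_keys[[k]]
      ), con)
    }
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  for (i in seq_len(nrow(variants))) {
    info <- character()
    for (k in names(info_keys)) {
      if (k %in% names(variants) && !is.na(variants[[k]][i])) {
        info <- c(info, paste0(info_keys[[k]], "=", variants[[k]][i]))
      }
    }
    writeLines(sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
      variants$chrom[i], as.integer(variants$pos[i]) + 1L,
      variants$variant_id[i], variants$ref[i], variants$alt[i],
      if (length(info)) paste(info, collapse = ";") else "."
    ), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_variants_vcf()] back into a variant table
#'
#' @param path VCF file.
#' @return variant data frame with 0-based `pos` and score columns.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_keys <- c(
    SPLICEAI_MAX = "spliceai_max", CADD_PHRED = "cadd_phred",
    PHYLOP = "phylop", CLNSIG = "clinvar_status", AF_INT = "af_internal",
    AC_INT = "ac_internal", AF_GNOMAD_POPMAX = "af_gnomad_popmax"
  )
  out <- data.frame(
    variant_id = vapply(f, `[`, "", 3L),
    chrom = vapply(f, `[`, "", 1L),
    pos = as.integer(vapply(f, `[`, "", 2L)) - 1L,
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
  infos <- lapply(f, function(x) {
    kv <- strsplit(strsplit(x[8], ";", fixed = TRUE)[[1]], "=",
                   fixed = TRUE)
    stats::setNames(
      vapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_,
             character(1)),
      vapply(kv, `[`, "", 1L)
    )
  })
  for (key in names(info_keys)) {
    val <- vapply(infos, function(kv) {
      if (key %in% names(kv)) kv[[key]] else NA_character_
    }, character(1))
    out[[info_keys[[key]]]] <-
      if (key == "CLNSIG") val else as.numeric(val)
  }
  out
}

#' Write track elements as BED with attribute columns
#'
#' Columns beyond the interval are emitted as extra tab-separated fields:
#' track, in_core_dhs, ref_affinity, alt_affinity.
#'
#' @param elements track element data frame.
#' @param path output file.
#' @export
write_track_bed <- function(elements, path) {
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s\t%s",
    elements$chrom, elements$start, elements$end, elements$track,
    fmt(elements$in_core_dhs), fmt(elements$ref_affinity),
    fmt(elements$alt_affinity)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Emit a complete synthetic fixture to a directory
#'
#' Writes the genome (FASTA), transcripts (GFF3), near-coding regions
#' (BED), planted variants (VCF), track elements (BED), TF model
#' predictions and truth table (TSV), and the simulated cohort tables
#' (TSV).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
simulate_fixture <- function(spec = fixture_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- make_genome_and_transcripts(spec)
  pv <- plant_variants(spec, gt)
  cohort <- simulate_cohort(spec$cohort, seed = spec$seed)
  regions <- build_near_coding_regions(gt$transcripts, gt$ccres)
  write_fasta(gt$genome, file.path(out_dir, "genome.fa"))
  write_transcripts_gff3(gt$transcripts,
                         file.path(out_dir, "transcripts.gff3"))
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  write_variants_vcf(pv$variants, file.path(out_dir, "variants.vcf"),
                     contigs = c(chrS = nchar(gt$genome[["chrS"]])))
  if (!is.null(pv$track_elements)) {
    write_track_bed(pv$track_elements, file.path(out_dir, "tracks.bed"))
  }
  if (!is.null(pv$tf_predictions)) {
    utils::write.table(pv$tf_predictions,
                       file.path(out_dir, "tf_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(pv$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$participants,
                     file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$king_pairs,
                     file.path(out_dir, "king_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = gt, variants = pv, cohort = cohort,
                 regions = regions))
}
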