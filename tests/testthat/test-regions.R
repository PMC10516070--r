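make_tx <- function(exons, cds_start, cds_end, strand = "+",
                    id = "TX1", gene = "G1", chrom = "toy") {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = exons[, 1], end = exons[, 2]),
                   cds_start, cds_end)
}

test_that("promoter uses the cCRE unchanged when it meets minimal extents", {
  tx <- make_tx(rbind(c(1000, 1400)), 1200, 1380)
  ccre <- data.frame(chrom = "toy", start = 700, end = 1100)
  p <- derive_promoter(tx, ccre)
  expect_equal(c(p$start, p$end), c(700, 1100))
})

test_that("deficient cCRE sides are extended to exactly the minimal extents", {
  tx <- make_tx(rbind(c(1000, 1400)), 1200, 1380)
  ccre <- data.frame(chrom = "toy", start = 900, end = 1020)
  p <- derive_promoter(tx, ccre)
  expect_equal(c(p$start, p$end), c(819, 1067))
  # only the deficient side moves
  ccre2 <- data.frame(chrom = "toy", start = 700, end = 1020)
  p2 <- derive_promoter(tx, ccre2)
  expect_equal(c(p2$start, p2$end), c(700, 1067))
})

test_that("without a TSS-overlapping cCRE the 75th percentiles are used", {
  tx <- make_tx(rbind(c(1000, 1400)), 1200, 1380)
  p <- derive_promoter(tx, NULL)
  expect_equal(c(p$start, p$end), c(734, 1139))
  # a cCRE that misses the TSS is equivalent to no cCRE
  ccre <- data.frame(chrom = "toy", start = 1500, end = 1900)
  p2 <- derive_promoter(tx, ccre)
  expect_equal(c(p2$start, p2$end), c(734, 1139))
  # and one on another chromosome is ignored
  ccre3 <- data.frame(chrom = "other", start = 700, end = 1100)
  p3 <- derive_promoter(tx, ccre3)
  expect_equal(c(p3$start, p3$end), c(734, 1139))
})

test_that("promoter construction is strand-symmetric", {
  L <- 5000
  for (k in 1:20) {
    set.seed(k)
    tss <- sample(1000:3000, 1)
    cc_up <- sample(c(50, 120, 200, 260), 1)
    cc_down <- sample(c(20, 67, 100, 150), 1)
    tx_p <- make_tx(rbind(c(tss, tss + 400)), tss + 100, tss + 200)
    ccre_p <- data.frame(chrom = "toy", start = tss - cc_up,
                         end = tss + cc_down)
    # mirrored world: x -> L - x, strand flipped; interval [s,e) -> [L-e, L-s)
    tx_m <- make_tx(rbind(c(L - (tss + 400 + 1), L - tss)),
                    L - (tss + 200), L - (tss + 100), strand = "-")
    # mirrored transcript's TSS base is L-1-tss
    expect_equal(tx_m$tss, L - 1 - tss)
    ccre_m <- data.frame(chrom = "toy",
                         start = L - (tss + cc_down),
                         end = L - (tss - cc_up))
    p <- derive_promoter(tx_p, ccre_p)
    m <- derive_promoter(tx_m, ccre_m)
    expect_equal(c(m$start, m$end), c(L - p$end, L - p$start))
  }
})

test_that("UTR exons and introns are extracted strand-aware", {
  tx <- make_tx(rbind(c(0, 100), c(200, 300)), 250, 300)
  r <- extract_utr_regions(tx)
  five <- r[r$region_class == "five_utr", ]
  expect_equal(unname(as.matrix(five[, c("start", "end")])),
               rbind(c(0, 100), c(200, 250)))
  expect_equal(r[r$region_class == "five_utr_intron", c("start", "end")],
               data.frame(start = 100, end = 200),
               ignore_attr = TRUE)
  expect_false("three_utr" %in% r$region_class)

  # minus strand mirrors the classification
  txm <- make_tx(rbind(c(0, 100), c(200, 300)), 0, 50, strand = "-")
  rm_ <- extract_utr_regions(txm)
  fivem <- rm_[rm_$region_class == "five_utr", ]
  expect_equal(unname(as.matrix(fivem[, c("start", "end")])),
               rbind(c(50, 100), c(200, 300)))
  expect_equal(rm_[rm_$region_class == "five_utr_intron",
                   c("start", "end")],
               data.frame(start = 100, end = 200), ignore_attr = TRUE)

  # single-exon transcript: UTRs but no introns
  tx1 <- make_tx(rbind(c(0, 300)), 100, 200)
  r1 <- extract_utr_regions(tx1)
  expect_setequal(r1$region_class, c("five_utr", "three_utr"))

  # non-coding transcript is rejected
  txnc <- transcript_model("TXN", "GN", "toy", "+",
                           data.frame(start = 0, end = 100))
  expect_error(extract_utr_regions(txnc), "non-coding")
})

test_that("CDS subtraction splits, preserves labels, never adds bases", {
  tx1 <- make_tx(rbind(c(700, 1100)), 750, 1050)
  other <- make_tx(rbind(c(800, 900)), 800, 900, id = "TX2")
  promoter <- data.frame(chrom = "toy", start = 700, end = 1100,
                         region_class = "promoter", transcript_id = "TX1",
                         gene_symbol = "G1", stringsAsFactors = FALSE)
  out <- subtract_cds(promoter, list(other))
  expect_equal(unname(as.matrix(out[, c("start", "end")])),
               rbind(c(700, 800), c(900, 1100)))
  expect_true(all(out$region_class == "promoter"))
  expect_true(all(out$transcript_id == promoter$transcript_id[1]))

  # no overlap -> identity
  out2 <- subtract_cds(promoter, list(make_tx(rbind(c(5000, 5100)),
                                              5000, 5100, id = "TX3")))
  expect_equal(out2, promoter)

  # fully covered region is dropped and the base count shrinks by its length
  region <- promoter
  region$start <- 820; region$end <- 880
  out3 <- subtract_cds(region, list(other))
  expect_equal(nrow(out3), 0)
  before <- region_base_counts(rbind(promoter, region))[["total"]]
  after <- region_base_counts(subtract_cds(rbind(promoter, region),
                                           list(other)))[["total"]]
  expect_lt(after, before)
  expect_equal(before - after, 100 + 60)
})

test_that("region assignment reports overlaps and deep-intronic status", {
  regions <- rbind(
    data.frame(chrom = "toy", start = 100, end = 300,
               region_class = "promoter", transcript_id = "T1",
               gene_symbol = "G1"),
    data.frame(chrom = "toy", start = 200, end = 400,
               region_class = "five_utr", transcript_id = "T1",
               gene_symbol = "G1"),
    data.frame(chrom = "toy", start = 400, end = 600,
               region_class = "five_utr_intron", transcript_id = "T1",
               gene_symbol = "G1")
  )
  both <- assign_region("toy", 250, "A", regions)
  expect_setequal(both$region_classes, c("promoter", "five_utr"))
  expect_false(both$deep_intronic)

  # 17 bases from the acceptor end of the intron: not deep
  near <- assign_region("toy", 600 - 17, "A", regions)
  expect_equal(near$region_classes, "five_utr_intron")
  expect_false(near$deep_intronic)

  # 50 bases from both ends: deep
  deep <- assign_region("toy", 450, "A", regions)
  expect_true(deep$deep_intronic)
  # 21st base in from the donor is the first deep one
  expect_false(assign_region("toy", 419, "A", regions)$deep_intronic)
  expect_true(assign_region("toy", 420, "A", regions)$deep_intronic)

  none <- assign_region("toy", 5000, "A", regions)
  expect_length(none$region_classes, 0)
})

test_that("region builder agrees with a per-base brute-force labeller", {
  for (seed in 1:4) {
    set.seed(seed)
    txs <- random_toy_transcripts(n_tx = 3, chrom_len = 6000)
    promoters <- do.call(rbind, lapply(txs, derive_promoter, ccres = NULL))
    regions <- build_near_coding_regions(txs, ccres = NULL)
    want <- oracle_label_bases(6000, txs, promoters)
    got <- regions_to_base_labels(6000, regions)
    mism <- sum(vapply(seq_len(6000), function(b) {
      !setequal(got[[b]], want[[b]])
    }, logical(1)))
    expect_equal(mism, 0)
    # zero CDS leakage, brute force
    for (tx in txs) {
      s <- pmax(tx$exons$start, tx$cds_start)
      e <- pmin(tx$exons$end, tx$cds_end)
      for (i in which(e > s)) {
        for (b0 in s[i]:(e[i] - 1L)) {
          expect_length(got[[b0 + 1L]], 0)
        }
      }
    }
  }
})
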