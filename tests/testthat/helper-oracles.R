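# Independent brute-force oracles. These deliberately use naive explicit
# loops and closed forms, not the package's vectorised code paths.

# ---- upstream-ORF enumeration oracle -------------------------------------

# All 0-based AUG starts before cds_offset, by per-position character scan.
oracle_find_augs <- function(seq, cds_offset) {
  ch <- strsplit(seq, "")[[1]]
  out <- integer()
  i <- 1L
  while (i <= cds_offset) {             # 1-based i -> 0-based i-1
    if (i + 2L <= length(ch) &&
        ch[i] == "A" && ch[i + 1L] == "T" && ch[i + 2L] == "G") {
      out <- c(out, i - 1L)
    }
    i <- i + 1L
  }
  out
}

# First in-frame stop codon fully 5' of cds_offset; NA if none.
oracle_first_stop <- function(seq, aug0, cds_offset) {
  ch <- strsplit(seq, "")[[1]]
  j <- aug0 + 3L
  while (j + 3L <= cds_offset) {
    codon <- paste0(ch[j + 1L], ch[j + 2L], ch[j + 3L])
    if (codon %in% c("TAA", "TAG", "TGA")) return(j)
    j <- j + 3L
  }
  NA_integer_
}

oracle_outcome <- function(seq, aug0, cds_offset) {
  s <- oracle_first_stop(seq, aug0, cds_offset)
  if (!is.na(s)) return(list(outcome = "uORF", stop = s))
  if ((cds_offset - aug0) %% 3L == 0L) {
    list(outcome = "inFrame_oORF", stop = NA_integer_)
  } else {
    list(outcome = "outOfFrame_oORF", stop = NA_integer_)
  }
}

oracle_kozak_full <- function(seq, aug0) {
  ch <- strsplit(seq, "")[[1]]
  m3_ok <- aug0 >= 3L && ch[aug0 - 2L] %in% c("A", "G")
  p4_ok <- aug0 + 4L <= length(ch) && ch[aug0 + 4L] == "G"
  if (m3_ok && p4_ok) "strong" else if (m3_ok || p4_ok) "moderate"
  else "weak"
}

# Full event oracle mirroring the annotation semantics with naive loops.
oracle_annotate <- function(seq, cds_offset, pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (pos >= cds_offset || pos + lr > cds_offset) {
    return(data.frame(effect_class = character(),
                      orf_outcome = character(), kozak = character(),
                      uaug_position = integer()))
  }
  ch <- strsplit(seq, "")[[1]]
  alt_ch <- c(if (pos > 0) ch[1:pos] else character(),
              strsplit(alt, "")[[1]],
              if (pos + lr < length(ch)) ch[(pos + lr + 1L):length(ch)]
              else character())
  alt_seq <- paste(alt_ch, collapse = "")
  cds_alt <- cds_offset + la - lr
  r2a <- function(p) if (p < pos) p else if (p >= pos + lr) p + la - lr
  else NA_integer_
  a2r <- function(p) if (p < pos) p else if (p >= pos + la) p - la + lr
  else NA_integer_
  ref_augs <- oracle_find_augs(seq, cds_offset)
  alt_augs <- oracle_find_augs(alt_seq, cds_alt)
  rows <- list()
  push <- function(cls, o, k, at) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect_class = cls, orf_outcome = o, kozak = k, uaug_position = at,
      stringsAsFactors = FALSE
    )
  }
  for (a in alt_augs) {
    r <- a2r(a)
    if (is.na(r) || !(r %in% ref_augs)) {
      oc <- oracle_outcome(alt_seq, a, cds_alt)
      push("uAUG_gain", oc$outcome, oracle_kozak_full(alt_seq, a), a)
    }
  }
  for (r in ref_augs) {
    a <- r2a(r)
    if (is.na(a) || !(a %in% alt_augs)) {
      oc <- oracle_outcome(seq, r, cds_offset)
      push("uAUG_loss", oc$outcome, oracle_kozak_full(seq, r), r)
    }
  }
  fs <- (la - lr) %% 3L != 0L
  for (r in ref_augs) {
    a <- r2a(r)
    if (is.na(a) || !(a %in% alt_augs)) next
    oc_ref <- oracle_outcome(seq, r, cds_offset)
    if (oc_ref$outcome != "uORF") next
    s <- oc_ref$stop
    hits_stop <- pos < s + 3L && pos + max(1L, lr) > s
    if (hits_stop) {
      oc_alt <- oracle_outcome(alt_seq, a, cds_alt)
      same <- !is.na(oc_alt$stop) && !is.na(a2r(oc_alt$stop)) &&
        a2r(oc_alt$stop) == s
      if (!same) {
        push("uSTOP_loss", oc_alt$outcome,
             oracle_kozak_full(alt_seq, a), a)
      }
    } else if (fs && pos >= r + 3L && pos + lr <= s) {
      oc_alt <- oracle_outcome(alt_seq, a, cds_alt)
      push("uFrameshift", oc_alt$outcome,
           oracle_kozak_full(alt_seq, a), a)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(effect_class = character(),
                      orf_outcome = character(), kozak = character(),
                      uaug_position = integer()))
  }
  do.call(rbind, rows)
}

# canonical ordering so data frames can be compared
sort_consequences <- function(df) {
  df <- df[order(df$effect_class, df$uaug_position, df$orf_outcome), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# random 5'UTR/CDS test case generator
random_utr_case <- function() {
  utr_len <- sample(20:70, 1)
  utr <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
               collapse = "")
  n_codons <- sample(3:8, 1)
  body <- paste(sample(c("GCT", "GCC", "AAA", "GGA", "CTT"), n_codons,
                       replace = TRUE), collapse = "")
  seq <- paste0(utr, "ATG", body, "TAA")
  kind <- sample(c("snv", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2))
  if (kind == "snv") {
    pos <- sample(0:(utr_len - 1L), 1)
    ref <- substr(seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  } else if (kind == "ins") {
    pos <- sample(0:(utr_len - 1L), 1)
    ref <- substr(seq, pos + 1L, pos + 1L)
    alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                    sample(1:4, 1), replace = TRUE),
                             collapse = ""))
  } else {
    dlen <- sample(1:4, 1)
    pos <- sample(0:(utr_len - 1L - dlen), 1)
    ref <- substr(seq, pos + 1L, pos + 1L + dlen)
    alt <- substr(ref, 1L, 1L)
  }
  list(seq = seq, cds_offset = utr_len, pos = pos, ref = ref, alt = alt)
}

# ---- Fisher / hypergeometric oracle --------------------------------------

# Two-sided Fisher P by explicit closed-form hypergeometric probabilities.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n || m + n == 0) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- numeric(hi - lo + 1L)
  for (x in lo:hi) {
    probs[x - lo + 1L] <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# ---- per-base region labelling oracle ------------------------------------

# Labels every base of a toy chromosome by scanning each transcript
# directly; returns a set of "class:transcript" strings per base.
oracle_label_bases <- function(chrom_len, transcripts, promoters) {
  labels <- vector("list", chrom_len)
  for (tx in transcripts) {
    exonic <- logical(chrom_len)
    for (i in seq_len(nrow(tx$exons))) {
      exonic[(tx$exons$start[i] + 1L):tx$exons$end[i]] <- TRUE
    }
    span <- c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])
    for (b0 in span[1]:(span[2] - 1L)) {
      b <- b0 + 1L
      in_span <- TRUE
      left_of_cds <- b0 < tx$cds_start
      right_of_cds <- b0 >= tx$cds_end
      if (exonic[b]) {
        if (left_of_cds) {
          cls <- if (tx$strand == "+") "five_utr" else "three_utr"
        } else if (right_of_cds) {
          cls <- if (tx$strand == "+") "three_utr" else "five_utr"
        } else {
          cls <- NA
        }
      } else {
        # intronic: which intron?
        intr <- NULL
        for (i in seq_len(nrow(tx$exons) - 1L)) {
          if (b0 >= tx$exons$end[i] && b0 < tx$exons$start[i + 1L]) {
            intr <- c(tx$exons$end[i], tx$exons$start[i + 1L])
          }
        }
        if (intr[2] <= tx$cds_start) {
          cls <- if (tx$strand == "+") "five_utr_intron" else
            "three_utr_intron"
        } else if (intr[1] >= tx$cds_end) {
          cls <- if (tx$strand == "+") "three_utr_intron" else
            "five_utr_intron"
        } else {
          cls <- NA
        }
      }
      if (!is.na(cls)) {
        labels[[b]] <- c(labels[[b]], paste0(cls, ":", tx$transcript_id))
      }
    }
  }
  for (k in seq_len(nrow(promoters))) {
    p <- promoters[k, ]
    for (b0 in p$start:(p$end - 1L)) {
      labels[[b0 + 1L]] <-
        c(labels[[b0 + 1L]], paste0("promoter:", p$transcript_id))
    }
  }
  # CDS subtraction
  for (tx in transcripts) {
    for (i in seq_len(nrow(tx$exons))) {
      s <- max(tx$exons$start[i], tx$cds_start)
      e <- min(tx$exons$end[i], tx$cds_end)
      if (e > s) for (b0 in s:(e - 1L)) labels[b0 + 1L] <- list(NULL)
    }
  }
  labels
}

# region data frame -> the same per-base representation
regions_to_base_labels <- function(chrom_len, regions) {
  labels <- vector("list", chrom_len)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (b0 in r$start:(r$end - 1L)) {
      labels[[b0 + 1L]] <- c(labels[[b0 + 1L]],
                             paste0(r$region_class, ":", r$transcript_id))
    }
  }
  labels
}

# random small transcript set on a toy chromosome
random_toy_transcripts <- function(n_tx = 4, chrom_len = 8000) {
  slot <- chrom_len %/% n_tx
  lapply(seq_len(n_tx), function(i) {
    o <- (i - 1L) * slot + 400L
    n_ex <- sample(2:4, 1)
    lens <- sample(40:120, n_ex, replace = TRUE)
    gaps <- sample(30:100, n_ex - 1L, replace = TRUE)
    starts <- o + cumsum(c(0L, lens[-n_ex] + gaps))
    ends <- starts + lens
    total <- sum(lens)
    cds_lo_t <- sample(seq_len(total %/% 3), 1)
    cds_hi_t <- cds_lo_t + sample(seq_len(total - cds_lo_t - 1L), 1)
    # map transcript-space (genomic-order) offsets to genomic coords
    exonic <- unlist(lapply(seq_len(n_ex), function(j) {
      seq.int(starts[j], ends[j] - 1L)
    }))
    transcript_model(
      transcript_id = sprintf("T%d", i), gene_symbol = sprintf("G%d", i),
      chrom = "toy", strand = sample(c("+", "-"), 1),
      exons = data.frame(start = starts, end = ends),
      cds_start = exonic[cds_lo_t], cds_end = exonic[cds_hi_t] + 1L
    )
  })
}
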