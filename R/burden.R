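# Cohort construction and burden testing: genotype QC, ancestry Z-score
# outlier removal, relatedness pruning, 1:1 sex/ancestry matching,
# carrier Fisher tests with Bonferroni correction, and iterative power
# estimation.

#' Genotype-level QC for aggregated variant calls
#'
#' Per-call pass requires GQ >= 20, DP >= 10, heterozygous allele balance
#' within \[0.2, 0.8\] and homozygous allele balance <= 0.02. A variant is
#' dropped entirely when its missingness across all participants exceeds
#' 5%, or when 25% or more of the calls in cases fail the per-call
#' filters.
#'
#' @param calls long-format data frame with columns `variant_id`,
#'   `participant_id`, `is_case` (logical), `genotype` (`"het"`, `"hom"`,
#'   `"ref"`, `"missing"`), `gq`, `dp`, `ab`.
#' @param max_missingness,max_case_fail proportions (defaults 0.05, 0.25).
#' @return character vector of retained `variant_id`s.
#' @export
genotype_qc <- function(calls, max_missingness = 0.05,
                        max_case_fail = 0.25) {
  if (nrow(calls) == 0L) return(character())
  miss <- calls$genotype == "missing"
  pass <- !miss &
    calls$gq >= 20 & calls$dp >= 10 &
    ifelse(calls$genotype == "het", calls$ab >= 0.2 & calls$ab <= 0.8, TRUE) &
    ifelse(calls$genotype == "hom", calls$ab <= 0.02, TRUE)
  keep <- vapply(split(seq_len(nrow(calls)), calls$variant_id), function(i) {
    m <- mean(miss[i])
    ci <- i[calls$is_case[i]]
    case_fail <- if (length(ci)) mean(!pass[ci]) else 0
    m <= max_missingness && case_fail < max_case_fail
  }, logical(1))
  names(keep)[keep]
}

#' Drop per-participant variant-count outliers within ancestry groups
#'
#' Within each genetically-inferred ancestry group, computes
#' z = (x - mu) / sigma where x is the participant's variant count and mu,
#' sigma are the group mean and (sample) standard deviation. Participants
#' with |z| >= 2 are dropped (the cutoff is inclusive). Groups with zero
#' variance keep all members, with a warning.
#'
#' @param counts data frame with columns `participant_id`, `ancestry`,
#'   `count`.
#' @param cutoff absolute Z cutoff (default 2).
#' @return `counts` restricted to kept participants, with a `z` column.
#' @export
zscore_filter <- function(counts, cutoff = 2) {
  out <- lapply(split(counts, counts$ancestry), function(g) {
    mu <- mean(g$count)
    sigma <- stats::sd(g$count)
    if (is.na(sigma) || sigma == 0) {
      warning("ancestry group '", g$ancestry[1],
              "' has zero variance; all members kept")
      g$z <- 0
      return(g)
    }
    g$z <- (g$count - mu) / sigma
    g[abs(g$z) < cutoff, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prune related participants by kinship coefficient
#'
#' Iteratively removes one randomly chosen participant from a randomly
#' chosen remaining pair with a KING kinship coefficient at or above the
#' threshold (0.0442, third-degree relatedness), until no such pair
#' remains. The removal sequence is reproducible for a given seed.
#'
#' @param participant_ids character vector of candidate participants.
#' @param king_pairs data frame with columns `id1`, `id2`, `king`.
#' @param threshold kinship threshold (default 0.0442).
#' @param seed integer seed.
#' @return character vector of retained participant ids.
#' @export
prune_related <- function(participant_ids, king_pairs, threshold = 0.0442,
                          seed = 1L) {
  kept <- unique(as.character(participant_ids))
  edges <- king_pairs[king_pairs$king >= threshold &
                        king_pairs$id1 %in% kept &
                        king_pairs$id2 %in% kept, , drop = FALSE]
  .with_seed(seed, {
    while (nrow(edges) > 0) {
      e <- edges[sample.int(nrow(edges), 1L), ]
      drop <- if (stats::runif(1) < 0.5) e$id1 else e$id2
      kept <- setdiff(kept, drop)
      edges <- edges[edges$id1 != drop & edges$id2 != drop, , drop = FALSE]
    }
  })
  kept
}

#' Match cases 1:1 to controls on sex and ancestry
#'
#' Ancestry groups are first restricted to those with more than
#' `min_stratum` cases and more than `min_stratum` controls; cases are
#' restricted to those with at most `max_panel_genes` assigned green
#' dominant panel genes (when a `n_panel_genes` column is present). Within
#' each (sex, ancestry) stratum, each case is assigned a uniformly random
#' eligible control with replacement (so one control may serve several
#' cases), never sharing a family ID; cases with no eligible control are
#' dropped with a message.
#'
#' @param cases,controls data frames with columns `participant_id`,
#'   `sex`, `ancestry`, `family_id` (cases may carry `n_panel_genes`).
#' @param seed integer seed making the pairing reproducible.
#' @param min_stratum ancestry size floor (default 200).
#' @param max_panel_genes cap on assigned panel genes per case (default
#'   100).
#' @return data frame of pairs: `case_id`, `control_id`, `sex`,
#'   `ancestry`.
#' @export
match_case_control <- function(cases, controls, seed = 1L,
                               min_stratum = 200L, max_panel_genes = 100L) {
  if ("n_panel_genes" %in% names(cases)) {
    cases <- cases[cases$n_panel_genes <= max_panel_genes, , drop = FALSE]
  }
  anc_ok <- intersect(
    names(which(table(cases$ancestry) > min_stratum)),
    names(which(table(controls$ancestry) > min_stratum))
  )
  cases <- cases[cases$ancestry %in% anc_ok, , drop = FALSE]
  controls <- controls[controls$ancestry %in% anc_ok, , drop = FALSE]
  pairs <- list()
  .with_seed(seed, {
    strata <- unique(cases[, c("sex", "ancestry")])
    for (k in seq_len(nrow(strata))) {
      sx <- strata$sex[k]; an <- strata$ancestry[k]
      cs <- cases[cases$sex == sx & cases$ancestry == an, , drop = FALSE]
      ct <- controls[controls$sex == sx & controls$ancestry == an, ,
                     drop = FALSE]
      cs <- cs[sample.int(nrow(cs)), , drop = FALSE]
      for (i in seq_len(nrow(cs))) {
        elig <- ct[ct$family_id != cs$family_id[i], , drop = FALSE]
        if (nrow(elig) == 0L) {
          message("case ", cs$participant_id[i],
                  " has no eligible control; dropped")
          next
        }
        j <- sample.int(nrow(elig), 1L)
        pairs[[length(pairs) + 1L]] <- data.frame(
          case_id = cs$participant_id[i],
          control_id = elig$participant_id[j],
          sex = sx, ancestry = an, stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) {
    out <- data.frame(case_id = character(), control_id = character(),
                      sex = character(), ancestry = character())
  }
  rownames(out) <- NULL
  out
}

# Two-sided Fisher exact P for a 2x2 table by hypergeometric enumeration:
# the sum of probabilities of all tables (with the observed margins) at
# most as probable as the observed one, using the conventional 1 + 1e-7
# relative tolerance on the comparison.
.fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0L || k == 0L || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Carrier burden test (2x2 Fisher exact test)
#'
#' Compares the number of carrier cases (participants with one or more
#' qualifying prioritised variants) to carrier controls. The two-sided
#' exact P-value is computed by hypergeometric enumeration over all tables
#' with the observed margins (summing the probabilities of tables at most
#' as probable as the observed one). The odds ratio is the sample odds
#' ratio (a d)/(b c); the 95% CI is obtained by conditional-likelihood
#' inversion (as in [stats::fisher.test()]). The per-test significance
#' threshold is `family_alpha / n_tests` (Bonferroni).
#'
#' @param case_carrier_flags,control_carrier_flags logical vectors, one
#'   element per participant.
#' @param annotation_label label of the annotation being tested.
#' @param n_tests number of annotation tests in the family (default 16).
#' @param family_alpha family-wise alpha (default 0.05).
#' @return object of class `burden_result`: a list with `annotation_label`,
#'   the table cells `a`, `b`, `c`, `d`, `odds_ratio` (NA with
#'   `or_undefined = TRUE` on a zero margin), `p_value`, `ci95`,
#'   `adjusted_alpha`, `significant`.
#' @export
fisher_burden <- function(case_carrier_flags, control_carrier_flags,
                          annotation_label = "combined", n_tests = 16L,
                          family_alpha = 0.05) {
  if (length(case_carrier_flags) == 0L) {
    stop("no case participants; burden test undefined")
  }
  if (length(control_carrier_flags) == 0L) {
    stop("no control participants; burden test undefined")
  }
  a <- sum(case_carrier_flags)
  b <- sum(!case_carrier_flags)
  c <- sum(control_carrier_flags)
  d <- sum(!control_carrier_flags)
  p <- .fisher_p_two_sided(a, b, c, d)
  or_undefined <- (b == 0L || c == 0L)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else NA_real_
  ci <- tryCatch(
    as.numeric(stats::fisher.test(matrix(c(a, b, c, d), 2,
                                         byrow = TRUE))$conf.int),
    error = function(e) c(NA_real_, NA_real_)
  )
  adjusted_alpha <- bonferroni_alpha(family_alpha, n_tests)$exact
  structure(
    list(
      annotation_label = annotation_label,
      a = a, b = b, c = c, d = d,
      odds_ratio = or, or_undefined = or_undefined,
      p_value = p, ci95 = ci,
      adjusted_alpha = adjusted_alpha,
      significant = p <= adjusted_alpha
    ),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    paste0("<burden_result> %s: carriers %d/%d cases vs %d/%d controls; ",
           "OR=%s P=%.4g (per-test alpha %.4g)\n"),
    x$annotation_label, x$a, x$a + x$b, x$c, x$c + x$d,
    if (is.na(x$odds_ratio)) "undef" else sprintf("%.3g", x$odds_ratio),
    x$p_value, x$adjusted_alpha
  ))
  invisible(x)
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param family_alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (default 16, one per region/variant
#'   annotation label).
#' @return list with `exact` (family_alpha / n_tests) and `display` (the
#'   same value rounded to two significant figures).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 16L) {
  stopifnot(n_tests >= 1)
  exact <- family_alpha / n_tests
  list(exact = exact, display = signif(exact, 2))
}

#' Cohort size required for significance at fixed carrier proportions
#'
#' Starting from an observed 2x2 carrier table, grows the case and control
#' cohorts by one participant each per step, holding the observed carrier
#' proportions fixed (carrier counts are rounded to the nearest integer at
#' each size), recomputing the exact P-value at each step, and returns the
#' first cohort sizes at which P <= `alpha`.
#'
#' @param a,b,c,d observed carrier cases, non-carrier cases, carrier
#'   controls, non-carrier controls. The case carrier proportion must
#'   exceed the control proportion.
#' @param alpha target P-value threshold.
#' @param max_n safety cap on the case cohort size (default 1e6).
#' @return list with `n_cases`, `n_controls`, `p_value`, `steps`; when the
#'   proportions are equal (never significant) all elements are `NA` and
#'   `reason` explains why.
#' @export
required_n <- function(a, b, c, d, alpha = 0.0031, max_n = 1e6) {
  n1 <- a + b
  n2 <- c + d
  p_case <- a / n1
  p_ctrl <- c / n2
  if (p_case <= p_ctrl) {
    return(list(n_cases = NA_integer_, n_controls = NA_integer_,
                p_value = NA_real_, steps = NA_integer_,
                reason = "case carrier proportion does not exceed controls"))
  }
  step <- 0L
  repeat {
    m1 <- n1 + step
    m2 <- n2 + step
    aa <- round(p_case * m1)
    cc <- round(p_ctrl * m2)
    p <- .fisher_p_two_sided(aa, m1 - aa, cc, m2 - cc)
    if (p <= alpha) {
      return(list(n_cases = m1, n_controls = m2, p_value = p,
                  steps = step, reason = NULL))
    }
    step <- step + 1L
    if (n1 + step > max_n) {
      stop("required_n exceeded max_n without reaching alpha")
    }
  }
}
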