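test_that("per-call and per-variant genotype QC thresholds apply", {
  call <- function(vid, pid, case, gt, gq, dp, ab) {
    data.frame(variant_id = vid, participant_id = pid, is_case = case,
               genotype = gt, gq = gq, dp = dp, ab = ab,
               stringsAsFactors = FALSE)
  }
  # clean variant: 10 case calls, all passing
  clean <- do.call(rbind, lapply(1:10, function(i) {
    call("v1", paste0("p", i), TRUE, "het", 25, 12, 0.5)
  }))
  expect_equal(genotype_qc(clean), "v1")
  # 3 of 10 case calls failing AB: 30% >= 25% -> dropped
  bad <- clean
  bad$ab[1:3] <- 0.15
  expect_equal(genotype_qc(bad), character())
  # 2 of 10 failing: 20% < 25% -> kept
  ok <- clean
  ok$ab[1:2] <- 0.15
  expect_equal(genotype_qc(ok), "v1")
  # homozygous AB rule
  hom <- clean
  hom$genotype <- "hom"; hom$ab <- 0.01
  expect_equal(genotype_qc(hom), "v1")
  hom$ab[1:3] <- 0.05
  expect_equal(genotype_qc(hom), character())
  # missingness > 5% drops the variant
  missy <- clean
  missy$genotype[1] <- "missing"
  expect_equal(genotype_qc(missy), character())
  expect_equal(genotype_qc(clean[0, ]), character())
})

test_that("Z-score filter drops outliers at |z| >= 2 within ancestry", {
  # all-but-one zero in a group of 6: outlier z = 5/sqrt(6) = 2.041 >= 2
  g6 <- data.frame(participant_id = paste0("p", 1:6), ancestry = "EUR",
                   count = c(0, 0, 0, 0, 0, 60))
  expect_equal((60 - 10) / sd(g6$count), 5 / sqrt(6), tolerance = 1e-12)
  kept6 <- zscore_filter(g6)
  expect_false("p6" %in% kept6$participant_id)
  expect_equal(nrow(kept6), 5)
  # in a group of 5 the same shape only reaches z = 4/sqrt(5) = 1.789: kept
  g5 <- data.frame(participant_id = paste0("q", 1:5), ancestry = "EUR",
                   count = c(0, 0, 0, 0, 50))
  expect_equal(nrow(zscore_filter(g5)), 5)
  # equal counts: zero variance, all kept with a warning
  eq <- data.frame(participant_id = paste0("r", 1:4), ancestry = "SAS",
                   count = rep(7, 4))
  expect_warning(kept <- zscore_filter(eq), "zero variance")
  expect_equal(nrow(kept), 4)
  # groups are independent
  both <- rbind(g6, eq)
  expect_warning(k2 <- zscore_filter(both), "zero variance")
  expect_equal(nrow(k2), 9)
})

test_that("relatedness pruning removes members until no edge remains", {
  pairs <- data.frame(id1 = "a", id2 = "b", king = 0.05)
  kept <- prune_related(c("a", "b", "c"), pairs, seed = 1)
  expect_length(kept, 2)
  expect_true("c" %in% kept)
  # below threshold: identity
  low <- data.frame(id1 = "a", id2 = "b", king = 0.01)
  expect_setequal(prune_related(c("a", "b"), low, seed = 1), c("a", "b"))
  # a related triangle needs at least two removals
  tri <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                    king = 0.2)
  kept_tri <- prune_related(c("a", "b", "c"), tri, seed = 3)
  expect_length(kept_tri, 1)
  # post-hoc: no remaining pair at or above threshold; deterministic
  set.seed(99)
  ids <- paste0("p", 1:30)
  kp <- data.frame(id1 = sample(ids, 40, TRUE), id2 = sample(ids, 40, TRUE),
                   king = runif(40, 0, 0.2))
  kp <- kp[kp$id1 != kp$id2, ]
  k1 <- prune_related(ids, kp, seed = 7)
  k2 <- prune_related(ids, kp, seed = 7)
  expect_identical(k1, k2)
  left <- kp[kp$id1 %in% k1 & kp$id2 %in% k1, ]
  expect_true(all(left$king < 0.0442))
})

test_that("matching pairs on sex and ancestry, never within a family", {
  cases <- data.frame(
    participant_id = c("c1", "c2", "c3"),
    sex = c("XX", "XX", "XY"), ancestry = "EUR",
    family_id = c("f1", "f2", "f3"), stringsAsFactors = FALSE
  )
  controls <- data.frame(
    participant_id = c("k1", "k2"),
    sex = c("XX", "XY"), ancestry = "EUR",
    family_id = c("f9", "f3"), stringsAsFactors = FALSE
  )
  pairs <- match_case_control(cases, controls, seed = 1, min_stratum = 0)
  # both XX cases share the single XX control (reuse with replacement)
  expect_equal(sum(pairs$control_id == "k1"), 2)
  # c3's only sex/ancestry match shares its family: dropped
  expect_false("c3" %in% pairs$case_id)
  for (i in seq_len(nrow(pairs))) {
    ca <- cases[cases$participant_id == pairs$case_id[i], ]
    co <- controls[controls$participant_id == pairs$control_id[i], ]
    expect_equal(ca$sex, co$sex)
    expect_equal(ca$ancestry, co$ancestry)
    expect_false(ca$family_id == co$family_id)
  }
})

test_that("ancestry strata below the size floor are excluded entirely", {
  set.seed(5)
  cases <- data.frame(
    participant_id = paste0("c", 1:500),
    sex = sample(c("XX", "XY"), 500, TRUE),
    ancestry = rep(c("EUR", "AFR"), c(300, 200)),
    family_id = paste0("fc", 1:500), stringsAsFactors = FALSE
  )
  controls <- data.frame(
    participant_id = paste0("k", 1:400),
    sex = sample(c("XX", "XY"), 400, TRUE),
    ancestry = rep(c("EUR", "AFR"), c(250, 150)),
    family_id = paste0("fk", 1:400), stringsAsFactors = FALSE
  )
  pairs <- match_case_control(cases, controls, seed = 2)
  # AFR has only 150 controls (< 200): the whole stratum is excluded
  expect_false(any(pairs$ancestry == "AFR"))
  expect_true(all(pairs$ancestry == "EUR"))
})

test_that("matching invariants hold on a simulated cohort", {
  sim <- simulate_cohort(list(n_cases = 400, n_controls = 400,
                              carrier_p_case = 0.1,
                              carrier_p_control = 0.05,
                              ancestry_mix = c(EUR = 0.7, SAS = 0.3),
                              related_pairs = 0), seed = 11)
  p <- sim$participants
  pairs <- match_case_control(p[p$affected, ], p[!p$affected, ],
                              seed = 3, min_stratum = 50)
  expect_gt(nrow(pairs), 0)
  idx <- match(pairs$case_id, p$participant_id)
  jdx <- match(pairs$control_id, p$participant_id)
  expect_equal(p$sex[idx], p$sex[jdx])
  expect_equal(p$ancestry[idx], p$ancestry[jdx])
  expect_true(all(p$family_id[idx] != p$family_id[jdx]))
  # reproducible under the same seed
  pairs2 <- match_case_control(p[p$affected, ], p[!p$affected, ],
                               seed = 3, min_stratum = 50)
  expect_identical(pairs, pairs2)
})

test_that("the carrier Fisher test matches symmetry and flags zero margins", {
  r <- fisher_burden(rep(c(TRUE, FALSE), each = 5),
                     rep(c(TRUE, FALSE), each = 5))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_false(r$or_undefined)

  # all cases carriers, no control carriers
  r2 <- fisher_burden(rep(TRUE, 8), rep(FALSE, 8))
  expect_true(r2$or_undefined)
  expect_true(is.na(r2$odds_ratio))
  expect_equal(r2$p_value, oracle_fisher_p(8, 0, 0, 8), tolerance = 1e-12)

  # cross-check a representative table against the closed-form oracle
  # and the reference implementation
  f <- fisher_burden(rep(c(TRUE, FALSE), c(10, 90)),
                     rep(c(TRUE, FALSE), c(2, 98)))
  expect_equal(f$p_value, oracle_fisher_p(10, 90, 2, 98),
               tolerance = 1e-12)
  expect_equal(f$p_value,
               stats::fisher.test(matrix(c(10, 90, 2, 98), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_error(fisher_burden(logical(), logical()), "no case")
})

test_that("Bonferroni adjustment reports exact and two-sig-fig values", {
  b <- bonferroni_alpha(0.05, 16)
  expect_equal(b$exact, 0.003125)
  expect_equal(b$display, 0.0031)
  expect_equal(bonferroni_alpha(0.05, 1)$exact, 0.05)
  expect_equal(bonferroni_alpha(0.05, 10)$exact, 0.005)
})

test_that("required_n reproduces an explicit-loop scan and honours alpha", {
  # independent re-implementation with explicit loops
  scan_required <- function(a, b, c, d, alpha) {
    p_case <- a / (a + b); p_ctrl <- c / (c + d)
    s <- 0
    repeat {
      m1 <- a + b + s; m2 <- c + d + s
      aa <- round(p_case * m1); cc <- round(p_ctrl * m2)
      p <- stats::fisher.test(matrix(c(aa, m1 - aa, cc, m2 - cc), 2,
                                     byrow = TRUE))$p.value
      if (p <= alpha) return(c(m1, m2))
      s <- s + 1
    }
  }
  got <- required_n(5, 5, 3, 7, alpha = 0.05)
  want <- scan_required(5, 5, 3, 7, 0.05)
  expect_equal(c(got$n_cases, got$n_controls), want)
  expect_lte(got$p_value, 0.05)

  # alpha = 1 returns the observed sizes
  triv <- required_n(5, 5, 3, 7, alpha = 1)
  expect_equal(c(triv$n_cases, triv$n_controls), c(10, 10))

  # equal proportions: never significant, sentinel with diagnostic
  eq <- required_n(5, 5, 5, 5, alpha = 0.05)
  expect_true(is.na(eq$n_cases))
  expect_match(eq$reason, "proportion")
})

test_that("required_n is monotone in alpha and in effect size", {
  set.seed(31)
  for (k in 1:10) {
    a <- sample(3:8, 1); b <- sample(5:15, 1)
    c_ <- sample(1:2, 1); d <- b + a - c_
    strict <- required_n(a, b, c_, d, alpha = 0.0031)
    loose <- required_n(a, b, c_, d, alpha = 0.05)
    expect_gte(strict$n_cases, loose$n_cases)
  }
  # growing case carrier proportion at fixed baseline shrinks required n
  sizes <- sapply(c(6, 8, 10), function(a) {
    required_n(a, 20 - a, 3, 17, alpha = 0.05)$n_cases
  })
  expect_true(all(diff(sizes) <= 0))
})
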