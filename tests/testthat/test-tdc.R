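test_that("spectrum competition keeps one best PSM per spectrum", {
  sc <- data.frame(spectrum_id = "s1", peptide = c("AAAK", "CCCK"),
                   score = c(2, 1), is_decoy = c(FALSE, TRUE))
  expect_equal(spectrum_competition(sc)$peptide, "AAAK")
  tie <- data.frame(spectrum_id = "s1", peptide = c("AAAK", "CCCK"),
                    score = c(2, 2), is_decoy = c(FALSE, TRUE))
  expect_true(spectrum_competition(tie)$is_decoy)  # conservative tie-break
  set.seed(53)
  for (trial in 1:30) {
    sc <- random_scored(20, 6, seed = trial)
    got <- spectrum_competition(sc)
    expect_equal(nrow(got), length(unique(sc$spectrum_id)))
    for (sid in unique(sc$spectrum_id)) {
      expect_equal(got$score[got$spectrum_id == sid],
                   max(sc$score[sc$spectrum_id == sid]))
    }
  }
})

test_that("peptide collapse keeps the top PSM per modified sequence", {
  ps <- data.frame(spectrum_id = c("s1", "s2", "s3"),
                   peptide = "AAAK", score = c(1, 3, 2), is_decoy = FALSE)
  got <- peptide_collapse(ps)
  expect_equal(nrow(got), 1L)
  expect_equal(got$score, 3)
  distinct <- data.frame(spectrum_id = c("s1", "s2"),
                         peptide = c("AAAK", "CCCK"), score = 1:2,
                         is_decoy = FALSE)
  expect_equal(nrow(peptide_collapse(distinct)), 2L)
  set.seed(59)
  for (trial in 1:30) {
    ps <- spectrum_competition(random_scored(25, 5, seed = 100 + trial))
    got <- peptide_collapse(ps)
    oracle <- tapply(ps$score, ps$peptide, max)
    expect_equal(nrow(got), length(oracle))
    expect_equal(got$score[order(got$peptide)],
                 as.numeric(oracle[sort(names(oracle))]))
  }
})

test_that("pair competition keeps the better matched side of each pair", {
  base <- data.frame(peptide = c("AAAK", "KAAA"), score = c(5, NA),
                     is_decoy = c(FALSE, TRUE), pair_id = 1L)
  # unmatched decoy auto-loses: only the target row exists
  got <- pair_competition(base[1, ])
  expect_equal(got$peptide, "AAAK")
  both <- data.frame(peptide = c("AAAK", "KAAA"), score = c(5, 7),
                     is_decoy = c(FALSE, TRUE), pair_id = 1L)
  expect_true(pair_competition(both)$is_decoy)
  tie <- transform(both, score = c(5, 5))
  expect_true(pair_competition(tie)$is_decoy)
  expect_error(pair_competition(data.frame(peptide = "A", score = 1,
                                           is_decoy = FALSE)), "pair_id")
  # collision pairs are dropped with a message
  col <- data.frame(peptide = c("AAK", "AAK"), score = c(3, 3),
                    is_decoy = c(FALSE, TRUE), pair_id = 1L,
                    collision = TRUE)
  expect_message(got <- pair_competition(col), "collision")
  expect_equal(nrow(got), 0L)
  set.seed(61)
  for (trial in 1:30) {
    best <- peptide_collapse(spectrum_competition(
      random_scored(25, 5, seed = 200 + trial)))
    got <- pair_competition(best)
    oracle <- tapply(best$score, best$pair_id, max)
    expect_equal(sort(got$score), sort(as.numeric(oracle)))
    expect_false(anyDuplicated(got$pair_id) > 0)
  }
})

test_that("FDR estimation reproduces the hand-enumerated ranked list", {
  surv <- data.frame(peptide = c("AAAK", "CCCK", "DDDK", "EEEK"),
                     score = c(9, 8, 7, 6),
                     is_decoy = c(FALSE, FALSE, FALSE, TRUE),
                     pair_id = 1:4)
  det <- estimate_fdr(surv, alpha = 0.4)
  expect_equal(det$fdr, c(1, 1 / 2, 1 / 3, 2 / 3))
  expect_equal(det$qvalue, c(1 / 3, 1 / 3, 1 / 3, 2 / 3))
  expect_equal(attr(det, "n_accepted"), 3L)
  # a decoy outranking all targets caps the estimate at 1
  swap <- transform(surv, is_decoy = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(estimate_fdr(swap, 0.4)$fdr[1], 1)
  # no decoys: FDR_k = 1/k
  nod <- transform(surv, is_decoy = FALSE)
  expect_equal(estimate_fdr(nod, 0.5)$fdr, 1 / (1:4))
  empty <- surv[0, ]
  det0 <- estimate_fdr(empty, 0.01)
  expect_equal(nrow(det0), 0L)
  expect_equal(attr(det0, "n_accepted"), 0L)
  expect_error(estimate_fdr(surv, 1.0))
})

test_that("q-values are monotone and acceptance sets nest across alpha", {
  set.seed(67)
  for (trial in 1:20) {
    surv <- pair_competition(peptide_collapse(spectrum_competition(
      random_scored(40, 4, seed = 300 + trial))))
    det <- estimate_fdr(surv, 0.5)
    expect_true(!is.unsorted(det$qvalue))
    expect_true(all(det$fdr >= 0 & det$fdr <= 1))
    expect_equal(det$T_k + det$D_k, seq_len(nrow(det)))
    acc_tight <- as.data.frame(estimate_fdr(surv, 0.2))
    acc_loose <- as.data.frame(estimate_fdr(surv, 0.5))
    expect_true(all(acc_tight$peptide[acc_tight$accepted] %in%
                      acc_loose$peptide[acc_loose$accepted]))
  }
})

test_that("target match percentage is the target share of assigned spectra", {
  ps <- data.frame(spectrum_id = sprintf("s%d", 1:100),
                   is_decoy = rep(c(FALSE, TRUE), c(70, 30)))
  got <- tmp(ps)
  expect_equal(got$tmp, 0.70)
  expect_equal(got$T_inf, 70L)
  expect_equal(tmp(ps[1:70, ])$tmp, 1.0)
  expect_error(tmp(ps[0, ]), "no PSMs")
  set.seed(71)
  lab <- sample(c(TRUE, FALSE), 57, replace = TRUE)
  expect_equal(tmp(data.frame(spectrum_id = as.character(1:57),
                              is_decoy = lab))$tmp, mean(!lab))
})

test_that("precursor-m/z stratification selects empirical quartiles", {
  ps <- data.frame(spectrum_id = as.character(1:100), precursor_mz = 1:100,
                   is_decoy = FALSE)
  expect_equal(stratify_by_precursor(ps, "lower")$precursor_mz, 1:25)
  expect_equal(stratify_by_precursor(ps, "upper")$precursor_mz, 76:100)
  # degenerate constant m/z: both strata equal the full set
  const <- transform(ps, precursor_mz = 500)
  expect_equal(nrow(stratify_by_precursor(const, "lower")), 100L)
  expect_equal(nrow(stratify_by_precursor(const, "upper")), 100L)
  low <- stratify_by_precursor(ps, "lower")
  up <- stratify_by_precursor(ps, "upper")
  expect_length(intersect(low$precursor_mz, up$precursor_mz), 0L)
  expect_error(stratify_by_precursor(ps[1:3, ], "lower"))
})
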