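test_that("rounding is half away from zero at any precision", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)
  expect_equal(round_half_up(2.5), 3)     # base round() would give 2
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0.685, 2), 0.69)
  expect_equal(round_half_up(84.45, 1), 84.5)
  expect_equal(round_half_up(71.4285, 3), 71.429)
})

test_that("enumeration recovers the published rows' unique tables", {
  # yang hyperactivity
  r <- summary_row("yang_hyperactivity", 90.5, 92.0, 61.3, 98.6, n = 171)
  cand <- enumerate_tables(r)
  expect_equal(nrow(cand), 1L)
  expect_equal(unlist(cand), c(tp = 19L, fn = 2L, fp = 12L, tn = 138L))
  # blood stasis
  cand <- enumerate_tables(summary_row("blood_stasis", 94.7, 85.3, 83.7,
                                       95.3, n = 171))
  expect_equal(unlist(cand), c(tp = 72L, fn = 4L, fp = 14L, tn = 81L))
  # zero-error rows are deliberately ambiguous: nine tables at n = 10
  cand <- enumerate_tables(summary_row("toy", "100.0", "100.0", "100.0",
                                       "100.0", n = 10))
  expect_equal(nrow(cand), 9L)
  expect_equal(cand$tp, 1:9)
  expect_equal(cand$tn, 9:1)
  expect_true(all(cand$fn == 0 & cand$fp == 0))
})

test_that("printed precision is honoured per rate", {
  # 71.428 is only reachable with three printed decimals; at one decimal
  # the same value string would be 71.4
  r3 <- summary_row("x", "71.428", "92.4", "75.1", "84.1", n = 171)
  expect_equal(unname(r3$digits),  c(3L, 1L, 1L, 1L))
  # a three-decimal sensitivity of 5/7 = 71.429 does not match 71.428
  cand <- enumerate_tables(r3)
  if (nrow(cand) > 0) {
    expect_true(all(round_half_up(100 * cand$tp / (cand$tp + cand$fn), 3)
                    == 71.428))
  }
})

test_that("enumeration agrees with the brute-force O(n^3) scan", {
  set.seed(61)
  for (rep in 1:12) {
    n <- sample(8:60, 1)
    tab <- rmultinom(1, n - 4, rep(0.25, 4))[, 1] + 1L
    se <- oracle_rhu(100 * tab[1] / (tab[1] + tab[2]), 1)
    sp <- oracle_rhu(100 * tab[4] / (tab[3] + tab[4]), 1)
    ppv <- oracle_rhu(100 * tab[1] / (tab[1] + tab[3]), 1)
    npv <- oracle_rhu(100 * tab[4] / (tab[2] + tab[4]), 1)
    got <- enumerate_tables(summary_row("x", se, sp, ppv, npv, n = n))
    got <- got[order(got$tp, got$fn, got$fp), ]
    want <- oracle_enumerate(se, sp, ppv, npv, n)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # the generating table is always among the candidates
    expect_true(any(got$tp == tab[1] & got$fn == tab[2] &
                      got$fp == tab[3] & got$tn == tab[4]))
  }
})

test_that("candidates round-trip to the printed percentages", {
  set.seed(67)
  for (rep in 1:10) {
    n <- sample(40:200, 1)
    tab <- rmultinom(1, n - 4, runif(4, 0.1, 1))[, 1] + 1L
    row <- summary_row("x",
                       oracle_rhu(100 * tab[1] / (tab[1] + tab[2]), 1),
                       oracle_rhu(100 * tab[4] / (tab[3] + tab[4]), 1),
                       oracle_rhu(100 * tab[1] / (tab[1] + tab[3]), 1),
                       oracle_rhu(100 * tab[4] / (tab[2] + tab[4]), 1),
                       n = n)
    cand <- enumerate_tables(row)
    expect_gte(nrow(cand), 1L)
    for (i in seq_len(nrow(cand))) {
      m <- accuracy_metrics(confusion(cand$tp[i], cand$fn[i], cand$fp[i],
                                      cand$tn[i]))
      expect_equal(round_half_up(100 * m$sensitivity, 1),
                   row$sensitivity_pct)
      expect_equal(round_half_up(100 * m$specificity, 1),
                   row$specificity_pct)
      expect_equal(round_half_up(100 * m$ppv, 1), row$ppv_pct)
      expect_equal(round_half_up(100 * m$npv, 1), row$npv_pct)
    }
  }
})

test_that("verify_row checks printed kappa and chi-square when unique", {
  r <- verify_row(summary_row("yang_hyperactivity", 90.5, 92.0, 61.3, 98.6,
                              kappa = 0.685, chi_square = 84.4, n = 171))
  expect_true(r$unique)
  expect_equal(round_half_up(r$kappa_check, 3), 0.685)
  expect_equal(round_half_up(r$chi_square_check, 1), 84.4)
  expect_true(r$consistent)
  # marrow deficiency
  r <- verify_row(summary_row("marrow_deficiency", 63.6, 94.9, 75.0, 91.6,
                              kappa = 0.621, chi_square = 66.7, n = 171))
  expect_equal(unlist(r$candidates), c(tp = 21L, fn = 12L, fp = 7L,
                                       tn = 131L))
  expect_equal(round_half_up(r$kappa_check, 3), 0.621)
  # blood deficiency admits no integer table at all
  r <- verify_row(summary_row("blood_deficiency", "71.428", "92.4", "75.1",
                              "84.1", kappa = 0.547, chi_square = 73.913,
                              n = 171))
  expect_equal(nrow(r$candidates), 0L)
  expect_false(r$unique)
  expect_false(r$consistent)
})

test_that("the bundled summary table verifies as published", {
  v <- verify_summary_table()
  expect_equal(nrow(v$report), 11L)
  expect_equal(v$report$subscale_id[7], "yang_hyperactivity")
  # qi deficiency and endogenous heat recover their printed tables
  qi <- v$results$qi_deficiency
  expect_equal(unlist(qi$candidates), c(tp = 30L, fn = 21L, fp = 10L,
                                        tn = 110L))
  eh <- v$results$endogenous_heat
  expect_equal(unlist(eh$candidates), c(tp = 16L, fn = 6L, fp = 18L,
                                        tn = 131L))
  # endogenous heat: kappa reproduces, chi-square differs in the last digit
  expect_true(eh$kappa_consistent)
  expect_false(eh$chi_square_consistent)
  # rows with no consistent table are reported, never guessed
  expect_equal(v$report$n_candidates[v$report$subscale_id %in%
                                       c("kidney_deficiency",
                                         "spleen_deficiency",
                                         "yang_deficiency",
                                         "blood_deficiency")],
               rep(0L, 4))
})
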