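test_that("confusion_table counts partition the cohort", {
  ct <- confusion_table(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(ct[c("tp", "fn", "fp", "tn")]),
               c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  ct <- confusion_table(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(ct$tp + ct$tn, 0L)
  expect_equal(ct$fn, 2L)
  expect_equal(ct$fp, 2L)
  expect_error(confusion_table(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusion_table(c(1, 2), c(1, 0)), "binary")
  expect_error(confusion_table(integer(), integer()), "at least one")
})

test_that("accuracy metrics match closed forms on reference tables", {
  # the recovered yang-hyperactivity table
  m <- accuracy_metrics(confusion(tp = 19, fn = 2, fp = 12, tn = 138))
  expect_equal(round_half_up(m$sensitivity, 3), 0.905)
  expect_equal(round_half_up(m$specificity, 3), 0.920)
  expect_equal(round_half_up(m$ppv, 3), 0.613)
  expect_equal(round_half_up(m$npv, 3), 0.986)
  expect_equal(round_half_up(m$kappa, 3), 0.685)
  expect_equal(round_half_up(m$chi_square, 1), 84.4)
  # perfect agreement
  m <- accuracy_metrics(confusion(10, 0, 0, 10))
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "kappa")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 kappa = 1))
  # independence: kappa and chi-square both zero
  m <- accuracy_metrics(confusion(25, 25, 25, 25))
  expect_equal(m$kappa, 0)
  expect_equal(m$chi_square, 0)
  expect_equal(m$p_value, 1)
})

test_that("undefined metrics are flagged, not silently zero", {
  m <- accuracy_metrics(confusion(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true("sensitivity" %in% m$undefined)
  expect_true(is.na(m$sensitivity))
  expect_true("chi_square" %in% m$undefined)
  m <- accuracy_metrics(confusion(tp = 5, fn = 5, fp = 0, tn = 0))
  expect_true(all(c("specificity", "chi_square") %in% m$undefined))
  expect_equal(m$npv, 0)  # defined: denominator tn + fn = 5
})

test_that("metrics agree with a brute-force recount on random small cohorts", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:30, 1)
    predicted <- rbinom(n, 1, runif(1, 0.2, 0.8))
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    o <- oracle_metrics(predicted, truth)
    m <- accuracy_metrics(confusion_table(predicted, truth))
    for (f in c("sensitivity", "specificity", "ppv", "npv", "kappa",
                "chi_square")) {
      expect_equal(m[[f]], o[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("kappa boundary cases follow the 2x2 identities", {
  set.seed(23)
  for (rep in 1:40) {
    tab <- as.list(rmultinom(1, sample(8:60, 1), runif(4, 0.05, 1))[, 1])
    names(tab) <- c("tp", "fn", "fp", "tn")
    if ((tab$tp + tab$fn) == 0 || (tab$fp + tab$tn) == 0 ||
        (tab$tp + tab$fp) == 0 || (tab$fn + tab$tn) == 0) next
    m <- accuracy_metrics(confusion(tab$tp, tab$fn, tab$fp, tab$tn))
    # kappa = 1 iff no discordant cells (both classes present)
    expect_equal(isTRUE(all.equal(m$kappa, 1)),
                 tab$fn == 0 && tab$fp == 0)
    # kappa = 0 and chi-square = 0 whenever tp*tn = fn*fp
    if (tab$tp * tab$tn == tab$fn * tab$fp) {
      expect_equal(m$kappa, 0)
      expect_equal(m$chi_square, 0)
    }
    # chi-square invariant under jointly swapping test and reference labels
    sw <- accuracy_metrics(confusion(tab$tn, tab$fp, tab$fn, tab$tp))
    expect_equal(m$chi_square, sw$chi_square, tolerance = 1e-12)
    expect_gte(m$chi_square, 0)
    # chi-square p-value agrees with the uncorrected Pearson test
    suppressWarnings(
      ref <- stats::chisq.test(matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2),
                               correct = FALSE))
    expect_equal(m$chi_square, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("prevalence-based predictive values match the empirical ones", {
  expect_equal(predictive_values_from_prevalence(0.9, 0.9, 0.5),
               list(ppv = 0.9, npv = 0.9))
  # zero prevalence: NPV 1, PPV undefined when specificity is perfect
  pv <- predictive_values_from_prevalence(0.8, 1, 0)
  expect_true(is.na(pv$ppv))
  expect_equal(pv$npv, 1)
  # algebraic identity with pi = (tp+fn)/n, on random tables
  set.seed(31)
  for (rep in 1:40) {
    tab <- rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1))[, 1] + 1L
    m <- accuracy_metrics(confusion(tab[1], tab[2], tab[3], tab[4]))
    pv <- predictive_values_from_prevalence(
      m$sensitivity, m$specificity, (tab[1] + tab[2]) / sum(tab))
    expect_equal(pv$ppv, m$ppv, tolerance = 1e-12)
    expect_equal(pv$npv, m$npv, tolerance = 1e-12)
  }
  # the reconstructed yang-hyperactivity operating point
  pv <- predictive_values_from_prevalence(19 / 21, 138 / 150, 21 / 171)
  expect_equal(round_half_up(pv$ppv, 3), 0.613)
})

test_that("ROC curve matches the exhaustive pair-counting oracle", {
  # perfect separation
  expect_equal(roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # all ties
  expect_equal(roc_curve(rep(3, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # positives {3, 1}, negatives {2, 0}: 3 of 4 pairs concordant
  expect_equal(roc_curve(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "positive and one negative")
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(0:6, n, replace = TRUE) / 2
    r <- roc_curve(scores, truth)
    expect_equal(r$auc, oracle_auc(scores, truth), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(roc_curve(exp(scores), truth)$auc, r$auc)
    # curve points monotone as the threshold relaxes
    expect_true(all(diff(r$points$tpr) <= 0))
    expect_true(all(diff(r$points$fpr) <= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(rnorm(n, mean = 3 * truth, sd = 2), 1)
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores,
                                                quiet = TRUE)))
    expect_equal(roc_curve(scores, truth)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("AUC standard error and test follow the closed forms", {
  expect_equal(auc_standard_error(1, 10, 20), 0)
  expect_equal(round_half_up(auc_standard_error(0.5, 10, 10), 4), 0.1323)
  # independent symbolic recomputation of the variance formula
  a <- 0.9; np <- 20; nn <- 150
  v <- (a * (1 - a) + (np - 1) * (a / (2 - a) - a^2) +
          (nn - 1) * (2 * a^2 / (1 + a) - a^2)) / (np * nn)
  expect_equal(auc_standard_error(a, np, nn), sqrt(v))
  t <- auc_test_vs_half(0.5, 0.1)
  expect_equal(t$p_value, 1)
  expect_equal(t$ci, c(0.304, 0.696))
  # published yang-hyperactivity AUC row: CI 0.952-0.996
  t <- auc_test_vs_half(0.974, 0.011)
  expect_equal(round_half_up(t$ci, 3), c(0.952, 0.996))
  t <- auc_test_vs_half(0.7, 0)
  expect_true(t$degenerate)
  expect_equal(t$p_value, 0)
})

test_that("Youden cut-off maximizes J with sensitive tie-breaking", {
  # perfect separation: J = 1
  y <- youden_optimal_cutoff(roc_curve(c(8, 9, 1, 2), c(1, 1, 0, 0)))
  expect_equal(y$youden_j, 1)
  expect_gt(y$threshold, 2)
  expect_lte(y$threshold, 8)
  # all ties: J = 0
  y <- youden_optimal_cutoff(roc_curve(rep(2, 4), c(1, 1, 0, 0)))
  expect_equal(y$youden_j, 0)
  # ties in J break toward the lower (more sensitive) threshold
  y <- youden_optimal_cutoff(roc_curve(c(4, 3, 2, 1), c(1, 1, 0, 0)))
  expect_equal(y$threshold, 3)
})

test_that("validate_cohort reproduces per-subscale metrics and ROC", {
  inst <- pes_instrument()
  set.seed(53)
  cfg <- simulation_config(n_patients = 150, seed = 53)
  co <- simulate_cohort(cfg, inst)
  profiles <- profile_cohort(co$records, inst)
  val <- validate_cohort(profiles, co$records)
  expect_s3_class(val, "pes_validation")
  expect_equal(nrow(val$metrics), 11L)
  expect_equal(val$metrics$subscale_id, subscale_ids(inst))
  # spot-check one subscale against direct recomputation
  s <- "blood_stasis"
  truth <- co$records[[paste0("expert_", s)]]
  m <- accuracy_metrics(confusion_table(profiles[[paste0("dx_", s)]], truth))
  row <- val$metrics[val$metrics$subscale_id == s, ]
  expect_equal(row$kappa, m$kappa)
  expect_equal(row$sensitivity, m$sensitivity)
  expect_equal(row$auc, roc_curve(profiles[[paste0("score_", s)]],
                                  truth)$auc)
  # degenerate subscale: no expert positives -> Se undefined, ROC omitted
  ex <- co$records
  ex[["expert_yang_hyperactivity"]] <- 0L
  expect_warning(val2 <- validate_cohort(profiles, ex), "single-class")
  r2 <- val2$metrics[val2$metrics$subscale_id == "yang_hyperactivity", ]
  expect_true(is.na(r2$sensitivity))
  expect_true(is.na(r2$auc))
  expect_false("yang_hyperactivity" %in% names(val2$roc))
})
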