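#' 2x2 confusion table of a binary test against a reference standard
#'
#' @param predicted Binary (0/1 or logical) test results, one per patient.
#' @param truth Binary reference-standard labels of the same length.
#' @return An object of class `confusion_table`: list with integer counts
#'   `tp`, `fn`, `fp`, `tn` and `n`.
#' @examples
#' confusion_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_table <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (length(predicted) < 1L) stop("need at least one observation")
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (!all(predicted %in% 0:1) || !all(truth %in% 0:1)) {
    stop("predicted and truth must be binary (0/1)")
  }
  confusion(tp = sum(predicted == 1L & truth == 1L),
            fn = sum(predicted == 0L & truth == 1L),
            fp = sum(predicted == 1L & truth == 0L),
            tn = sum(predicted == 0L & truth == 0L))
}

#' Construct a confusion table from its four counts
#' @param tp,fn,fp,tn Non-negative integer counts (true positive, false
#'   negative, false positive, true negative).
#' @return A `confusion_table` object.
#' @export
confusion <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n <= 0) stop("confusion table must contain at least one observation")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n = as.integer(n)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy and agreement metrics of a 2x2 table
#'
#' Computes sensitivity tp/(tp+fn), specificity tn/(tn+fp), predictive
#' values PPV = tp/(tp+fp) and NPV = tn/(tn+fn), Cohen's kappa
#' (p_o - p_e)/(1 - p_e) with observed agreement p_o = (tp+tn)/n and chance
#' agreement p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn))/n^2, and the Pearson
#' chi-square statistic n(tp*tn - fp*fn)^2 / ((tp+fp)(fn+tn)(tp+fn)(fp+tn))
#' without continuity correction, with its p-value on 1 degree of freedom.
#'
#' A metric whose denominator is zero is reported as `NA` and named in the
#' `undefined` field, never silently set to 0.
#'
#' @param ct A `confusion_table` object.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, `kappa`,
#'   `chi_square`, `p_value`, `n` and `undefined` (character vector naming
#'   metrics with zero denominators).
#' @export
accuracy_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  tp <- ct$tp; fn <- ct$fn; fp <- ct$fp; tn <- ct$tn; n <- ct$n
  undefined <- character()
  rate <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      NA_real_
    } else num / den
  }
  se <- rate(tp, tp + fn, "sensitivity")
  sp <- rate(tn, tn + fp, "specificity")
  ppv <- rate(tp, tp + fp, "ppv")
  npv <- rate(tn, tn + fn, "npv")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) {
    undefined <- c(undefined, "kappa")
    NA_real_
  } else (p_o - p_e) / (1 - p_e)
  denom <- (tp + fp) * (fn + tn) * (tp + fn) * (fp + tn)
  if (denom == 0) {
    undefined <- c(undefined, "chi_square")
    chi2 <- NA_real_
    pval <- NA_real_
  } else {
    chi2 <- n * (tp * tn - fp * fn)^2 / denom
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
       kappa = kappa, chi_square = chi2, p_value = pval, n = n,
       undefined = undefined)
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes-rule predictive values at prevalence pi:
#' PPV = se*pi / (se*pi + (1-sp)(1-pi)) and
#' NPV = sp(1-pi) / (sp(1-pi) + (1-se)pi). With pi taken as the sample
#' positive fraction these reproduce the empirical PPV/NPV of the same 2x2
#' table exactly.
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @param prevalence Positive-class prevalence in \[0, 1\].
#' @return List with `ppv` and `npv`; a value is `NA` when both terms of its
#'   denominator vanish (e.g. PPV at prevalence 0 with perfect specificity).
#' @export
predictive_values_from_prevalence <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            prevalence >= 0, prevalence <= 1)
  dpos <- se * prevalence + (1 - sp) * (1 - prevalence)
  dneg <- sp * (1 - prevalence) + (1 - se) * prevalence
  list(ppv = if (dpos == 0) NA_real_ else se * prevalence / dpos,
       npv = if (dneg == 0) NA_real_ else sp * (1 - prevalence) / dneg)
}

#' ROC curve of a continuous score against a binary reference
#'
#' Sweeps every distinct observed score (plus a +Inf sentinel) as a
#' candidate cut-off, classifying positive when score >= threshold, and
#' records (1 - specificity, sensitivity) at each. The area under the curve
#' is the Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted 1/2 — computed from midranks, so it is exact
#' and invariant under strictly monotone score transforms. The standard
#' error uses the Hanley-McNeil closed form and the curve carries the
#' asymptotic 95% CI and two-sided p-value against AUC = 0.5.
#'
#' @param scores Numeric scores, higher meaning more test-positive.
#' @param truth Binary reference labels of the same length; both classes
#'   must be present.
#' @return Object of class `pes_roc`: list with `thresholds`, `points`
#'   (data frame `threshold`, `fpr`, `tpr`), `auc`, `se`, `ci`,
#'   `p_value_vs_half`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  truth <- as.integer(truth)
  if (!all(truth %in% 0:1)) stop("truth must be binary (0/1)")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one positive and one negative")
  }
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0L) / n_neg, 0)
  # Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  se <- auc_standard_error(auc, n_pos, n_neg)
  test <- auc_test_vs_half(auc, se)
  structure(list(thresholds = thr,
                 points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, se = se, ci = test$ci,
                 p_value_vs_half = test$p_value,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pes_roc")
}

#' @export
print.pes_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f, p vs 0.5 = %.3g); %d+/%d-\n",
    x$auc, x$se, x$ci[1], x$ci[2], x$p_value_vs_half, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of a nonparametric AUC
#'
#' SE^2 = (A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)) /
#' (n_pos * n_neg), with Q1 = A/(2-A) and Q2 = 2A^2/(1+A).
#'
#' @param auc Area under the curve in \[0, 1\].
#' @param n_pos,n_neg Number of positive and negative subjects (each >= 1).
#' @return The standard error (0 when the area is exactly 0 or 1).
#' @export
auc_standard_error <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' Asymptotic test of an AUC against the no-discrimination value 0.5
#'
#' 95% CI = auc +/- 1.96*se; two-sided p-value from the normal deviate
#' z = (auc - 0.5)/se. With se = 0 the test degenerates: p = 1 when the
#' area is exactly 0.5, otherwise p = 0 with `degenerate = TRUE`.
#'
#' @param auc Area under the curve.
#' @param se Its standard error (>= 0).
#' @return List with `ci` (length-2 vector), `p_value` and `degenerate`.
#' @export
auc_test_vs_half <- function(auc, se) {
  stopifnot(se >= 0)
  ci <- c(auc - 1.96 * se, auc + 1.96 * se)
  if (se == 0) {
    if (auc == 0.5) {
      return(list(ci = ci, p_value = 1, degenerate = FALSE))
    }
    return(list(ci = ci, p_value = 0, degenerate = TRUE))
  }
  z <- (auc - 0.5) / se
  list(ci = ci, p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Optimal cut-off by the Youden index
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's candidate
#' thresholds; ties are broken toward the lower threshold (the more
#' sensitive choice, appropriate for a screening instrument).
#'
#' @param curve A `pes_roc` object.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "pes_roc"))
  j <- curve$points$tpr - curve$points$fpr
  best <- which(j == max(j))
  i <- best[which.min(curve$points$threshold[best])]
  list(threshold = curve$points$threshold[i],
       sensitivity = curve$points$tpr[i],
       specificity = 1 - curve$points$fpr[i],
       youden_j = j[i])
}

#' Validate scored profiles against expert standard labels
#'
#' For every subscale with expert labels, builds the 2x2 table of the PES
#' diagnosis against the expert label, computes [accuracy_metrics()], and
#' fits the ROC of the subscale score against the expert label. Subscales
#' whose expert labels contain a single class get their 2x2 metrics (where
#' defined) but no ROC, with a warning.
#'
#' @param profiles Output of [profile_cohort()] (`score_`/`dx_` columns).
#' @param expert Data frame with `patient_id` and one `expert_<subscale_id>`
#'   binary column per evaluated subscale (a cohort table as read by
#'   [read_cohort()] works directly).
#' @return Object of class `pes_validation`: list with `metrics` (one row
#'   per subscale: Se/Sp/PPV/NPV, kappa, chi-square, p-value, AUC, AUC SE,
#'   CI bounds, AUC p-value) and `roc` (named list of `pes_roc`).
#' @export
validate_cohort <- function(profiles, expert) {
  if (!"patient_id" %in% names(expert)) stop("expert table lacks patient_id")
  idx <- match(profiles$patient_id, expert$patient_id)
  if (any(is.na(idx))) {
    stop("expert labels missing for patient '",
         profiles$patient_id[which(is.na(idx))[1L]], "'")
  }
  expert <- expert[idx, , drop = FALSE]
  sub_ids <- sub("^dx_", "", grep("^dx_", names(profiles), value = TRUE))
  sub_ids <- sub_ids[paste0("expert_", sub_ids) %in% names(expert)]
  if (!length(sub_ids)) stop("no expert_<subscale> columns match the profiles")
  rows <- list()
  rocs <- list()
  for (s in sub_ids) {
    truth <- as.integer(expert[[paste0("expert_", s)]])
    if (any(is.na(truth))) stop("missing expert label for subscale '", s, "'")
    m <- accuracy_metrics(confusion_table(profiles[[paste0("dx_", s)]], truth))
    roc <- NULL
    if (length(unique(truth)) == 2L) {
      roc <- roc_curve(profiles[[paste0("score_", s)]], truth)
    } else {
      warning("subscale '", s, "': single-class expert labels, ROC omitted")
    }
    rows[[s]] <- data.frame(
      subscale_id = s,
      kappa = m$kappa, chi_square = m$chi_square, p_value = m$p_value,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv,
      auc = if (is.null(roc)) NA_real_ else roc$auc,
      auc_se = if (is.null(roc)) NA_real_ else roc$se,
      auc_ci_lower = if (is.null(roc)) NA_real_ else roc$ci[1],
      auc_ci_upper = if (is.null(roc)) NA_real_ else roc$ci[2],
      auc_p_value = if (is.null(roc)) NA_real_ else roc$p_value_vs_half,
      stringsAsFactors = FALSE
    )
    if (!is.null(roc)) rocs[[s]] <- roc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(metrics = out, roc = rocs), class = "pes_validation")
}

#' @export
print.pes_validation <- function(x, ...) {
  cat("PES validation against expert standard (", nrow(x$metrics),
      " subscales)\n", sep = "")
  df <- x$metrics
  df$sensitivity <- format_pct(df$sensitivity)
  df$specificity <- format_pct(df$specificity)
  df$ppv <- format_pct(df$ppv)
  df$npv <- format_pct(df$npv)
  df$kappa <- sprintf("%.3f", df$kappa)
  df$chi_square <- sprintf("%.1f", df$chi_square)
  print(df[, c("subscale_id", "kappa", "chi_square", "sensitivity",
               "specificity", "ppv", "npv", "auc")], row.names = FALSE)
  invisible(x)
}
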