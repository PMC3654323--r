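# Independent oracles: deliberately naive implementations, kept free of the
# package code paths they are used to check.

# exhaustive pair-counting AUC (ties count 1/2)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# direct recount of all 2x2 metrics from raw labels
oracle_metrics <- function(predicted, truth) {
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else NA_real_,
       chi_square = {
         d <- (tp + fp) * (fn + tn) * (tp + fn) * (fp + tn)
         if (d > 0) n * (tp * tn - fp * fn)^2 / d else NA_real_
       })
}

# half-away-from-zero rounding, written independently of the package's
oracle_rhu <- function(x, d) {
  p <- 10^d
  ifelse(x < 0, -trunc(abs(x) * p + 0.5) / p, trunc(x * p + 0.5) / p)
}

# brute-force O(n^3) scan over every integer 2x2 table summing to n
oracle_enumerate <- function(se, sp, ppv, npv, n, digits = 1) {
  g <- expand.grid(tp = 0:n, fn = 0:n, fp = 0:n)
  g <- g[g$tp + g$fn + g$fp <= n, ]
  g$tn <- n - g$tp - g$fn - g$fp
  ok <- (g$tp + g$fn) >= 1 & (g$fp + g$tn) >= 1 &
    (g$tp + g$fp) >= 1 & (g$fn + g$tn) >= 1 &
    oracle_rhu(100 * g$tp / (g$tp + g$fn), digits) == se &
    oracle_rhu(100 * g$tn / (g$tn + g$fp), digits) == sp &
    oracle_rhu(100 * g$tp / (g$tp + g$fp), digits) == ppv &
    oracle_rhu(100 * g$tn / (g$tn + g$fn), digits) == npv
  out <- g[ok, c("tp", "fn", "fp", "tn")]
  out[order(out$tp, out$fn, out$fp), ]
}

# minimal all-absent cohort data frame for an instrument
blank_cohort <- function(n, instrument) {
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (s in instrument$subscales) {
    for (id in s$items$item_id) df[[id]] <- rep(0L, n)
  }
  df
}
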