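#' Round half away from zero
#'
#' Commercial/spreadsheet rounding: halves move away from zero, unlike base
#' [round()]'s round-half-even. Printed percentages in clinical reports
#' follow this convention, so the reconstruction engine matches against it.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' A printed per-subscale summary row
#'
#' Bundles the published summary statistics of one subscale: the four rates
#' as printed percentages, the printed kappa and chi-square, and the cohort
#' size. Rates are kept as strings internally long enough to count their
#' printed decimal places, so a value published at anomalous precision
#' (e.g. 71.428) is matched at that precision.
#'
#' @param subscale_id Subscale identifier.
#' @param sensitivity_pct,specificity_pct,ppv_pct,npv_pct Percentages as
#'   printed (numbers or strings; strings preserve trailing zeros).
#' @param kappa,chi_square Printed agreement values (optional, `NA` to skip
#'   verification).
#' @param n Cohort size (>= 4).
#' @return Object of class `summary_row`.
#' @export
summary_row <- function(subscale_id, sensitivity_pct, specificity_pct,
                        ppv_pct, npv_pct, kappa = NA_real_,
                        chi_square = NA_real_, n = 171L) {
  n <- as.integer(n)
  if (n < 4L) stop("cohort size must be at least 4")
  pct <- list(sensitivity = sensitivity_pct, specificity = specificity_pct,
              ppv = ppv_pct, npv = npv_pct)
  parsed <- lapply(pct, function(v) {
    s <- as.character(v)
    x <- as.numeric(s)
    if (is.na(x) || x < 0 || x > 100) stop("percentage out of [0, 100]: ", s)
    list(value = x, digits = .printed_digits(s))
  })
  structure(list(subscale_id = as.character(subscale_id),
                 sensitivity_pct = parsed$sensitivity$value,
                 specificity_pct = parsed$specificity$value,
                 ppv_pct = parsed$ppv$value,
                 npv_pct = parsed$npv$value,
                 digits = vapply(parsed, `[[`, 0L, "digits"),
                 kappa = as.numeric(kappa),
                 chi_square = as.numeric(chi_square),
                 n = n),
            class = "summary_row")
}

.printed_digits <- function(s) {
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0) 0L else nchar(s) - dot
}

#' Enumerate every 2x2 table consistent with printed summary rates
#'
#' Exhaustively searches all integer confusion tables (tp, fn, fp, tn) with
#' tp + fn + fp + tn = n, every margin non-degenerate (at least one
#' reference positive and one reference negative, and positive denominators
#' for all four printed rates), such that 100*Se, 100*Sp, 100*PPV and
#' 100*NPV each round — half away from zero, at each rate's printed number
#' of decimals — to the printed percentages. An empty result means no
#' integer table can have produced the printed row (the row is internally
#' inconsistent); multiple results mean the printed precision does not pin
#' the table down.
#'
#' @param row A [summary_row()].
#' @return Data frame of candidate tables with columns `tp`, `fn`, `fp`,
#'   `tn` (possibly zero rows).
#' @export
enumerate_tables <- function(row) {
  stopifnot(inherits(row, "summary_row"))
  n <- row$n
  d <- row$digits
  out <- vector("list", n - 1L)
  for (npos in seq_len(n - 1L)) {
    nneg <- n - npos
    tp <- which(round_half_up(100 * (0:npos) / npos, d[["sensitivity"]]) ==
                  row$sensitivity_pct) - 1L
    if (!length(tp)) next
    tn <- which(round_half_up(100 * (0:nneg) / nneg, d[["specificity"]]) ==
                  row$specificity_pct) - 1L
    if (!length(tn)) next
    g <- expand.grid(tp = tp, tn = tn, KEEP.OUT.ATTRS = FALSE)
    g$fp <- nneg - g$tn
    g$fn <- npos - g$tp
    ok <- (g$tp + g$fp) >= 1L & (g$fn + g$tn) >= 1L &
      round_half_up(100 * g$tp / (g$tp + g$fp), d[["ppv"]]) == row$ppv_pct &
      round_half_up(100 * g$tn / (g$tn + g$fn), d[["npv"]]) == row$npv_pct
    if (any(ok)) out[[npos]] <- g[ok, c("tp", "fn", "fp", "tn")]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(tp = integer(), fn = integer(), fp = integer(),
               tn = integer())
  }
  rownames(res) <- NULL
  res
}

#' Reconstruct one summary row and verify its printed agreement statistics
#'
#' Runs [enumerate_tables()]; when the reconstruction is unique, recomputes
#' Cohen's kappa and the Pearson chi-square from the recovered table via
#' [accuracy_metrics()] and compares them with the printed values at their
#' printed precision (kappa to 3 decimals, chi-square to 1 decimal unless
#' printed finer).
#'
#' @param row A [summary_row()].
#' @return Object of class `reconstruction_result`: list with `row`,
#'   `candidates` (data frame), `unique`, `kappa_check`,
#'   `chi_square_check`, `kappa_consistent`, `chi_square_consistent` and
#'   `consistent` (unique AND both printed statistics reproduced).
#' @export
verify_row <- function(row) {
  stopifnot(inherits(row, "summary_row"))
  cand <- enumerate_tables(row)
  unique_tab <- nrow(cand) == 1L
  kappa_check <- NA_real_
  chi_check <- NA_real_
  kappa_ok <- NA
  chi_ok <- NA
  if (unique_tab) {
    m <- accuracy_metrics(confusion(cand$tp, cand$fn, cand$fp, cand$tn))
    kappa_check <- m$kappa
    chi_check <- m$chi_square
    if (!is.na(row$kappa)) {
      kappa_ok <- round_half_up(kappa_check, 3) == row$kappa
    }
    if (!is.na(row$chi_square)) {
      chi_digits <- max(1L, .printed_digits(format(row$chi_square)))
      chi_ok <- round_half_up(chi_check, chi_digits) == row$chi_square
    }
  }
  structure(list(row = row, candidates = cand, unique = unique_tab,
                 kappa_check = kappa_check, chi_square_check = chi_check,
                 kappa_consistent = kappa_ok, chi_square_consistent = chi_ok,
                 consistent = unique_tab && isTRUE(kappa_ok) &&
                   isTRUE(chi_ok)),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("%s: %d candidate table(s)", x$row$subscale_id,
              nrow(x$candidates)))
  if (x$unique) {
    cat(sprintf(" (tp=%d fn=%d fp=%d tn=%d); kappa %.4f, chi-square %.3f",
                x$candidates$tp, x$candidates$fn, x$candidates$fp,
                x$candidates$tn, x$kappa_check, x$chi_square_check))
  }
  cat("\n")
  invisible(x)
}

#' Bundled transcription of the published per-subscale summary table
#'
#' @return List of 11 [summary_row()] objects, in published order, carrying
#'   the printed kappa, chi-square, Se/Sp/PPV/NPV percentages and n = 171.
#' @export
pes_published_summary <- function() {
  path <- system.file("extdata", "published_summary.csv", package = "pesval")
  raw <- utils::read.csv(path, colClasses = "character")
  lapply(seq_len(nrow(raw)), function(i) {
    summary_row(subscale_id = raw$subscale_id[i],
                sensitivity_pct = raw$sensitivity_pct[i],
                specificity_pct = raw$specificity_pct[i],
                ppv_pct = raw$ppv_pct[i],
                npv_pct = raw$npv_pct[i],
                kappa = as.numeric(raw$kappa[i]),
                chi_square = as.numeric(raw$chi_square[i]),
                n = as.integer(raw$n[i]))
  })
}

#' Reconstruct and verify a whole summary table
#'
#' @param rows List of [summary_row()] objects; defaults to the bundled
#'   published table ([pes_published_summary()]).
#' @return Object of class `summary_verification`: list with `results`
#'   (per-row [verify_row()] output, named by subscale), `report` (one data
#'   frame row per subscale: candidate count, uniqueness, recovered table,
#'   kappa/chi-square checks and consistency flags) and `n_consistent`.
#' @export
verify_summary_table <- function(rows = pes_published_summary()) {
  results <- lapply(rows, verify_row)
  names(results) <- vapply(rows, function(r) r$subscale_id, "")
  report <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      subscale_id = r$row$subscale_id,
      n_candidates = nrow(r$candidates),
      unique = r$unique,
      tp = if (r$unique) r$candidates$tp else NA_integer_,
      fn = if (r$unique) r$candidates$fn else NA_integer_,
      fp = if (r$unique) r$candidates$fp else NA_integer_,
      tn = if (r$unique) r$candidates$tn else NA_integer_,
      kappa_printed = r$row$kappa,
      kappa_check = r$kappa_check,
      kappa_consistent = r$kappa_consistent,
      chi_square_printed = r$row$chi_square,
      chi_square_check = r$chi_square_check,
      chi_square_consistent = r$chi_square_consistent,
      consistent = r$consistent,
      stringsAsFactors = FALSE
    )
  }))
  rownames(report) <- NULL
  structure(list(results = results, report = report,
                 n_consistent = sum(report$consistent)),
            class = "summary_verification")
}

#' @export
print.summary_verification <- function(x, ...) {
  cat("Summary-table reconstruction:", x$n_consistent, "of",
      nrow(x$report), "rows fully consistent\n")
  print(x$report[, c("subscale_id", "n_candidates", "tp", "fn", "fp", "tn",
                     "kappa_check", "chi_square_check", "consistent")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
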