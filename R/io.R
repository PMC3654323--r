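#' Format a proportion as a printed percentage
#'
#' One decimal place, half rounded away from zero (the published tables'
#' convention). `NA` renders as an empty string.
#'
#' @param x Proportions in \[0, 1\].
#' @param digits Decimal places (default 1).
#' @return Character vector like `"90.5"`.
#' @export
format_pct <- function(x, digits = 1) {
  out <- ifelse(is.na(x), "",
                formatC(round_half_up(100 * x, digits),
                        format = "f", digits = digits))
  out
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits),
                               format = "f", digits = digits))
}

#' Read a patient cohort table
#'
#' Reads a comma-separated UTF-8 cohort file (header row, one row per
#' patient): a `patient_id` column, one 0/1 column per instrument item id,
#' and optionally `expert_<subscale_id>` labels, `mmse_<domain>` scores and
#' eligibility covariates (`mmse_total`, `education`, `adl`, `cdr`,
#' `hamd`). Item and expert cells must be 0, 1 or empty (empty = missing);
#' a non-binary cell is an error reported with its row and column. Columns
#' the instrument does not know are kept but warned about.
#'
#' @param path Path to the CSV file.
#' @param instrument A `pes_instrument` used to validate column names.
#' @return The cohort data frame, rows in file order.
#' @export
read_cohort <- function(path, instrument = pes_instrument()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        encoding = "UTF-8", check.names = FALSE)
  if (!"patient_id" %in% names(df)) {
    stop("cohort file lacks a patient_id column: ", path)
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dup <- df$patient_id[duplicated(df$patient_id)][1L]
    stop("duplicate patient_id '", dup, "' in ", path)
  }
  items <- unlist(lapply(instrument$subscales, function(s) s$items$item_id),
                  use.names = FALSE)
  subs <- subscale_ids(instrument)
  known <- c("patient_id", items, paste0("expert_", subs),
             paste0("mmse_", names(.mmse_domains)),
             "mmse_total", "education", "adl", "cdr", "hamd")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("ignoring unknown cohort column(s): ",
            paste(unknown, collapse = ", "))
  }
  binary_cols <- intersect(names(df), c(items, paste0("expert_", subs)))
  for (col in binary_cols) {
    v <- df[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad)) {
      stop("non-binary value '", v[bad[1L]], "' at row ", bad[1L],
           ", column '", col, "' of ", path)
    }
    df[[col]] <- as.integer(v)
  }
  df
}

#' Write a cohort (or any tabular result) as CSV
#'
#' Comma-separated UTF-8 with header row, decimal point, `NA` written as
#' empty string — the package's single tabular dialect, readable back by
#' [read_cohort()] / [utils::read.csv()].
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write published-table-shaped validation reports
#'
#' Renders results as delimited text files mirroring the published table
#' layouts, at the published precisions (percentages to one decimal, kappa
#' to three, chi-square to one, AUC to three): an agreement/accuracy table
#' and an AUC table from a `pes_validation`, per-subscale ROC point files,
#' a reconstruction verification table from a `summary_verification`, and
#' correlation/cross-loading tables from a `pes_cca`. Repeated runs on the
#' same inputs produce byte-identical files.
#'
#' @param validation Optional `pes_validation` from [validate_cohort()].
#' @param reconstruction Optional `summary_verification` from
#'   [verify_summary_table()].
#' @param cca Optional `pes_cca` from [canonical_correlations()].
#' @param outdir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(validation = NULL, reconstruction = NULL,
                          cca = NULL, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(outdir, file)
    write_cohort(df, p)
    paths <<- c(paths, p)
  }
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "pes_validation"))
    m <- validation$metrics
    emit(data.frame(subscale_id = m$subscale_id,
                    kappa = .fmt(m$kappa, 3),
                    chi_square = .fmt(m$chi_square, 1),
                    p_value = .fmt(m$p_value, 3),
                    sensitivity_pct = format_pct(m$sensitivity),
                    specificity_pct = format_pct(m$specificity),
                    ppv_pct = format_pct(m$ppv),
                    npv_pct = format_pct(m$npv),
                    stringsAsFactors = FALSE),
         "agreement_accuracy.csv")
    emit(data.frame(subscale_id = m$subscale_id,
                    auc = .fmt(m$auc, 3),
                    auc_se = .fmt(m$auc_se, 3),
                    auc_p_value = .fmt(m$auc_p_value, 3),
                    ci_lower = .fmt(m$auc_ci_lower, 3),
                    ci_upper = .fmt(m$auc_ci_upper, 3),
                    stringsAsFactors = FALSE),
         "auc.csv")
    for (s in names(validation$roc)) {
      emit(validation$roc[[s]]$points, paste0("roc_", s, ".csv"))
    }
  }
  if (!is.null(reconstruction)) {
    stopifnot(inherits(reconstruction, "summary_verification"))
    emit(reconstruction$report, "reconstruction.csv")
  }
  if (!is.null(cca)) {
    stopifnot(inherits(cca, "pes_cca"))
    emit(data.frame(k = seq_along(cca$correlations),
                    canonical_correlation = .fmt(cca$correlations, 3),
                    wilks_lambda = .fmt(cca$wilks, 3),
                    chi_square = .fmt(cca$chi_square, 3),
                    df = cca$df,
                    p_value = .fmt(cca$p_value, 3),
                    stringsAsFactors = FALSE),
         "cca_correlations.csv")
    xl <- as.data.frame(round_half_up(cca$x_cross_loadings, 3))
    emit(cbind(data.frame(variable = rownames(cca$x_cross_loadings),
                          stringsAsFactors = FALSE), xl),
         "cca_cross_loadings_set1.csv")
    yl <- as.data.frame(round_half_up(cca$y_cross_loadings, 3))
    emit(cbind(data.frame(variable = rownames(cca$y_cross_loadings),
                          stringsAsFactors = FALSE), yl),
         "cca_cross_loadings_set2.csv")
  }
  invisible(paths)
}

.log <- function(level, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...)))
}

.usage <- function() {
  message("usage: pes <score|validate|reconstruct|cca|simulate> [options]\n",
          "  score      --cohort FILE --out FILE [--instrument FILE]",
          " [--cutoff N] [--missing error|absent]\n",
          "  validate   --cohort FILE --outdir DIR [--instrument FILE]",
          " [--cutoff N]\n",
          "  reconstruct [--summary FILE] --out FILE\n",
          "  cca        --cohort FILE --outdir DIR [--instrument FILE]\n",
          "  simulate   --out FILE [--latent FILE] [--seed N] [--n N]")
}

.parse_flags <- function(args, allowed) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- substring(a, 3L)
    if (!key %in% allowed) stop("unknown flag --", key)
    if (i + 1L > length(args)) stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands `score` (score and diagnose a cohort CSV),
#' `validate` (accuracy/agreement/ROC reports against expert labels),
#' `reconstruct` (verify a printed summary table by enumeration), `cca`
#' (canonical correlation reports from `mmse_*` columns and subscale
#' scores) and `simulate` (write a synthetic cohort and its latent-truth
#' sidecar). Structured log lines go to standard error. Exit statuses:
#' 0 success, 2 usage error, 3 data validation error, 4 internal error.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name), e.g. `c("score", "--cohort", "c.csv", "--out", "s.csv")`.
#' @return Integer exit status, invisibly.
#' @export
pes_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L ||
      !argv[1L] %in% c("score", "validate", "reconstruct", "cca",
                       "simulate")) {
    .usage()
    return(invisible(2L))
  }
  cmd <- argv[1L]
  status <- tryCatch({
    opts <- .parse_flags(argv[-1L],
                         c("cohort", "instrument", "cutoff", "missing",
                           "summary", "out", "outdir", "seed", "n",
                           "latent"))
    switch(cmd,
           score = .cmd_score(opts),
           validate = .cmd_validate(opts),
           reconstruct = .cmd_reconstruct(opts),
           cca = .cmd_cca(opts),
           simulate = .cmd_simulate(opts))
    0L
  },
  usage_error = function(e) {
    .log("error", conditionMessage(e)); .usage(); 2L
  },
  error = function(e) {
    .log("error", conditionMessage(e))
    if (inherits(e, "simpleError") &&
        grepl("unknown flag|needs a value|unexpected argument|required flag",
              conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}

.need <- function(opts, key) {
  if (is.null(opts[[key]])) stop("required flag --", key, " missing")
  opts[[key]]
}

.opt_instrument <- function(opts) {
  if (is.null(opts$instrument)) pes_instrument() else
    pes_instrument(opts$instrument)
}

.cmd_score <- function(opts) {
  inst <- .opt_instrument(opts)
  cutoff <- if (is.null(opts$cutoff)) inst$cutoff else as.numeric(opts$cutoff)
  cohort <- read_cohort(.need(opts, "cohort"), inst)
  .log("info", "scoring ", nrow(cohort), " patients")
  profiles <- profile_cohort(cohort, inst, cutoff = cutoff,
                             missing = opts$missing %||% "error")
  write_cohort(profiles, .need(opts, "out"))
  .log("info", "wrote ", opts$out)
}

.cmd_validate <- function(opts) {
  inst <- .opt_instrument(opts)
  cutoff <- if (is.null(opts$cutoff)) inst$cutoff else as.numeric(opts$cutoff)
  cohort <- read_cohort(.need(opts, "cohort"), inst)
  profiles <- profile_cohort(cohort, inst, cutoff = cutoff)
  val <- validate_cohort(profiles, cohort)
  files <- write_reports(validation = val, outdir = .need(opts, "outdir"))
  .log("info", "wrote ", length(files), " report files to ", opts$outdir)
}

.cmd_reconstruct <- function(opts) {
  rows <- if (is.null(opts$summary) || identical(opts$summary, "bundled")) {
    pes_published_summary()
  } else {
    raw <- utils::read.csv(opts$summary, colClasses = "character")
    lapply(seq_len(nrow(raw)), function(i) {
      summary_row(raw$subscale_id[i], raw$sensitivity_pct[i],
                  raw$specificity_pct[i], raw$ppv_pct[i], raw$npv_pct[i],
                  kappa = as.numeric(raw$kappa[i]),
                  chi_square = as.numeric(raw$chi_square[i]),
                  n = as.integer(raw$n[i]))
    })
  }
  ver <- verify_summary_table(rows)
  write_cohort(ver$report, .need(opts, "out"))
  .log("info", ver$n_consistent, " of ", nrow(ver$report),
       " rows fully consistent; wrote ", opts$out)
}

.cmd_cca <- function(opts) {
  inst <- .opt_instrument(opts)
  cohort <- read_cohort(.need(opts, "cohort"), inst)
  x <- as.matrix(cohort[, paste0("mmse_", names(.mmse_domains))])
  colnames(x) <- names(.mmse_domains)
  profiles <- profile_cohort(cohort, inst)
  y <- as.matrix(profiles[, paste0("score_", subscale_ids(inst))])
  colnames(y) <- subscale_ids(inst)
  cc <- canonical_correlations(x, y)
  files <- write_reports(cca = cc, outdir = .need(opts, "outdir"))
  .log("info", "first canonical correlation ",
       round(cc$correlations[1L], 3), "; wrote ", length(files), " files")
}

.cmd_simulate <- function(opts) {
  config <- simulation_config(
    n_patients = if (is.null(opts$n)) 171L else as.integer(opts$n),
    seed = if (is.null(opts$seed)) 1L else as.integer(opts$seed))
  cohort <- simulate_cohort(config)
  write_cohort(cohort$records, .need(opts, "out"))
  if (!is.null(opts$latent)) write_cohort(cohort$latent, opts$latent)
  .log("info", "simulated ", nrow(cohort$records), " patients (seed ",
       config$seed, ") to ", opts$out)
}
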