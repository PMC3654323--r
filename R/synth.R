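# MMSE domain score ranges (points)
.mmse_domains <- c(time_orientation = 5, place_orientation = 5, memory = 3,
                   attention_calculation = 5, recall = 3, language = 9)

# Default per-subscale prevalence of latent pattern-element status. Where a
# unique confusion table is recoverable from the published summary rates the
# prevalence is the recovered positive fraction (of 171); the remaining
# subscales get values in the same low-to-high span.
.default_prevalence <- c(
  kidney_deficiency  = 0.50,
  spleen_deficiency  = 0.18,
  qi_deficiency      = 0.30,   # 51/171
  blood_deficiency   = 0.25,
  yin_deficiency     = 0.35,   # 60/171
  yang_deficiency    = 0.27,
  marrow_deficiency  = 0.19,   # 33/171
  yang_hyperactivity = 0.12,   # 21/171
  endogenous_heat    = 0.13,   # 22/171
  phlegm_muddiness   = 0.60,   # 103/171
  blood_stasis       = 0.44    # 76/171
)

#' Configuration of the synthetic dementia cohort generator
#'
#' The generator emulates the validation study's data-producing process:
#' each patient has a latent binary pattern-element status per subscale,
#' clinical-feature items that are present with a status-conditional
#' probability (conditionally independent given status), three experts who
#' label each subscale with independent error, and six MMSE cognition
#' domains driven by a shared latent severity factor. Qi-deficiency and
#' blood-stasis status liabilities load on the same severity factor that
#' depresses the memory and language domains, planting the negative
#' subscale-by-cognition coupling the analysis is meant to detect.
#'
#' @param n_patients Cohort size (default 171, the study's sample).
#' @param prevalence Named per-subscale probability of latent positive
#'   status; the default spans 0.12 (yang hyperactivity) to 0.60 (phlegm
#'   muddiness), using the reconstructed positive fractions where a unique
#'   reconstruction exists.
#' @param item_prob_positive,item_prob_negative Probability that an item is
#'   present given positive / negative latent status: a scalar applied to
#'   all 77 items, or a named list of length-7 vectors per subscale id.
#'   Defaults 0.40 and 0.06.
#' @param expert_fn,expert_fp Per-expert mislabeling probabilities (miss a
#'   true positive / call a false positive), independent across experts and
#'   subscales. Defaults 0.10 and 0.05.
#' @param mmse_coupling List with `subscales` (named liability loadings on
#'   the shared severity factor, magnitudes < 1) and `domains` (named
#'   pre-truncation loadings of each MMSE domain on the same factor,
#'   negative = worse cognition with higher severity).
#' @param seed Master integer seed; expanded internally into independent
#'   per-component streams (severity, latent status, items, experts, MMSE)
#'   so that adding draws to one component does not perturb the others.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 171,
                              prevalence = .default_prevalence,
                              item_prob_positive = 0.40,
                              item_prob_negative = 0.06,
                              expert_fn = 0.10,
                              expert_fp = 0.05,
                              mmse_coupling = list(
                                subscales = c(qi_deficiency = 0.8,
                                              blood_stasis = 0.8),
                                domains = c(time_orientation = -0.2,
                                            place_orientation = -0.2,
                                            memory = -0.5,
                                            attention_calculation = -0.2,
                                            recall = -0.2,
                                            language = -0.5)),
                              seed = 1L) {
  stopifnot(n_patients >= 1,
            all(prevalence >= 0), all(prevalence <= 1),
            expert_fn >= 0, expert_fn <= 1, expert_fp >= 0, expert_fp <= 1)
  .check_probs(item_prob_positive, "item_prob_positive")
  .check_probs(item_prob_negative, "item_prob_negative")
  if (any(abs(mmse_coupling$subscales) >= 1) ||
      any(abs(mmse_coupling$domains) >= 1)) {
    stop("coupling loadings must have magnitude < 1 (unit-variance ",
         "liability decomposition is infeasible otherwise)")
  }
  unknown <- setdiff(names(mmse_coupling$domains), names(.mmse_domains))
  if (length(unknown)) stop("unknown MMSE domain: ", unknown[1L])
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 item_prob_positive = item_prob_positive,
                 item_prob_negative = item_prob_negative,
                 expert_fn = expert_fn, expert_fp = expert_fp,
                 mmse_coupling = mmse_coupling,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.check_probs <- function(p, what) {
  vals <- unlist(p)
  if (any(vals < 0) || any(vals > 1)) stop(what, " must lie in [0, 1]")
}

# per-component reproducible streams derived from the master seed
.component_seed <- function(seed, component) {
  idx <- match(component, c("severity", "latent", "items", "experts",
                            "mmse"))
  (as.numeric(seed) * 48271 + idx * 16807) %% 2147483647
}

.expand_item_probs <- function(p, instrument, what) {
  out <- lapply(instrument$subscales, function(s) {
    v <- if (is.list(p)) {
      if (is.null(p[[s$id]])) stop(what, " lacks entry for '", s$id, "'")
      p[[s$id]]
    } else rep(p, 7L)
    if (length(v) != 7L) stop(what, "$", s$id, " must have length 7")
    as.numeric(v)
  })
  names(out) <- names(instrument$subscales)
  out
}

#' Simulate a synthetic dementia cohort
#'
#' Draws a full cohort under a [simulation_config()]: latent status, item
#' responses, three independent expert labelings adjudicated per protocol
#' (experts 1 and 2 decide when they agree, expert 3 settles
#' disagreements), and integer MMSE domain scores truncated to each
#' domain's valid range. Fully reproducible: the same config (including
#' seed) yields an identical cohort.
#'
#' @param config A [simulation_config()].
#' @param instrument A `pes_instrument`; defaults to the bundled PES.
#' @return Object of class `pes_cohort`: list with `records` (cohort data
#'   frame: `patient_id`, 77 item columns, `expert_<subscale>` adjudicated
#'   labels, `mmse_<domain>` scores), `latent` (true status per patient and
#'   subscale), `raters` (3-expert label array, patients x subscales x
#'   experts), `bookkeeping` (per-subscale realized confusion counts of the
#'   adjudicated expert label and of the PES diagnosis against latent
#'   truth) and `config`.
#' @export
simulate_cohort <- function(config, instrument = pes_instrument()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(instrument, "pes_instrument"))
  n <- config$n_patients
  subs <- subscale_ids(instrument)
  prev <- config$prevalence[subs]
  if (any(is.na(prev))) {
    stop("prevalence missing for subscale '", subs[is.na(prev)][1L], "'")
  }
  p1 <- .expand_item_probs(config$item_prob_positive, instrument,
                           "item_prob_positive")
  p0 <- .expand_item_probs(config$item_prob_negative, instrument,
                           "item_prob_negative")

  set.seed(.component_seed(config$seed, "severity"))
  severity <- stats::rnorm(n)

  # latent status: probit liability, optionally loading on severity
  set.seed(.component_seed(config$seed, "latent"))
  latent <- matrix(0L, n, length(subs), dimnames = list(NULL, subs))
  for (j in seq_along(subs)) {
    a <- config$mmse_coupling$subscales[subs[j]]
    a <- if (is.na(a)) 0 else a
    liab <- a * severity + sqrt(1 - a^2) * stats::rnorm(n)
    latent[, j] <- as.integer(liab > stats::qnorm(1 - prev[j]))
  }

  set.seed(.component_seed(config$seed, "items"))
  records <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
  for (j in seq_along(subs)) {
    s <- instrument$subscales[[subs[j]]]
    pos <- latent[, j] == 1L
    for (k in 1:7) {
      pr <- ifelse(pos, p1[[subs[j]]][k], p0[[subs[j]]][k])
      records[[s$items$item_id[k]]] <- stats::rbinom(n, 1L, pr)
    }
  }

  set.seed(.component_seed(config$seed, "experts"))
  raters <- array(0L, dim = c(n, length(subs), 3L),
                  dimnames = list(NULL, subs, paste0("expert", 1:3)))
  for (e in 1:3) {
    for (j in seq_along(subs)) {
      flip <- stats::rbinom(n, 1L,
                            ifelse(latent[, j] == 1L, config$expert_fn,
                                   config$expert_fp))
      raters[, j, e] <- ifelse(flip == 1L, 1L - latent[, j], latent[, j])
    }
  }
  for (j in seq_along(subs)) {
    records[[paste0("expert_", subs[j])]] <-
      adjudicate(raters[, j, 1L], raters[, j, 2L], raters[, j, 3L])
  }

  set.seed(.component_seed(config$seed, "mmse"))
  for (d in names(.mmse_domains)) {
    l <- config$mmse_coupling$domains[d]
    l <- if (is.na(l)) 0 else l
    maxd <- .mmse_domains[[d]]
    z <- 0.55 * maxd + 0.25 * maxd *
      (l * severity + sqrt(1 - l^2) * stats::rnorm(n))
    records[[paste0("mmse_", d)]] <- pmin(maxd, pmax(0, round(z)))
  }

  profiles <- profile_cohort(records, instrument)
  bookkeeping <- do.call(rbind, lapply(seq_along(subs), function(j) {
    ex <- confusion_table(records[[paste0("expert_", subs[j])]], latent[, j])
    dx <- confusion_table(profiles[[paste0("dx_", subs[j])]], latent[, j])
    data.frame(subscale_id = subs[j],
               n_latent_positive = sum(latent[, j]),
               expert_tp = ex$tp, expert_fn = ex$fn,
               expert_fp = ex$fp, expert_tn = ex$tn,
               pes_tp = dx$tp, pes_fn = dx$fn,
               pes_fp = dx$fp, pes_tn = dx$tn,
               stringsAsFactors = FALSE)
  }))
  latent_df <- cbind(data.frame(patient_id = records$patient_id,
                                stringsAsFactors = FALSE),
                     as.data.frame(latent))
  structure(list(records = records, latent = latent_df, raters = raters,
                 bookkeeping = bookkeeping, config = config),
            class = "pes_cohort")
}

#' @export
print.pes_cohort <- function(x, ...) {
  cat("Synthetic PES cohort:", nrow(x$records), "patients,",
      ncol(x$latent) - 1L, "subscales (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Adjudicate two independent expert labels with a third
#'
#' The protocol's consensus rule: when experts 1 and 2 agree, their shared
#' label stands (the third expert is not consulted); on disagreement the
#' third expert's label decides.
#'
#' @param expert1,expert2,expert3 Binary label vectors of equal length.
#'   `expert3` may be `NA` wherever the first two agree.
#' @return Integer vector of final labels.
#' @export
adjudicate <- function(expert1, expert2, expert3) {
  if (length(expert1) != length(expert2) ||
      length(expert1) != length(expert3)) {
    stop("expert label vectors must have equal length")
  }
  ok <- function(v) all(v %in% c(0L, 1L) | is.na(v))
  if (!ok(expert1) || !ok(expert2) || !ok(expert3)) {
    stop("expert labels must be binary (0/1)")
  }
  disagree <- expert1 != expert2
  if (any(is.na(expert1) | is.na(expert2))) {
    stop("experts 1 and 2 must always provide a label")
  }
  if (any(disagree & is.na(expert3))) {
    stop("third expert label required where experts 1 and 2 disagree")
  }
  as.integer(ifelse(disagree, expert3, expert1))
}

#' Expected operating characteristics of the PES rule under a config
#'
#' Computes, by exhaustive enumeration of the 2^7 item-response patterns of
#' each subscale, the exact probability that the weighted score reaches the
#' diagnostic cut-off given positive and given negative latent status —
#' i.e. the planted sensitivity and specificity of the PES decision rule
#' under the generator's item model. Used as the closed-form reference in
#' parameter-recovery tests.
#'
#' @param x A [simulation_config()] or a `pes_cohort` (whose config is
#'   used).
#' @param instrument A `pes_instrument`; defaults to the bundled PES.
#' @return Data frame with `subscale_id`, `prevalence`,
#'   `expected_sensitivity`, `expected_specificity`.
#' @export
planted_truth_report <- function(x, instrument = pes_instrument()) {
  config <- if (inherits(x, "pes_cohort")) x$config else x
  stopifnot(inherits(config, "simulation_config"))
  p1 <- .expand_item_probs(config$item_prob_positive, instrument,
                           "item_prob_positive")
  p0 <- .expand_item_probs(config$item_prob_negative, instrument,
                           "item_prob_negative")
  patterns <- as.matrix(expand.grid(rep(list(0:1), 7L)))
  out <- do.call(rbind, lapply(instrument$subscales, function(s) {
    score <- patterns %*% s$items$weight
    hit <- as.numeric(score >= instrument$cutoff)
    prob_hit <- function(p) {
      lik <- apply(patterns, 1L, function(r) prod(p^r * (1 - p)^(1 - r)))
      sum(lik * hit)
    }
    data.frame(subscale_id = s$id,
               prevalence = unname(config$prevalence[s$id]),
               expected_sensitivity = prob_hit(p1[[s$id]]),
               expected_specificity = 1 - prob_hit(p0[[s$id]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate two variable sets with a planted first canonical correlation
#'
#' Single shared-factor construction: one variable in each set loads
#' sqrt(rho) on a common standard-normal factor, all other variables are
#' independent noise, so the population first canonical correlation is
#' exactly `rho` and all later ones are zero. Used in recovery tests of
#' [canonical_correlations()].
#'
#' @param n Number of observations.
#' @param rho Planted first canonical correlation in \[0, 1).
#' @param p,q Number of variables in each set.
#' @param seed Integer seed.
#' @return List with matrices `x` (n x p), `y` (n x q) and `rho`.
#' @export
simulate_planted_cca <- function(n, rho = 0.5, p = 6, q = 11, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n > p + q)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  x <- matrix(stats::rnorm(n * p), n, p)
  y <- matrix(stats::rnorm(n * q), n, q)
  x[, 1] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
  y[, 1] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
  list(x = x, y = y, rho = rho)
}
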