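#' Load a Pattern Element Scale instrument definition
#'
#' Reads a structured YAML instrument definition and validates it: 11
#' pattern-element subscales of exactly 7 weighted clinical-feature items
#' each, 77 items in total, every weight in (0, 6], and a positive diagnostic
#' cut-off. The definition bundled with the package encodes the published
#' PES: subscale identifiers are ASCII slugs (e.g. `yang_hyperactivity`) with
#' the printed names kept as display labels, and the diagnostic cut-off is 6
#' points (a subscale total of 6 or more diagnoses that pattern element).
#'
#' @param path Path to a YAML instrument document. The default loads the
#'   bundled PES definition.
#' @return An object of class `pes_instrument`: a list with `cutoff` (points)
#'   and `subscales`, a named list in which each element has `id`, `label`,
#'   `max_score` and an `items` data frame (`item_id`, `label`, `weight`).
#' @examples
#' inst <- pes_instrument()
#' subscale_maxima(inst)
#' @export
pes_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pes_instrument.yaml", package = "pesval")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("instrument definition file not found: ", path)
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed instrument document: ",
                             conditionMessage(e), call. = FALSE)
  )
  load_instrument(doc)
}

#' Build a validated instrument from a parsed definition document
#'
#' Lower-level constructor used by [pes_instrument()]; accepts an already
#' parsed list (e.g. from [yaml::read_yaml()]) so that programmatically
#' built definitions can be validated the same way.
#'
#' @param doc A list with fields `cutoff` and `subscales`, where each
#'   subscale has `id`, `label` and `items` (each item: `id`, `label`,
#'   `weight`).
#' @return A `pes_instrument` object.
#' @export
load_instrument <- function(doc) {
  if (!is.list(doc) || is.null(doc$subscales)) {
    stop("malformed instrument document: no 'subscales' field")
  }
  cutoff <- doc$cutoff %||% 6
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("instrument cutoff must be a single positive number")
  }
  if (length(doc$subscales) != 11L) {
    stop("instrument must have 11 subscales, found ", length(doc$subscales))
  }
  subscales <- lapply(doc$subscales, function(s) {
    if (is.null(s$id) || !nzchar(s$id)) stop("subscale without an id")
    if (length(s$items) != 7L) {
      stop("subscale '", s$id, "' must have exactly 7 items, found ",
           length(s$items))
    }
    items <- data.frame(
      item_id = vapply(s$items, function(it) as.character(it$id), ""),
      label   = vapply(s$items, function(it) as.character(it$label), ""),
      weight  = vapply(s$items, function(it) as.numeric(it$weight), 0),
      stringsAsFactors = FALSE
    )
    bad <- which(!is.finite(items$weight) | items$weight <= 0 |
                   items$weight > 6)
    if (length(bad)) {
      stop("subscale '", s$id, "': item '", items$item_id[bad[1L]],
           "' has invalid weight ", items$weight[bad[1L]],
           " (must be in (0, 6])")
    }
    if (anyDuplicated(items$item_id)) {
      stop("subscale '", s$id, "': duplicated item ids")
    }
    list(id = as.character(s$id),
         label = as.character(s$label %||% s$id),
         items = items,
         max_score = sum(items$weight))
  })
  names(subscales) <- vapply(subscales, `[[`, "", "id")
  if (anyDuplicated(names(subscales))) stop("duplicated subscale ids")
  all_items <- unlist(lapply(subscales, function(s) s$items$item_id))
  if (length(all_items) != 77L || anyDuplicated(all_items)) {
    stop("instrument must define 77 distinct items across subscales")
  }
  structure(list(cutoff = cutoff, subscales = subscales),
            class = "pes_instrument")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pes_instrument <- function(x, ...) {
  cat("Pattern Element Scale instrument:", length(x$subscales),
      "subscales,", sum(vapply(x$subscales, function(s) nrow(s$items), 0L)),
      "items, cutoff", x$cutoff, "points\n")
  for (s in x$subscales) {
    cat(sprintf("  %-20s %-20s max %5.1f\n", s$id, s$label, s$max_score))
  }
  invisible(x)
}

#' Subscale identifiers of an instrument
#' @param instrument A `pes_instrument` object.
#' @return Character vector of the 11 subscale ids, in instrument order.
#' @export
subscale_ids <- function(instrument) {
  stopifnot(inherits(instrument, "pes_instrument"))
  names(instrument$subscales)
}

#' Maximum attainable score of each subscale
#' @param instrument A `pes_instrument` object.
#' @return Named numeric vector of per-subscale maxima (sum of item weights).
#' @export
subscale_maxima <- function(instrument) {
  stopifnot(inherits(instrument, "pes_instrument"))
  vapply(instrument$subscales, `[[`, 0, "max_score")
}

#' All item definitions of an instrument as one table
#' @param instrument A `pes_instrument` object.
#' @return Data frame with `subscale_id`, `item_id`, `label`, `weight`
#'   (77 rows for the bundled PES).
#' @export
instrument_items <- function(instrument) {
  stopifnot(inherits(instrument, "pes_instrument"))
  do.call(rbind, lapply(instrument$subscales, function(s) {
    cbind(subscale_id = s$id, s$items, stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Score one subscale from item responses
#'
#' The subscale score is the weighted sum of present items:
#' score = sum over items of weight_i * presence_i, with presence coded 0/1.
#' Half-point weights are carried exactly; no rounding is applied.
#'
#' @param responses Named vector of 0/1 presence indicators; names are item
#'   ids. Extra items are ignored.
#' @param subscale One element of `instrument$subscales`.
#' @param missing Missing-response policy: `"error"` (default, strict) stops
#'   naming the missing item; `"absent"` treats a missing response as item
#'   not present. The study protocol reports no missing data, so strictness
#'   is the safe default.
#' @return The subscale score in points, between 0 and the subscale maximum.
#' @export
score_subscale <- function(responses, subscale,
                           missing = c("error", "absent")) {
  missing <- match.arg(missing)
  ids <- subscale$items$item_id
  r <- responses[ids]
  miss <- is.na(r)
  if (any(miss)) {
    if (missing == "error") {
      stop("missing response for item '", ids[which(miss)[1L]],
           "' of subscale '", subscale$id, "'")
    }
    r[miss] <- 0
  }
  if (!all(r %in% c(0, 1))) {
    bad <- ids[which(!(r %in% c(0, 1)))[1L]]
    stop("non-binary response for item '", bad, "': ", r[[bad]])
  }
  sum(subscale$items$weight * as.numeric(r))
}

#' Pattern-element diagnosis from a subscale score
#'
#' A pattern element is diagnosed when the subscale score reaches the
#' cut-off; the comparison is inclusive (score >= cutoff).
#'
#' @param score Subscale score(s) in points; must be non-negative.
#' @param cutoff Diagnostic cut-off in points (default 6).
#' @return Logical vector: `TRUE` where the pattern element is diagnosed.
#' @export
diagnose <- function(score, cutoff = 6) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("scores must be finite and non-negative")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  score >= cutoff
}

#' Score and diagnose a whole cohort
#'
#' Applies [score_subscale()] and [diagnose()] over every patient and
#' subscale. Deterministic and order-preserving: one output row per input
#' row, in input order.
#'
#' @param cohort Data frame with a `patient_id` column and one 0/1 column
#'   per instrument item id (see [read_cohort()]).
#' @param instrument A `pes_instrument` object.
#' @param cutoff Diagnostic cut-off; defaults to the instrument's.
#' @param missing Missing-response policy passed to [score_subscale()].
#' @return Data frame with `patient_id`, one `score_<subscale_id>` column
#'   (points) and one `dx_<subscale_id>` column (0/1 diagnosis) per subscale.
#' @export
profile_cohort <- function(cohort, instrument, cutoff = instrument$cutoff,
                           missing = c("error", "absent")) {
  stopifnot(inherits(instrument, "pes_instrument"))
  missing <- match.arg(missing)
  if (!"patient_id" %in% names(cohort)) stop("cohort lacks a patient_id column")
  if (anyDuplicated(cohort$patient_id)) {
    dup <- cohort$patient_id[duplicated(cohort$patient_id)][1L]
    stop("duplicate patient_id: '", dup, "'")
  }
  out <- data.frame(patient_id = cohort$patient_id,
                    stringsAsFactors = FALSE)
  for (s in instrument$subscales) {
    ids <- s$items$item_id
    present <- ids %in% names(cohort)
    if (!all(present) && missing == "error") {
      stop("cohort lacks response column '", ids[!present][1L],
           "' for subscale '", s$id, "'")
    }
    m <- matrix(0, nrow = nrow(cohort), ncol = length(ids))
    for (j in seq_along(ids)) {
      if (present[j]) {
        v <- cohort[[ids[j]]]
        if (any(is.na(v))) {
          if (missing == "error") {
            stop("missing response in column '", ids[j], "'")
          }
          v[is.na(v)] <- 0
        }
        if (!all(v %in% c(0, 1))) {
          stop("non-binary response in column '", ids[j], "'")
        }
        m[, j] <- v
      }
    }
    score <- as.numeric(m %*% s$items$weight)
    out[[paste0("score_", s$id)]] <- score
    out[[paste0("dx_", s$id)]] <- as.integer(diagnose(score, cutoff))
  }
  out
}

# MMSE cut-off defining cognitive impairment, by education level
.mmse_cutoffs <- c(illiteracy = 19, primary = 22, middle = 23, higher = 26)

#' Screen study eligibility from clinical covariates
#'
#' Implements the dementia-cohort inclusion thresholds: MMSE total at or
#' below the education-specific cut-off (19 illiteracy, 22 primary school,
#' 23 middle school, 26 higher education), impaired activities of daily
#' living (ADL >= 16), clinical dementia rating CDR >= 0.5, and Hamilton
#' depression score HAMD <= 12 (excluding depression-driven impairment).
#'
#' @param mmse_total MMSE total score (0-30).
#' @param education One of `"illiteracy"`, `"primary"`, `"middle"`,
#'   `"higher"`.
#' @param adl Activities-of-daily-living score.
#' @param cdr Clinical dementia rating.
#' @param hamd 17-item Hamilton depression score.
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
eligibility_screen <- function(mmse_total, education, adl, cdr, hamd) {
  education <- as.character(education)
  if (!education %in% names(.mmse_cutoffs)) {
    stop("unknown education level '", education, "' (expected one of ",
         paste(names(.mmse_cutoffs), collapse = ", "), ")")
  }
  reasons <- character()
  if (!(mmse_total <= .mmse_cutoffs[[education]])) {
    reasons <- c(reasons, sprintf("MMSE %s exceeds cutoff %s for %s education",
                                  mmse_total, .mmse_cutoffs[[education]],
                                  education))
  }
  if (!(adl >= 16)) reasons <- c(reasons, sprintf("ADL %s < 16", adl))
  if (!(cdr >= 0.5)) reasons <- c(reasons, sprintf("CDR %s < 0.5", cdr))
  if (!(hamd <= 12)) reasons <- c(reasons, sprintf("HAMD %s > 12", hamd))
  list(eligible = length(reasons) == 0L, reasons = reasons)
}
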