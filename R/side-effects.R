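#' Side-effect checklist items and categories
#'
#' The 12-item self-report checklist covers insomnia, daytime sleepiness,
#' restlessness, muscle spasms/twitching, dry mouth, profuse sweating,
#' sexual disorders, nausea, constipation, diarrhoea, weight gain and
#' dizziness, administered for each antidepressant at the interval periods
#' 3, 5, 7 and 9. Items are grouped pharmacologically: seven serotonergic,
#' two cholinergic (dry mouth, constipation) and two histaminergic (daytime
#' sleepiness, weight gain); dizziness belongs to the total only.
#'
#' @return `asec_items()`: character vector of the 12 item names in order.
#'   `asec_categories()`: named list of integer item indices per category
#'   (`TOTAL`, `SEROTONERGIC`, `CHOLINERGIC`, `HISTAMINERGIC`).
#' @export
asec_items <- function() {
  c("insomnia", "daytime_sleepiness", "restlessness", "muscle_spasms",
    "dry_mouth", "profuse_sweating", "sexual_disorders", "nausea",
    "constipation", "diarrhoea", "weight_gain", "dizziness")
}

#' @rdname asec_items
#' @export
asec_categories <- function() {
  list(
    TOTAL = 1:12,
    SEROTONERGIC = c(1L, 3L, 4L, 6L, 7L, 8L, 10L),
    CHOLINERGIC = c(5L, 9L),
    HISTAMINERGIC = c(2L, 11L)
  )
}

.asec_periods <- c(3L, 5L, 7L, 9L)

#' Count reported side effects in a category
#'
#' @param items Binary vector of length 12, in the order of [asec_items()],
#'   with 1 = reported.
#' @param category One of `"TOTAL"`, `"SEROTONERGIC"`, `"CHOLINERGIC"`,
#'   `"HISTAMINERGIC"`.
#' @return Integer count of reported items in the category.
#' @examples
#' count_side_effects(rep(1, 12), "SEROTONERGIC") # 7
#' @export
count_side_effects <- function(items, category = "TOTAL") {
  cats <- asec_categories()
  category <- match.arg(category, names(cats))
  items <- as.integer(items)
  if (length(items) != 12 || anyNA(items) || !all(items %in% c(0L, 1L))) {
    stop("items must be 12 binary indicators", call. = FALSE)
  }
  sum(items[cats[[category]]])
}

# normalize an ASEC response table: accepts 1 = reported (default) or the
# questionnaire's transcription 0 = reported via coding = "zero_reported"
normalize_asec <- function(asec, coding = c("one_reported", "zero_reported")) {
  coding <- match.arg(coding)
  item_cols <- sprintf("item_%02d", 1:12)
  if (!all(c("patient_id", "period", "atc", item_cols) %in% names(asec))) {
    stop("asec must have columns patient_id, period, atc, item_01..item_12",
         call. = FALSE)
  }
  if (!all(asec$period %in% .asec_periods)) {
    stop("ASEC periods must lie in {3, 5, 7, 9}", call. = FALSE)
  }
  items <- as.matrix(asec[, item_cols])
  if (anyNA(items) || !all(items %in% c(0, 1))) {
    stop("ASEC items must be binary", call. = FALSE)
  }
  if (coding == "zero_reported") items <- 1 - items
  asec[, item_cols] <- items
  asec
}

#' Per-patient side-effect means for an enzyme subsample
#'
#' Two-stage averaging: within each assessment period the reported-item
#' counts are averaged over the patient's qualifying antidepressants (those
#' whose substrate class matches the enzyme; drugs metabolized by both
#' enzymes qualify for either), then the period means are averaged over the
#' periods at which the patient has a qualifying response — periods without
#' one are dropped from the denominator, not imputed as zero.
#'
#' `patient_period_mean()` returns the first stage (one row per
#' patient-period), `patient_overall_mean()` the second (one row per
#' patient).
#'
#' @param asec Data.frame `patient_id`, `period`, `atc`,
#'   `item_01`..`item_12`.
#' @param enzyme `"CYP2D6"` or `"CYP2C19"`.
#' @param category Side-effect category (see [asec_categories()]).
#' @param substrates Substrate table.
#' @param coding `"one_reported"` (canonical) or `"zero_reported"` (the
#'   questionnaire's printed convention).
#' @return A data.frame of means; empty (zero rows) when no response
#'   qualifies.
#' @export
patient_period_mean <- function(asec, enzyme = c("CYP2D6", "CYP2C19"),
                                category = "TOTAL",
                                substrates = substrate_table(),
                                coding = "one_reported") {
  enzyme <- match.arg(enzyme)
  asec <- normalize_asec(asec, coding)
  qualifies <- if (enzyme == "CYP2D6") {
    is_cyp2d6_substrate(asec$atc, substrates)
  } else {
    is_cyp2c19_substrate(asec$atc, substrates)
  }
  asec <- asec[qualifies, , drop = FALSE]
  if (nrow(asec) == 0) {
    return(data.frame(patient_id = character(0), period = integer(0),
                      mean_count = numeric(0)))
  }
  item_cols <- sprintf("item_%02d", 1:12)
  counts <- apply(asec[, item_cols], 1, count_side_effects, category = category)
  agg <- stats::aggregate(
    counts,
    by = list(patient_id = as.character(asec$patient_id),
              period = as.integer(asec$period)),
    FUN = mean
  )
  names(agg)[3] <- "mean_count"
  agg[order(agg$patient_id, agg$period), , drop = FALSE]
}

#' @rdname patient_period_mean
#' @export
patient_overall_mean <- function(asec, enzyme = c("CYP2D6", "CYP2C19"),
                                 category = "TOTAL",
                                 substrates = substrate_table(),
                                 coding = "one_reported") {
  pm <- patient_period_mean(asec, enzyme, category, substrates, coding)
  if (nrow(pm) == 0) {
    return(data.frame(patient_id = character(0), mean_count = numeric(0)))
  }
  agg <- stats::aggregate(pm$mean_count, by = list(patient_id = pm$patient_id),
                          FUN = mean)
  names(agg)[2] <- "mean_count"
  agg[order(agg$patient_id), , drop = FALSE]
}
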