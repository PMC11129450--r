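#' The 11-period observation structure
#'
#' Medication use is recorded over eleven ordered periods spanning three
#' years before baseline to the 9-year follow-up. Odd periods 1,3,5,7,9 are
#' intervals ("use between assessments"); even periods 2,4,6,8,10 and
#' period 11 are current use at an assessment.
#'
#' @return A data.frame with columns `index`, `kind`, `label`.
#' @export
observation_periods <- function() {
  idx <- 1:11
  kind <- ifelse(idx %% 2 == 1 & idx < 11, "INTERVAL", "CURRENT")
  label <- c(
    "3y before baseline to baseline", "current at baseline",
    "baseline to 1y FU", "current at 1y FU",
    "1y to 2y FU", "current at 2y FU",
    "2y to 4y FU", "current at 4y FU",
    "4y to 6y FU", "current at 6y FU",
    "current at 9y FU"
  )
  data.frame(index = idx, kind = kind, label = label, stringsAsFactors = FALSE)
}

#' Construct a medication timeline
#'
#' A timeline holds, for one patient, the set of ATC codes used in each
#' assessed period. Unassessed periods carry no information and are skipped
#' (not imputed as drug-free) by every downstream rule.
#'
#' @param meds Named list mapping period index (as name) to a character
#'   vector of ATC codes (possibly empty). Periods listed here must be
#'   assessed.
#' @param assessed Integer vector of assessed period indices (subset of
#'   1..11). Defaults to all periods named in `meds`, or all 11 if `meds`
#'   names cover none.
#' @return An object of class `med_timeline` with fields `periods` (sorted
#'   assessed indices) and `meds` (list of ATC sets aligned with `periods`).
#' @examples
#' tl <- medication_timeline(list(`1` = "N06AB05", `2` = "N06AB05"),
#'                           assessed = 1:11)
#' @export
medication_timeline <- function(meds = list(), assessed = NULL) {
  p_named <- as.integer(names(meds))
  if (length(meds) > 0 && anyNA(p_named)) {
    stop("meds must be named by period index", call. = FALSE)
  }
  if (is.null(assessed)) assessed <- if (length(p_named)) sort(unique(p_named)) else 1:11
  assessed <- sort(unique(as.integer(assessed)))
  if (any(assessed < 1 | assessed > 11)) {
    stop("period indices must lie in 1..11", call. = FALSE)
  }
  if (!all(p_named %in% assessed)) {
    stop("meds recorded at unassessed period(s)", call. = FALSE)
  }
  sets <- lapply(assessed, function(p) {
    i <- which(p_named == p)
    if (length(i) == 0) character(0) else unique(as.character(unlist(meds[i])))
  })
  structure(list(periods = assessed, meds = sets), class = "med_timeline")
}

#' @export
print.med_timeline <- function(x, ...) {
  cat("medication timeline:", length(x$periods), "assessed period(s)\n")
  for (i in seq_along(x$periods)) {
    cat(sprintf("  period %2d: %s\n", x$periods[i],
                if (length(x$meds[[i]])) paste(x$meds[[i]], collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Eligible index antidepressant of a timeline
#'
#' A patient enters the analysis with the single antidepressant used in
#' period 1, or the single antidepressant started at the first assessed
#' period in 2..10 with all earlier assessed periods drug-free. Starting on
#' more than one antidepressant, or never using one within periods 1–10,
#' makes the patient ineligible (returned as `NULL`, not an error).
#'
#' @param timeline A `med_timeline`.
#' @return `NULL`, or a list with `atc` and `start_period`.
#' @export
eligible_index_ad <- function(timeline) {
  keep <- timeline$periods <= 10
  p <- timeline$periods[keep]
  m <- timeline$meds[keep]
  nz <- which(lengths(m) > 0)
  if (length(nz) == 0) return(NULL)
  first <- nz[1]
  if (length(m[[first]]) != 1) return(NULL)
  list(atc = m[[first]], start_period = p[first])
}

#' Comparison pairs of a timeline
#'
#' Treatment-status comparisons are made between successive periods with
#' antidepressant use. Two consecutive assessed use-periods form an
#' ordinary pair; two use-periods interspersed by one or more drug-free
#' periods form a gap-spanning pair, which is preferred — the consecutive
#' comparisons inside the gap are neglected.
#'
#' @param timeline A `med_timeline`.
#' @return A data.frame `earlier`, `later`, `gap_spanning` (possibly
#'   zero rows).
#' @export
comparison_pairs <- function(timeline) {
  p <- timeline$periods
  use <- which(lengths(timeline$meds) > 0)
  if (length(use) < 2) {
    return(data.frame(earlier = integer(0), later = integer(0),
                      gap_spanning = logical(0)))
  }
  earlier <- p[use[-length(use)]]
  later <- p[use[-1]]
  data.frame(earlier = earlier, later = later,
             gap_spanning = (later - earlier) > 1L)
}

# switch predicate on one pair: both period sets non-empty and disjoint
# (carrying the original AD forward alongside an added one is not a switch)
is_switch_pair <- function(set1, set2) {
  length(set1) > 0 && length(set2) > 0 && !any(set1 %in% set2)
}

#' Classify one treatment trajectory
#'
#' Applies the longitudinal definitions: *switched* if any comparison pair
#' (including gap-spanning ones) moves to a disjoint set of
#' antidepressants; otherwise *discontinued* if use occurs in periods 1–4
#' but in no assessed period 5–11 and at least one period beyond 4 was
#' assessed; *not classifiable* if use is confined to periods 1–4 and no
#' later period was assessed (continuation cannot be ruled out); otherwise
#' *maintained*. Period 11 takes part in switch comparisons and in the
#' 5–11 emptiness test, while eligibility rests on use within periods 1–10.
#'
#' @param timeline A `med_timeline` for which [eligible_index_ad()] returns
#'   a value.
#' @return One of `"MAINTAINED"`, `"SWITCHED"`, `"DISCONTINUED"`,
#'   `"NOT_CLASSIFIABLE"`.
#' @export
classify_trajectory <- function(timeline) {
  if (is.null(eligible_index_ad(timeline))) {
    stop("timeline has no eligible index antidepressant", call. = FALSE)
  }
  p <- timeline$periods
  m <- timeline$meds
  use <- which(lengths(m) > 0)
  if (length(use) >= 2) {
    for (k in seq_len(length(use) - 1)) {
      if (is_switch_pair(m[[use[k]]], m[[use[k + 1]]])) return("SWITCHED")
    }
  }
  use_after4 <- any(p[use] >= 5)
  if (use_after4) return("MAINTAINED")
  if (any(p >= 5)) "DISCONTINUED" else "NOT_CLASSIFIABLE"
}

#' Enzyme subsample membership of an index antidepressant
#'
#' Patients enter the CYP2D6 and/or CYP2C19 analysis subsamples according
#' to the substrate class of their index antidepressant; drugs metabolized
#' by both enzymes contribute to both subsamples, non-substrates to
#' neither. Membership is fixed by the index drug even if the patient later
#' switches to a different substrate class.
#'
#' @param atc ATC code of the index antidepressant.
#' @param table Substrate table.
#' @return Character vector, a subset of `c("CYP2D6", "CYP2C19")`.
#' @export
subsample_membership <- function(atc, table = substrate_table()) {
  switch(substrate_class(atc, table),
         CYP2D6_ONLY = "CYP2D6",
         CYP2C19_ONLY = "CYP2C19",
         BOTH = c("CYP2D6", "CYP2C19"),
         NEITHER = character(0))
}

# build med_timeline objects for a cohort from long-format records;
# returns a named list keyed by patient_id
build_timelines <- function(medications, participation = NULL) {
  req <- c("patient_id", "period", "atc")
  if (!all(req %in% names(medications))) {
    stop("medications must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  pids <- unique(as.character(
    c(medications$patient_id,
      if (!is.null(participation)) participation$patient_id)
  ))
  med_split <- split(
    data.frame(period = as.integer(medications$period),
               atc = as.character(medications$atc), stringsAsFactors = FALSE),
    factor(as.character(medications$patient_id), levels = pids)
  )
  if (!is.null(participation)) {
    part <- participation[as.logical(participation$assessed), , drop = FALSE]
    part_split <- split(as.integer(part$period),
                        factor(as.character(part$patient_id), levels = pids))
  }
  out <- vector("list", length(pids))
  names(out) <- pids
  empty <- character(0)
  for (i in seq_along(pids)) {
    md <- med_split[[i]]
    assessed <- if (is.null(participation)) 1:11 else sort(unique(part_split[[i]]))
    if (nrow(md) == 0) {
      sets <- rep(list(empty), length(assessed))
    } else {
      if (!all(md$period %in% assessed)) {
        stop("meds recorded at unassessed period(s) for patient ", pids[i],
             call. = FALSE)
      }
      by_period <- split(md$atc, md$period)
      sets <- rep(list(empty), length(assessed))
      hit <- match(as.integer(names(by_period)), assessed)
      sets[hit] <- lapply(by_period, unique)
    }
    out[[i]] <- structure(list(periods = assessed, meds = sets),
                          class = "med_timeline")
  }
  out
}

#' Classify all trajectories in a cohort
#'
#' Builds per-patient timelines from long-format medication and
#' participation records, determines index-drug eligibility, classifies the
#' eligible trajectories and records subsample membership.
#'
#' @param medications Data.frame `patient_id`, `period`, `atc` (one row per
#'   drug used in a period).
#' @param participation Optional data.frame `patient_id`, `period`,
#'   `assessed`; when `NULL` all 11 periods count as assessed for every
#'   patient.
#' @param substrates Substrate table for subsample membership.
#' @return A data.frame with one row per patient: `patient_id`, `eligible`,
#'   `index_atc`, `start_period`, `label` (`NA` for ineligible patients),
#'   `in_cyp2d6`, `in_cyp2c19`.
#' @export
classify_cohort <- function(medications, participation = NULL,
                            substrates = substrate_table()) {
  tls <- build_timelines(medications, participation)
  n <- length(tls)
  eligible <- logical(n); index_atc <- rep(NA_character_, n)
  start_period <- rep(NA_integer_, n); label <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    el <- eligible_index_ad(tls[[i]])
    if (is.null(el)) next
    eligible[i] <- TRUE
    index_atc[i] <- el$atc
    start_period[i] <- el$start_period
    label[i] <- classify_trajectory(tls[[i]])
  }
  cls <- rep(NA_character_, n)
  known <- !is.na(index_atc)
  cls[known] <- substrate_class(index_atc[known], substrates)
  data.frame(
    patient_id = names(tls),
    eligible = eligible,
    index_atc = index_atc,
    start_period = start_period,
    label = label,
    in_cyp2d6 = !is.na(cls) & cls %in% c("CYP2D6_ONLY", "BOTH"),
    in_cyp2c19 = !is.na(cls) & cls %in% c("CYP2C19_ONLY", "BOTH"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Tabulate reasons for discontinuing by enzyme and metabolizer group
#'
#' Considers the three assessment transitions (period 5 to 6, 7 to 8, and
#' 9 to 10). A patient contributes an event at a transition when both
#' periods were assessed, the earlier period had antidepressant use, and
#' the drug set either emptied (discontinuation) or moved to a disjoint set
#' (switch). The self-reported reason is matched on the earlier (interval)
#' period and a drug from that period's set; events are grouped by the
#' substrate class of the prior drug(s) and by collapsed metabolizer group
#' (NM versus IM/PM for CYP2D6; NM versus IM/PM/UM for CYP2C19).
#'
#' @param medications,participation Long-format cohort records (see
#'   [classify_cohort()]).
#' @param reasons Data.frame `patient_id`, `period`, `atc`, `reason` with
#'   reasons in `symptom_free`, `ineffective`, `side_effects`.
#' @param phenotypes Output of [assign_phenotypes()].
#' @param substrates Substrate table.
#' @return A data.frame `enzyme`, `group`, `reason`, `n` covering every
#'   enzyme-group-reason cell (zero-filled).
#' @export
reasons_table <- function(medications, participation = NULL, reasons,
                          phenotypes, substrates = substrate_table()) {
  valid_reasons <- c("symptom_free", "ineffective", "side_effects")
  if (nrow(reasons) > 0 && !all(reasons$reason %in% valid_reasons)) {
    stop("reasons must be one of ", paste(valid_reasons, collapse = ", "),
         call. = FALSE)
  }
  tls <- build_timelines(medications, participation)
  transitions <- list(c(5L, 6L), c(7L, 8L), c(9L, 10L))

  # collect (patient, prior period, prior ATCs) for each switch/discontinue event
  events <- list()
  for (pid in names(tls)) {
    tl <- tls[[pid]]
    for (tr in transitions) {
      i1 <- match(tr[1], tl$periods); i2 <- match(tr[2], tl$periods)
      if (is.na(i1) || is.na(i2)) next
      s1 <- tl$meds[[i1]]; s2 <- tl$meds[[i2]]
      if (length(s1) == 0) next
      discontinued <- length(s2) == 0
      switched <- is_switch_pair(s1, s2)
      if (discontinued || switched) {
        events[[length(events) + 1]] <- list(pid = pid, period = tr[1], atcs = s1)
      }
    }
  }

  ph_key <- paste(phenotypes$patient_id, phenotypes$gene)
  ph_status <- stats::setNames(phenotypes$status, ph_key)
  cells <- expand.grid(
    enzyme = c("CYP2D6", "CYP2C19"),
    group = c("NM", "IM/PM", "IM/PM/UM"),
    reason = valid_reasons,
    stringsAsFactors = FALSE
  )
  cells <- cells[(cells$enzyme == "CYP2D6" & cells$group %in% c("NM", "IM/PM")) |
                 (cells$enzyme == "CYP2C19" & cells$group %in% c("NM", "IM/PM/UM")), ]
  cells$n <- 0L

  used <- rep(FALSE, nrow(reasons))
  r_key <- paste(reasons$patient_id, reasons$period, reasons$atc)
  for (ev in events) {
    hit <- which(r_key %in% paste(ev$pid, ev$period, ev$atcs))
    if (length(hit) == 0) next
    used[hit] <- TRUE
    reason <- reasons$reason[hit[1]]
    for (enz in unique(unlist(lapply(ev$atcs, subsample_membership, table = substrates)))) {
      gene_status <- ph_status[paste(ev$pid, enz)]
      if (is.na(gene_status) || gene_status == "UNKNOWN") next
      grp <- if (enz == "CYP2D6") {
        if (gene_status == "NM") "NM" else "IM/PM"
      } else {
        if (gene_status == "NM") "NM" else "IM/PM/UM"
      }
      row <- which(cells$enzyme == enz & cells$group == grp & cells$reason == reason)
      cells$n[row] <- cells$n[row] + 1L
    }
  }
  if (any(!used) && nrow(reasons) > 0) {
    warning(sum(!used), " reason record(s) without a matching medication change",
            " were excluded", call. = FALSE)
  }
  rownames(cells) <- NULL
  cells
}
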