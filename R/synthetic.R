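#' Default star-allele frequencies for the synthetic cohort
#'
#' Per-gene allele frequencies whose Hardy-Weinberg-implied phenotype
#' prevalences approximate a North-European depression/anxiety cohort
#' (CYP2C19 PM ~2.5%, IM ~21%, NM ~71%, UM ~6%; CYP2D6 PM ~2.4%, IM ~14%,
#' NM ~81% after array-based calling that collapses unidentifiable alleles
#' to *1). The class-level frequencies come from
#' [calibrate_allele_freqs()]; within a functional class the mass is split
#' across alleles in roughly European proportions (the phenotype depends
#' only on the class totals). The CYP2D6 printed prevalences are not
#' exactly Hardy-Weinberg-consistent, so the calibration is a compromise
#' fit; see the methods vignette.
#'
#' @return Named list with one named numeric vector of frequencies per
#'   gene, each summing to 1.
#' @export
default_allele_freqs <- function() {
  list(
    CYP2D6 = c(
      "*1" = 0.51496, "*2" = 0.34330,            # full
      "*4" = 0.07798, "*3" = 0.00917, "*6" = 0.00459, # inactive
      "*41" = 0.03250, "*10" = 0.01250, "*17" = 0.00500 # reduced
    ),
    CYP2C19 = c(
      "*1" = 0.62953,                             # full
      "*2" = 0.12221, "*3" = 0.00643,             # inactive
      "*17" = 0.24183                             # increased
    )
  )
}

#' Calibrate allele class frequencies to target phenotype prevalences
#'
#' Finds per-functional-class allele frequencies whose Hardy-Weinberg
#' diplotype distribution best matches target phenotype prevalences, by
#' minimizing the squared Hellinger distance on the prevalence simplex
#' (multistart BFGS over softmax-parameterized frequencies). For CYP2D6
#' the reduced-function class can be pinned to a fixed share (`qr_fixed`):
#' the usual targets are not exactly Hardy-Weinberg-attainable and an
#' unconstrained fit drives the reduced class to zero, which is
#' unrealistic; the fit quality is insensitive to this share.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @param targets Named prevalence vector. CYP2D6: `PM`, `IM`, `NM`
#'   (among patients with a known status); CYP2C19: `PM`, `IM`, `NM`,
#'   `UM`. Renormalized to sum to 1.
#' @param qr_fixed Fixed CYP2D6 reduced-class frequency (ignored for
#'   CYP2C19).
#' @param n_starts Number of random optimizer starts.
#' @return Named vector of class frequencies (`full`, `reduced`,
#'   `inactive` for CYP2D6; `full`, `inactive`, `increased` for CYP2C19)
#'   with attribute `fitted` holding the implied prevalences.
#' @export
calibrate_allele_freqs <- function(gene = c("CYP2D6", "CYP2C19"),
                                   targets = NULL, qr_fixed = 0.05,
                                   n_starts = 10) {
  gene <- match.arg(gene)
  if (gene == "CYP2C19") {
    if (is.null(targets)) targets <- c(PM = 0.025, IM = 0.209, NM = 0.707, UM = 0.059)
    targets <- targets[c("PM", "IM", "NM", "UM")] / sum(targets)
    model <- function(f) { # f = (full, inactive, increased)
      c(PM = f[2]^2, IM = 2 * f[2] * (f[1] + f[3]),
        NM = f[1]^2 + 2 * f[1] * f[3], UM = f[3]^2)
    }
    obj <- function(theta) {
      w <- exp(c(theta, 0)); f <- w / sum(w)
      sum((sqrt(model(f)) - sqrt(targets))^2)
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      o <- stats::optim(stats::rnorm(2, sd = 1), obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    w <- exp(c(best$par, 0)); f <- w / sum(w)
    out <- c(full = f[1], inactive = f[2], increased = f[3])
    attr(out, "fitted") <- model(f)
    return(out)
  }
  if (is.null(targets)) targets <- c(PM = 0.024, IM = 0.142, NM = 0.813)
  targets <- targets[c("PM", "IM", "NM")] / sum(targets)
  model <- function(pf, qr, qi) {
    c(PM = qi^2, IM = 2 * qi * qr + qr^2 + 2 * qi * pf,
      NM = pf^2 + 2 * pf * qr)
  }
  obj <- function(theta) { # theta: logit of qi share of the free mass
    qi <- stats::plogis(theta) * (1 - qr_fixed)
    pf <- 1 - qr_fixed - qi
    sum((sqrt(model(pf, qr_fixed, qi)) - sqrt(targets))^2)
  }
  o <- stats::optimize(obj, c(-10, 5))
  qi <- stats::plogis(o$minimum) * (1 - qr_fixed)
  pf <- 1 - qr_fixed - qi
  out <- c(full = pf, reduced = qr_fixed, inactive = qi)
  attr(out, "fitted") <- model(pf, qr_fixed, qi)
  out
}

#' Default index-antidepressant sampling frequencies
#'
#' Sampling weights for the index antidepressant, proportional to the drug
#' distribution of a Dutch depression/anxiety cohort of 928 single-drug
#' starters (SSRIs dominate, paroxetine and citalopram most common; three
#' patients on non-substrate drugs are retained).
#'
#' @return Data.frame `atc`, `name`, `weight` (counts; normalized at use).
#' @export
default_ad_freqs <- function() {
  data.frame(
    atc = c("N06AA09", "N06AB04", "N06AA04", "N06AX21", "N06AB10",
            "N06AB03", "N06AB08", "N06AA02", "N06AA21", "N06AX03",
            "N06AX11", "N06AG02", "N06AA10", "N06AB05", "N06AB06",
            "N06AF04", "N06AX05", "N06AX02", "N06AX16"),
    name = c("amitriptyline", "citalopram", "clomipramine", "duloxetine",
             "escitalopram", "fluoxetine", "fluvoxamine", "imipramine",
             "maprotiline", "mianserin", "mirtazapine", "moclobemide",
             "nortriptyline", "paroxetine", "sertraline", "tranylcypromine",
             "trazodone", "tryptophan", "venlafaxine"),
    weight = c(53, 146, 33, 9, 18, 77, 53, 2, 2, 2, 63, 2, 5, 283, 59,
               1, 4, 2, 114),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' the conditions of a naturalistic North-European depression/anxiety
#' cohort: 928 patients, Hardy-Weinberg diplotypes at
#' [default_allele_freqs()], 2.2% failed CYP2D6 imputation, a
#' 52/35/13 maintained/switched/discontinued trajectory mixture, index
#' drugs at [default_ad_freqs()], null metabolizer effects, moderate
#' side-effect report probabilities and a 40/25/35 split of
#' discontinuation reasons.
#'
#' @param n_patients Cohort size.
#' @param allele_freqs Per-gene named frequency vectors (must each sum
#'   to 1).
#' @param trajectory_mixture Named probabilities `maintained`, `switched`,
#'   `discontinued`, summing to 1.
#' @param effect_log_or Named list per gene of log odds ratios applied to
#'   the switch and discontinue odds of the collapsed non-reference
#'   groups, e.g. `list(CYP2D6 = c("IM/PM" = log(2)))`.
#' @param asec_item_prob Named per-item report probabilities by category
#'   (`SEROTONERGIC`, `CHOLINERGIC`, `HISTAMINERGIC`, `OTHER` for
#'   dizziness).
#' @param reason_probs Named probabilities `symptom_free`, `ineffective`,
#'   `side_effects`, summing to 1.
#' @param unknown_rate Probability that CYP2D6 imputation quality fails.
#' @param assessed_prob Per-period probability of being assessed.
#' @param ad_freqs Index-drug weights (data.frame `atc`, `weight`).
#' @param start_p1 Probability that the index drug is already in use in
#'   period 1; the remaining mass is uniform over start periods 2-10.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 928,
                          allele_freqs = default_allele_freqs(),
                          trajectory_mixture = c(maintained = 0.52,
                                                 switched = 0.35,
                                                 discontinued = 0.13),
                          effect_log_or = list(
                            CYP2D6 = c("IM/PM" = 0),
                            CYP2C19 = c("IM/PM" = 0, "UM" = 0)
                          ),
                          asec_item_prob = c(SEROTONERGIC = 0.25,
                                             CHOLINERGIC = 0.30,
                                             HISTAMINERGIC = 0.25,
                                             OTHER = 0.20),
                          reason_probs = c(symptom_free = 0.40,
                                           ineffective = 0.25,
                                           side_effects = 0.35),
                          unknown_rate = 0.022,
                          assessed_prob = 1,
                          ad_freqs = default_ad_freqs(),
                          start_p1 = 0.6) {
  stopifnot(n_patients >= 1)
  for (g in names(allele_freqs)) {
    if (abs(sum(allele_freqs[[g]]) - 1) > 1e-9) {
      stop("allele frequencies for ", g, " must sum to 1", call. = FALSE)
    }
    if (any(allele_freqs[[g]] < 0)) {
      stop("allele frequencies must be non-negative", call. = FALSE)
    }
  }
  mixture <- trajectory_mixture[c("maintained", "switched", "discontinued")]
  if (anyNA(mixture) || abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0)) {
    stop("trajectory_mixture must be named probabilities summing to 1",
         call. = FALSE)
  }
  rp <- reason_probs[c("symptom_free", "ineffective", "side_effects")]
  if (anyNA(rp) || abs(sum(rp) - 1) > 1e-9 || any(rp < 0)) {
    stop("reason_probs must be named probabilities summing to 1", call. = FALSE)
  }
  if (unknown_rate < 0 || unknown_rate > 1) {
    stop("unknown_rate must lie in [0, 1]", call. = FALSE)
  }
  if (assessed_prob <= 0 || assessed_prob > 1) {
    stop("assessed_prob must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    allele_freqs = allele_freqs,
    trajectory_mixture = mixture,
    effect_log_or = effect_log_or,
    asec_item_prob = asec_item_prob,
    reason_probs = rp,
    unknown_rate = unknown_rate,
    assessed_prob = assessed_prob,
    ad_freqs = ad_freqs,
    start_p1 = start_p1
  ), class = "cohort_config")
}

#' Sample Hardy-Weinberg diplotypes
#'
#' Draws two alleles independently per gene per patient from the
#' configured frequencies (random mating), and flags CYP2D6 records as
#' quality-failed with probability `unknown_rate`. Deterministic given the
#' R random seed.
#'
#' @param config A [cohort_config()].
#' @return Genotype data.frame `patient_id`, `gene`, `allele1`, `allele2`,
#'   `quality_ok`.
#' @export
sample_diplotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  pid <- sprintf("P%05d", seq_len(n))
  out <- lapply(names(config$allele_freqs), function(g) {
    fr <- config$allele_freqs[[g]]
    a1 <- sample(names(fr), n, replace = TRUE, prob = fr)
    a2 <- sample(names(fr), n, replace = TRUE, prob = fr)
    q <- if (g == "CYP2D6") stats::runif(n) >= config$unknown_rate else rep(TRUE, n)
    data.frame(patient_id = pid, gene = g, allele1 = a1, allele2 = a2,
               quality_ok = q, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$patient_id, res$gene), , drop = FALSE]
}

# sample one element of v (safe for length-1 vectors)
sample_one <- function(v) v[sample.int(length(v), 1L)]

# per-patient trajectory probabilities after tilting the switch and
# discontinue odds (relative to maintained) by the group's log-OR
tilt_mixture <- function(mixture, log_or) {
  odds_s <- mixture[["switched"]] / mixture[["maintained"]] * exp(log_or)
  odds_d <- mixture[["discontinued"]] / mixture[["maintained"]] * exp(log_or)
  total <- 1 + odds_s + odds_d
  c(maintained = 1 / total, switched = odds_s / total, discontinued = odds_d / total)
}

#' Simulate medication timelines
#'
#' Gives each patient an index antidepressant (weights `ad_freqs`), a start
#' period (period 1 with probability `start_p1`, otherwise uniform over
#' 2-10) and a realized trajectory drawn from the configured mixture.
#' Patients whose index drug is a substrate of an enzyme for which their
#' collapsed metabolizer group carries a non-zero `effect_log_or` have
#' their switch and discontinue odds tilted by that amount (summed over
#' qualifying enzymes). Realization: maintained patients keep the index
#' drug through period 11; switchers move to a different drug at a uniform
#' later period (with a drug-free gap before the new drug in 30% of
#' cases); discontinuers (start restricted to periods 1-4) stop at a
#' uniform period within 1-4 and stay drug-free. Participation is drawn
#' per period with probability `assessed_prob`.
#'
#' @param config A [cohort_config()].
#' @param phenotypes Output of [assign_phenotypes()] for the cohort (used
#'   only to apply `effect_log_or`).
#' @param substrates Substrate table.
#' @return List with data.frames `medications` (`patient_id`, `period`,
#'   `atc`), `participation` (`patient_id`, `period`, `assessed`) and the
#'   per-patient `truth` (`patient_id`, `index_atc`, `start_period`,
#'   `true_label`).
#' @export
simulate_timelines <- function(config, phenotypes,
                               substrates = substrate_table()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  pid <- sprintf("P%05d", seq_len(n))
  adf <- config$ad_freqs
  index_atc <- sample(adf$atc, n, replace = TRUE, prob = adf$weight / sum(adf$weight))

  # per-patient log-OR tilt from the phenotype of each substrate enzyme
  lor <- rep(0, n)
  ph_status <- stats::setNames(phenotypes$status,
                               paste(phenotypes$patient_id, phenotypes$gene))
  cls <- substrate_class(index_atc, substrates)
  for (g in names(config$effect_log_or)) {
    eff <- config$effect_log_or[[g]]
    if (all(eff == 0)) next
    in_sub <- if (g == "CYP2D6") cls %in% c("CYP2D6_ONLY", "BOTH") else
      cls %in% c("CYP2C19_ONLY", "BOTH")
    st <- ph_status[paste(pid, g)]
    grp <- collapse_groups(st, g)
    add <- ifelse(in_sub & !is.na(grp) & grp %in% names(eff),
                  eff[ifelse(is.na(grp), names(eff)[1], grp)], 0)
    lor <- lor + ifelse(is.na(add), 0, add)
  }

  # draw labels under tilted per-patient mixtures
  label <- character(n)
  u <- stats::runif(n)
  base <- config$trajectory_mixture
  for (l in unique(lor)) {
    idx <- which(lor == l)
    p <- if (l == 0) base[c("maintained", "switched", "discontinued")] else
      tilt_mixture(base, l)
    cp <- cumsum(p)
    label[idx] <- c("maintained", "switched", "discontinued")[
      findInterval(u[idx], cp, left.open = TRUE) + 1L]
  }

  # start periods: period 1 w.p. start_p1, else uniform over 2..10;
  # discontinuers need a start <= 4 (same relative weights over 1..4)
  w_all <- c(config$start_p1, rep((1 - config$start_p1) / 9, 9))
  start <- integer(n)
  disc <- label == "discontinued"
  if (any(!disc)) {
    start[!disc] <- sample(1:10, sum(!disc), replace = TRUE, prob = w_all)
  }
  if (any(disc)) {
    start[disc] <- sample(1:4, sum(disc), replace = TRUE, prob = w_all[1:4])
  }

  # realize period ranges for index drug and (for switchers) the new drug
  end1 <- integer(n); new_atc <- rep(NA_character_, n)
  new_start <- integer(n)
  for (i in seq_len(n)) {
    if (label[i] == "maintained") {
      end1[i] <- 11L
    } else if (label[i] == "discontinued") {
      end1[i] <- sample_one(start[i]:4)
    } else {
      sw <- sample_one((start[i] + 1):11)
      gap <- stats::runif(1) < 0.3 && sw - start[i] >= 2
      end1[i] <- if (gap) sample_one(start[i]:(sw - 2)) else sw - 1L
      new_start[i] <- sw
      repeat {
        cand <- sample(adf$atc, 1, prob = adf$weight / sum(adf$weight))
        if (cand != index_atc[i]) break
      }
      new_atc[i] <- cand
    }
  }

  len1 <- end1 - start + 1L
  med_pid <- rep(pid, len1)
  med_per <- unlist(lapply(seq_len(n), function(i) start[i]:end1[i]))
  med_atc <- rep(index_atc, len1)
  sw_idx <- which(!is.na(new_atc))
  if (length(sw_idx) > 0) {
    len2 <- 12L - new_start[sw_idx]
    med_pid <- c(med_pid, rep(pid[sw_idx], len2))
    med_per <- c(med_per, unlist(lapply(sw_idx, function(i) new_start[i]:11)))
    med_atc <- c(med_atc, rep(new_atc[sw_idx], len2))
  }
  medications <- data.frame(patient_id = med_pid, period = as.integer(med_per),
                            atc = med_atc, stringsAsFactors = FALSE)

  if (config$assessed_prob >= 1) {
    participation <- data.frame(
      patient_id = rep(pid, each = 11), period = rep(1:11, n),
      assessed = TRUE, stringsAsFactors = FALSE
    )
  } else {
    assessed <- stats::runif(11 * n) < config$assessed_prob
    participation <- data.frame(
      patient_id = rep(pid, each = 11), period = rep(1:11, n),
      assessed = assessed, stringsAsFactors = FALSE
    )
    key <- paste(medications$patient_id, medications$period)
    akey <- paste(participation$patient_id, participation$period)
    medications <- medications[key %in% akey[participation$assessed], , drop = FALSE]
  }

  list(
    medications = medications,
    participation = participation,
    truth = data.frame(patient_id = pid, index_atc = index_atc,
                       start_period = start, true_label = label,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate side-effect checklist responses
#'
#' For every drug a patient uses at the interval periods 3, 5, 7 and 9,
#' draws the 12 binary items independently with the configured
#' per-category report probabilities (dizziness uses the `OTHER`
#' probability).
#'
#' @param config A [cohort_config()].
#' @param medications Long-format medication records.
#' @return Data.frame `patient_id`, `period`, `atc`, `item_01`..`item_12`
#'   with 1 = reported.
#' @export
simulate_asec <- function(config, medications) {
  stopifnot(inherits(config, "cohort_config"))
  sel <- medications[medications$period %in% .asec_periods, , drop = FALSE]
  n <- nrow(sel)
  cats <- asec_categories()
  p_item <- numeric(12)
  p_item[cats$SEROTONERGIC] <- config$asec_item_prob[["SEROTONERGIC"]]
  p_item[cats$CHOLINERGIC] <- config$asec_item_prob[["CHOLINERGIC"]]
  p_item[cats$HISTAMINERGIC] <- config$asec_item_prob[["HISTAMINERGIC"]]
  p_item[12] <- config$asec_item_prob[["OTHER"]]
  items <- matrix(stats::rbinom(n * 12, 1, rep(p_item, each = n)), nrow = n)
  colnames(items) <- sprintf("item_%02d", 1:12)
  cbind(
    data.frame(patient_id = sel$patient_id, period = sel$period,
               atc = sel$atc, stringsAsFactors = FALSE),
    as.data.frame(items)
  )
}

#' Simulate discontinuation reasons
#'
#' Scans the transitions 5 to 6, 7 to 8 and 9 to 10; whenever a patient's
#' drug set empties or moves to a disjoint set, a reason is drawn from the
#' configured multinomial and recorded against the earlier (interval)
#' period and the drug(s) used there.
#'
#' @param config A [cohort_config()].
#' @param medications,participation Long-format cohort records.
#' @return Data.frame `patient_id`, `period`, `atc`, `reason`.
#' @export
simulate_reasons <- function(config, medications, participation = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  tls <- build_timelines(medications, participation)
  rows <- list()
  for (pidname in names(tls)) {
    tl <- tls[[pidname]]
    for (tr in list(c(5L, 6L), c(7L, 8L), c(9L, 10L))) {
      i1 <- match(tr[1], tl$periods); i2 <- match(tr[2], tl$periods)
      if (is.na(i1) || is.na(i2)) next
      s1 <- tl$meds[[i1]]; s2 <- tl$meds[[i2]]
      if (length(s1) == 0) next
      if (length(s2) == 0 || is_switch_pair(s1, s2)) {
        reason <- sample(names(config$reason_probs), 1,
                         prob = config$reason_probs)
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pidname, period = tr[1], atc = s1, reason = reason,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), period = integer(0),
                      atc = character(0), reason = character(0)))
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator — diplotypes, phenotypes (DPWG, paper-compat
#' collapsing, used only to apply effect sizes), timelines, side-effect
#' responses and discontinuation reasons — under one seed. With `out_dir`
#' set, writes the five input CSVs (`genotypes.csv`, `medications.csv`,
#' `participation.csv`, `asec.csv`, `reasons.csv`) plus a
#' `provenance.json` recording the configuration and seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; same seed, same cohort.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with all five data.frames plus `truth`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  genotypes <- sample_diplotypes(config)
  phenotypes <- assign_phenotypes(genotypes)
  tl <- simulate_timelines(config, phenotypes)
  asec <- simulate_asec(config, tl$medications)
  reasons <- simulate_reasons(config, tl$medications, tl$participation)
  out <- list(
    genotypes = genotypes,
    medications = tl$medications,
    participation = tl$participation,
    asec = asec,
    reasons = reasons,
    truth = tl$truth
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in c("genotypes", "medications", "participation", "asec", "reasons")) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    prov <- list(
      seed = as.integer(seed),
      n_patients = config$n_patients,
      trajectory_mixture = as.list(config$trajectory_mixture),
      effect_log_or = config$effect_log_or,
      reason_probs = as.list(config$reason_probs),
      unknown_rate = config$unknown_rate,
      assessed_prob = config$assessed_prob,
      allele_freqs = lapply(config$allele_freqs, as.list)
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
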