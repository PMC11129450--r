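#' Collapse metabolizer phenotypes into analysis groups
#'
#' The association analyses contrast NM (reference) against collapsed
#' groups: IM/PM for CYP2D6, and IM/PM plus UM for CYP2C19. Patients with
#' an UNKNOWN status are excluded (`NA`). A UM status for CYP2D6 is
#' unreachable under the gene-dose translation and raises an error.
#'
#' @param status Character vector of phenotype statuses.
#' @param enzyme `"CYP2D6"` or `"CYP2C19"`.
#' @return Character vector of group labels (`"NM"`, `"IM/PM"`, `"UM"`)
#'   with `NA` for excluded patients.
#' @export
collapse_groups <- function(status, enzyme = c("CYP2D6", "CYP2C19")) {
  enzyme <- match.arg(enzyme)
  vapply(status, function(s) {
    if (is.na(s) || s == "UNKNOWN") return(NA_character_)
    if (enzyme == "CYP2D6") {
      switch(s, PM = , IM = "IM/PM", NM = "NM",
             stop("status ", s, " is not reachable for CYP2D6", call. = FALSE))
    } else {
      switch(s, PM = , IM = "IM/PM", NM = "NM", UM = "UM",
             stop("unrecognized status ", s, call. = FALSE))
    }
  }, character(1), USE.NAMES = FALSE)
}

# counts of (group x label) for one enzyme subsample
subsample_counts <- function(trajectory, phenotypes, enzyme) {
  member_col <- if (enzyme == "CYP2D6") "in_cyp2d6" else "in_cyp2c19"
  sel <- trajectory[trajectory$eligible & trajectory[[member_col]] &
                    trajectory$label %in% c("MAINTAINED", "SWITCHED", "DISCONTINUED"),
                    , drop = FALSE]
  ph <- phenotypes[phenotypes$gene == enzyme, , drop = FALSE]
  status <- ph$status[match(sel$patient_id, ph$patient_id)]
  group <- collapse_groups(status, enzyme)
  keep <- !is.na(group)
  table(
    group = factor(group[keep],
                   levels = if (enzyme == "CYP2D6") c("NM", "IM/PM")
                            else c("NM", "UM", "IM/PM")),
    label = factor(sel$label[keep],
                   levels = c("MAINTAINED", "DISCONTINUED", "SWITCHED"))
  )
}

#' Metabolizer-status association table for one enzyme
#'
#' Builds the group-by-outcome contingency counts for an enzyme subsample
#' and computes crude odds ratios with Wald intervals for discontinued
#' versus maintained and switched versus maintained, each collapsed group
#' against the NM reference.
#'
#' @param trajectory Output of [classify_cohort()].
#' @param phenotypes Output of [assign_phenotypes()].
#' @param enzyme `"CYP2D6"` or `"CYP2C19"`.
#' @param alpha Two-sided level for the intervals.
#' @return Data.frame with one row per group-outcome contrast: `enzyme`,
#'   `group`, `outcome`, `n_maintained`, `n_event`, `pct_maintained`,
#'   `pct_event`, `odds_ratio`, `ci_low`, `ci_high` (`NA` odds ratio for
#'   the reference row and for empty groups).
#' @export
association_table <- function(trajectory, phenotypes,
                              enzyme = c("CYP2D6", "CYP2C19"), alpha = 0.05) {
  enzyme <- match.arg(enzyme)
  cnt <- subsample_counts(trajectory, phenotypes, enzyme)
  groups <- rownames(cnt)
  totals <- rowSums(cnt)
  rows <- list()
  for (outcome in c("DISCONTINUED", "SWITCHED")) {
    for (g in groups) {
      a <- cnt[g, outcome]; b <- cnt[g, "MAINTAINED"]
      c_ <- cnt["NM", outcome]; d <- cnt["NM", "MAINTAINED"]
      est <- if (g == "NM") {
        list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else if (min(a, b, c_, d) == 0) {
        warning("zero cell for ", enzyme, " ", g, " ", outcome,
                "; odds ratio skipped", call. = FALSE)
        list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else {
        odds_ratio_wald(a, b, c_, d, alpha = alpha)
      }
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = enzyme, group = g, outcome = outcome,
        n_group = as.integer(totals[g]),
        n_maintained = as.integer(b), n_event = as.integer(a),
        pct_maintained = round(100 * b / totals[g], 1),
        pct_event = round(100 * a / totals[g], 1),
        odds_ratio = est$odds_ratio, ci_low = est$ci_low,
        ci_high = est$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-hoc power table from realized group sizes
#'
#' For each non-reference group and outcome, computes the arcsine
#' two-proportion power ([power_two_proportions()]) of the realized
#' comparison: event share among event-or-maintained patients in the NM
#' group versus the contrast group.
#'
#' @inheritParams association_table
#' @return Data.frame `enzyme`, `group`, `outcome`, `p1`, `n1`, `p2`,
#'   `n2`, `h`, `power`.
#' @export
power_table <- function(trajectory, phenotypes,
                        enzyme = c("CYP2D6", "CYP2C19"), alpha = 0.05) {
  enzyme <- match.arg(enzyme)
  cnt <- subsample_counts(trajectory, phenotypes, enzyme)
  rows <- list()
  for (outcome in c("DISCONTINUED", "SWITCHED")) {
    for (g in setdiff(rownames(cnt), "NM")) {
      n1 <- cnt["NM", outcome] + cnt["NM", "MAINTAINED"]
      n2 <- cnt[g, outcome] + cnt[g, "MAINTAINED"]
      if (n1 == 0 || n2 == 0) next
      p1 <- cnt["NM", outcome] / n1
      p2 <- cnt[g, outcome] / n2
      if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) next
      pw <- power_two_proportions(p1, p2, n1, n2, alpha = alpha)
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = enzyme, group = g, outcome = outcome,
        p1 = p1, n1 = as.integer(n1), p2 = p2, n2 = as.integer(n2),
        h = pw$h, power = pw$power, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(enzyme = character(0), group = character(0),
                      outcome = character(0), p1 = numeric(0),
                      n1 = integer(0), p2 = numeric(0), n2 = integer(0),
                      h = numeric(0), power = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Side-effect comparison table
#'
#' Per enzyme and side-effect category, compares the per-patient overall
#' mean number of reported side effects between NM and IM/PM patients with
#' the tie-corrected Mann-Whitney U test.
#'
#' @param asec Side-effect responses (see [patient_overall_mean()]).
#' @param trajectory Output of [classify_cohort()] (defines the analysis
#'   cohort).
#' @param phenotypes Output of [assign_phenotypes()].
#' @param substrates Substrate table.
#' @param coding ASEC coding convention.
#' @return Data.frame `enzyme`, `category`, `n_nm`, `n_impm`, `median_nm`,
#'   `median_impm`, `U`, `z`, `p_value`.
#' @export
side_effect_table <- function(asec, trajectory, phenotypes,
                              substrates = substrate_table(),
                              coding = "one_reported") {
  rows <- list()
  cohort_ids <- trajectory$patient_id[trajectory$eligible]
  for (enzyme in c("CYP2D6", "CYP2C19")) {
    ph <- phenotypes[phenotypes$gene == enzyme, , drop = FALSE]
    group <- collapse_groups(ph$status, enzyme)
    nm_ids <- intersect(ph$patient_id[!is.na(group) & group == "NM"], cohort_ids)
    impm_ids <- intersect(ph$patient_id[!is.na(group) & group == "IM/PM"], cohort_ids)
    for (category in names(asec_categories())) {
      om <- patient_overall_mean(asec, enzyme, category, substrates, coding)
      x <- om$mean_count[om$patient_id %in% nm_ids]
      y <- om$mean_count[om$patient_id %in% impm_ids]
      if (length(x) == 0 || length(y) == 0) next
      mw <- mann_whitney_u(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = enzyme, category = category,
        n_nm = length(x), n_impm = length(y),
        median_nm = stats::median(x), median_impm = stats::median(y),
        U = mw$U, z = mw$z, p_value = mw$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(enzyme = character(0), category = character(0),
                      n_nm = integer(0), n_impm = integer(0),
                      median_nm = numeric(0), median_impm = numeric(0),
                      U = numeric(0), z = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file may set `input_dir`, `output_dir`, `guideline`,
#' `collapse`, `alpha` and `asec_coding`; unset keys fall back to the
#' [run_pipeline()] defaults. Paths are resolved relative to the YAML
#' file's directory.
#'
#' @param path Path to a YAML run configuration.
#' @return The [run_pipeline()] result list.
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input_dir)) stop("run config must set input_dir", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  run_pipeline(
    input_dir = resolve(cfg$input_dir),
    output_dir = resolve(cfg$output_dir),
    guideline = if (is.null(cfg$guideline)) "DPWG" else cfg$guideline,
    collapse = if (is.null(cfg$collapse)) "paper_compat" else cfg$collapse,
    alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
    asec_coding = if (is.null(cfg$asec_coding)) "one_reported" else cfg$asec_coding
  )
}

# read one input CSV, checking required columns with row-level diagnostics
read_input_csv <- function(path, required, name) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(name, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Run the full analysis pipeline
#'
#' Reads the five cohort CSVs from `input_dir` (`genotypes.csv`,
#' `medications.csv`, `participation.csv`, `asec.csv`, `reasons.csv` —
#' the last three optional), assigns phenotypes, classifies trajectories,
#' builds the enzyme subsamples and computes the association, power,
#' side-effect and discontinuation-reason tables. A run log records the
#' configuration and the patient counts at every selection step
#' (kept + excluded = input at each step).
#'
#' @param input_dir Directory with the input CSVs.
#' @param output_dir Optional directory for the report CSVs and run log.
#' @param guideline CYP2C19 convention, `"DPWG"` or `"CPIC"`.
#' @param collapse Unidentifiable-allele handling.
#' @param alpha Two-sided level for intervals and power.
#' @param asec_coding ASEC coding convention.
#' @param substrates Substrate table.
#' @param nonsubstrate_index `"keep"` (default) retains patients whose index
#'   drug is a substrate of neither enzyme in the cohort (they belong to no
#'   subsample); `"exclude"` drops them from the eligible cohort.
#' @return A list with `phenotypes`, `phenotype_counts`, `trajectory`,
#'   `association`, `power`, `side_effects`, `reasons`, `flowchart`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(input_dir, output_dir = NULL,
                         guideline = c("DPWG", "CPIC"),
                         collapse = c("paper_compat", "strict"),
                         alpha = 0.05, asec_coding = "one_reported",
                         substrates = substrate_table(),
                         nonsubstrate_index = c("keep", "exclude")) {
  guideline <- match.arg(guideline)
  collapse <- match.arg(collapse)
  nonsubstrate_index <- match.arg(nonsubstrate_index)
  log <- c(sprintf("guideline=%s collapse=%s alpha=%g asec_coding=%s",
                   guideline, collapse, alpha, asec_coding))

  genotypes <- read_input_csv(file.path(input_dir, "genotypes.csv"),
                              c("patient_id", "gene", "allele1", "allele2",
                                "quality_ok"), "genotypes")
  medications <- read_input_csv(file.path(input_dir, "medications.csv"),
                                c("patient_id", "period", "atc"), "medications")
  part_path <- file.path(input_dir, "participation.csv")
  participation <- if (file.exists(part_path)) {
    read_input_csv(part_path, c("patient_id", "period", "assessed"),
                   "participation")
  } else NULL
  asec_path <- file.path(input_dir, "asec.csv")
  asec <- if (file.exists(asec_path)) {
    read_input_csv(asec_path, c("patient_id", "period", "atc",
                                sprintf("item_%02d", 1:12)), "asec")
  } else NULL
  reasons_path <- file.path(input_dir, "reasons.csv")
  reasons <- if (file.exists(reasons_path)) {
    read_input_csv(reasons_path, c("patient_id", "period", "atc", "reason"),
                   "reasons")
  } else NULL

  phenotypes <- assign_phenotypes(genotypes, guideline = guideline,
                                  collapse = collapse)
  ph_counts <- phenotype_counts(phenotypes)

  trajectory <- classify_cohort(medications, participation, substrates)
  if (nonsubstrate_index == "exclude") {
    drop <- trajectory$eligible & !trajectory$in_cyp2d6 & !trajectory$in_cyp2c19
    trajectory$eligible[drop] <- FALSE
    trajectory$label[drop] <- NA_character_
    log <- c(log, sprintf("non-substrate index drug: %d patient(s) excluded",
                          sum(drop)))
  }
  n_total <- nrow(trajectory)
  n_elig <- sum(trajectory$eligible)
  n_nc <- sum(trajectory$label == "NOT_CLASSIFIABLE", na.rm = TRUE)
  n_class <- sum(trajectory$label %in% c("MAINTAINED", "SWITCHED", "DISCONTINUED"),
                 na.rm = TRUE)
  log <- c(log,
    sprintf("patients in input: %d", n_total),
    sprintf("eligible single-AD starters: %d (excluded: %d)",
            n_elig, n_total - n_elig),
    sprintf("classifiable: %d (not classifiable: %d)", n_class, n_nc),
    sprintf("CYP2D6 subsample: %d; CYP2C19 subsample: %d",
            sum(trajectory$eligible & trajectory$in_cyp2d6 &
                trajectory$label != "NOT_CLASSIFIABLE"),
            sum(trajectory$eligible & trajectory$in_cyp2c19 &
                trajectory$label != "NOT_CLASSIFIABLE")))
  flowchart <- data.frame(
    step = c("input", "eligible", "classifiable"),
    kept = c(n_total, n_elig, n_class),
    excluded = c(0L, n_total - n_elig, n_elig - n_class),
    stringsAsFactors = FALSE
  )

  assoc <- list(); pw <- list()
  for (enz in c("CYP2D6", "CYP2C19")) {
    cnt <- subsample_counts(trajectory, phenotypes, enz)
    if (sum(cnt) == 0) {
      warning("empty ", enz, " subsample; association skipped", call. = FALSE)
      log <- c(log, sprintf("%s subsample empty; association skipped", enz))
      next
    }
    assoc[[enz]] <- association_table(trajectory, phenotypes, enz, alpha)
    pw[[enz]] <- power_table(trajectory, phenotypes, enz, alpha)
  }
  association <- if (length(assoc)) do.call(rbind, c(assoc, make.row.names = FALSE)) else NULL
  power <- if (length(pw)) do.call(rbind, c(pw, make.row.names = FALSE)) else NULL

  side_effects <- if (!is.null(asec) && nrow(asec) > 0) {
    side_effect_table(asec, trajectory, phenotypes, substrates, asec_coding)
  } else NULL
  reasons_tab <- if (!is.null(reasons)) {
    reasons_table(medications, participation, reasons, phenotypes, substrates)
  } else NULL

  result <- list(
    phenotypes = phenotypes,
    phenotype_counts = ph_counts,
    trajectory = trajectory,
    association = association,
    power = power,
    side_effects = side_effects,
    reasons = reasons_tab,
    flowchart = flowchart,
    log = log
  )

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(trajectory, file.path(output_dir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(ph_counts, file.path(output_dir, "phenotype_counts.csv"),
                     row.names = FALSE)
    if (!is.null(association)) {
      out_assoc <- association
      out_assoc$odds_ratio <- round(out_assoc$odds_ratio, 2)
      out_assoc$ci_low <- round(out_assoc$ci_low, 2)
      out_assoc$ci_high <- round(out_assoc$ci_high, 2)
      utils::write.csv(out_assoc, file.path(output_dir, "association_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(power)) {
      out_pw <- power
      out_pw$power <- round(out_pw$power, 2)
      utils::write.csv(out_pw, file.path(output_dir, "power_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(side_effects)) {
      utils::write.csv(side_effects, file.path(output_dir, "side_effect_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(reasons_tab)) {
      utils::write.csv(reasons_tab, file.path(output_dir, "reasons_table.csv"),
                       row.names = FALSE)
    }
    writeLines(log, file.path(output_dir, "run_log.txt"))
  }
  result
}
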