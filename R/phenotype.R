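#' Total CYP2D6 gene dose of a diplotype
#'
#' The gene dose (activity score) is the sum of the two alleles' dose
#' contributions: 1 for a fully functional, 0.5 for a reduced-function and 0
#' for an inactive allele. Only CYP2D6 phenotypes are binned by dose;
#' CYP2C19 uses combination rules (see [cyp2c19_status()]).
#'
#' @param allele1,allele2 Star-allele names such as `"*1"`, `"*4"`.
#' @param table An `allele_table`; defaults to the built-in CYP2D6 table.
#' @return The total dose, one of 0, 0.5, 1, 1.5, 2.
#' @examples
#' gene_dose("*4", "*41") # 0.5
#' @export
gene_dose <- function(allele1, allele2, table = default_allele_table("CYP2D6")) {
  doses <- vapply(c(allele1, allele2), function(a) {
    fn <- lookup_fn(a, "CYP2D6", table)
    if (is.na(fn)) stop("allele ", a, " not in CYP2D6 table", call. = FALSE)
    d <- allele_dose(fn)
    if (is.na(d)) stop("allele ", a, " (", fn, ") carries no gene dose", call. = FALSE)
    d
  }, numeric(1))
  sum(doses)
}

#' CYP2D6 metabolizer status from a gene dose
#'
#' Poor metabolizer (PM) at dose 0, intermediate (IM) at 0.5–1, normal (NM)
#' at 1.5–2.5. Doses outside these closed bins cannot arise from a valid
#' allele table and raise an error rather than being binned silently.
#'
#' @param dose Total gene dose as returned by [gene_dose()].
#' @return `"PM"`, `"IM"` or `"NM"`.
#' @export
cyp2d6_status <- function(dose) {
  vapply(dose, function(d) {
    if (isTRUE(all.equal(d, 0))) return("PM")
    if (d >= 0.5 && d <= 1.0) return("IM")
    if (d >= 1.5 && d <= 2.5) return("NM")
    stop("invalid CYP2D6 gene dose: ", d, call. = FALSE)
  }, character(1))
}

#' CYP2C19 metabolizer status from a diplotype
#'
#' Combination rules on the two alleles' functional classes. Under the DPWG
#' convention: two inactive (or two reduced-function) alleles give PM;
#' exactly one inactive or reduced-function allele gives IM; full/full and
#' full/increased give NM; increased/increased gives UM. The CPIC convention
#' is identical except that full/increased (i.e. *1/*17) is UM.
#'
#' @param allele1,allele2 Star-allele names.
#' @param table An `allele_table`; defaults to the built-in CYP2C19 table.
#' @param guideline `"DPWG"` (default) or `"CPIC"`.
#' @param quality_ok If `FALSE` the imputation posterior was insufficient and
#'   the status is `"UNKNOWN"`.
#' @return One of `"PM"`, `"IM"`, `"NM"`, `"UM"`, `"UNKNOWN"`.
#' @examples
#' cyp2c19_status("*1", "*17")                      # NM under DPWG
#' cyp2c19_status("*1", "*17", guideline = "CPIC")  # UM under CPIC
#' @export
cyp2c19_status <- function(allele1, allele2,
                           table = default_allele_table("CYP2C19"),
                           guideline = c("DPWG", "CPIC"),
                           quality_ok = TRUE) {
  guideline <- match.arg(guideline)
  if (!isTRUE(quality_ok)) return("UNKNOWN")
  fns <- vapply(c(allele1, allele2), function(a) {
    fn <- lookup_fn(a, "CYP2C19", table)
    if (is.na(fn)) stop("allele ", a, " not in CYP2C19 table", call. = FALSE)
    fn
  }, character(1))
  n_loss <- sum(fns %in% c("inactive", "reduced"))
  n_incr <- sum(fns == "increased")
  if (n_loss == 2) return("PM")
  if (n_loss == 1) return("IM")
  if (n_incr == 2) return("UM")
  # remaining: full/full or full/increased
  if (n_incr == 1 && guideline == "CPIC") return("UM")
  "NM"
}

#' Translate one diplotype to a metabolizer status
#'
#' Dispatches on the gene: CYP2D6 via gene dose and [cyp2d6_status()],
#' CYP2C19 via [cyp2c19_status()]. Alleles that could not be identified
#' during genotyping (e.g. the *5 deletion or duplications, which array
#' imputation cannot call) are handled by `collapse`: in `"paper_compat"`
#' mode (default) they are assigned a *1 allele before translation — which
#' inflates the apparent NM share — while `"strict"` mode returns
#' `"UNKNOWN"`.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @param allele1,allele2 Star-allele names; unordered.
#' @param table Combined `allele_table` covering the gene.
#' @param guideline CYP2C19 convention, `"DPWG"` or `"CPIC"`.
#' @param quality_ok Imputation quality flag; `FALSE` gives `"UNKNOWN"`.
#' @param collapse `"paper_compat"` or `"strict"` handling of alleles absent
#'   from the table.
#' @return A metabolizer status string.
#' @export
metabolizer_status <- function(gene, allele1, allele2,
                               table = load_allele_table(),
                               guideline = c("DPWG", "CPIC"),
                               quality_ok = TRUE,
                               collapse = c("paper_compat", "strict")) {
  guideline <- match.arg(guideline)
  collapse <- match.arg(collapse)
  if (!isTRUE(quality_ok)) return("UNKNOWN")
  known <- table$allele[table$gene == gene]
  al <- c(allele1, allele2)
  missing_al <- !(al %in% known)
  if (any(missing_al)) {
    if (collapse == "strict") return("UNKNOWN")
    al[missing_al] <- "*1"
  }
  if (gene == "CYP2D6") {
    cyp2d6_status(gene_dose(al[1], al[2], table = table))
  } else if (gene == "CYP2C19") {
    cyp2c19_status(al[1], al[2], table = table, guideline = guideline)
  } else {
    stop("unsupported gene: ", gene, call. = FALSE)
  }
}

#' Assign metabolizer phenotypes to a cohort
#'
#' Takes genotype records (one diplotype per patient per gene) and returns
#' one status per patient per gene. Records flagged with insufficient
#' imputation quality receive `"UNKNOWN"`.
#'
#' @param genotypes A data.frame with columns `patient_id`, `gene`,
#'   `allele1`, `allele2` and `quality_ok` (logical).
#' @param table Allele function table.
#' @param guideline CYP2C19 convention.
#' @param collapse Unidentifiable-allele handling (see
#'   [metabolizer_status()]).
#' @return A data.frame `patient_id`, `gene`, `status` in wide-friendly long
#'   form, one row per patient-gene.
#' @export
assign_phenotypes <- function(genotypes,
                              table = load_allele_table(),
                              guideline = c("DPWG", "CPIC"),
                              collapse = c("paper_compat", "strict")) {
  guideline <- match.arg(guideline)
  collapse <- match.arg(collapse)
  req <- c("patient_id", "gene", "allele1", "allele2", "quality_ok")
  if (!all(req %in% names(genotypes))) {
    stop("genotypes must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  key <- paste(genotypes$patient_id, genotypes$gene)
  if (anyDuplicated(key)) {
    stop("duplicate patient-gene genotype record(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  }
  # translate each distinct (gene, unordered diplotype, quality) once
  a1 <- as.character(genotypes$allele1)
  a2 <- as.character(genotypes$allele2)
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  q <- as.logical(genotypes$quality_ok)
  dip_key <- paste(genotypes$gene, lo, hi, q)
  uniq <- !duplicated(dip_key)
  u_status <- vapply(which(uniq), function(i) {
    metabolizer_status(genotypes$gene[i], lo[i], hi[i], table = table,
                       guideline = guideline, quality_ok = isTRUE(q[i]),
                       collapse = collapse)
  }, character(1))
  status <- u_status[match(dip_key, dip_key[uniq])]
  data.frame(
    patient_id = genotypes$patient_id,
    gene = genotypes$gene,
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Tabulate phenotype counts per gene
#'
#' @param phenotypes Output of [assign_phenotypes()].
#' @return A data.frame `gene`, `status`, `n`, `pct`.
#' @export
phenotype_counts <- function(phenotypes) {
  out <- do.call(rbind, lapply(split(phenotypes, phenotypes$gene), function(g) {
    tab <- table(factor(g$status, levels = c("PM", "IM", "NM", "UM", "UNKNOWN")))
    data.frame(
      gene = g$gene[1],
      status = names(tab),
      n = as.integer(tab),
      pct = round(100 * as.integer(tab) / nrow(g), 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
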