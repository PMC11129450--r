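# shorthand: build a timeline from a compact period -> drugs spec,
# e.g. tl(`2` = "A", `3` = c("A", "B")), assessed defaulting to 1:11
tl <- function(..., assessed = 1:11) {
  meds <- list(...)
  medication_timeline(meds, assessed = assessed)
}

# independent rule oracle for phenotype translation, written directly from
# the verbal definitions (no gene-dose arithmetic shared with the package)
oracle_cyp2d6 <- function(fn1, fn2) {
  dose_of <- c(full = 1, reduced = 0.5, inactive = 0)
  d <- dose_of[fn1] + dose_of[fn2]
  if (d == 0) "PM" else if (d <= 1) "IM" else "NM"
}

oracle_cyp2c19 <- function(fn1, fn2, guideline = "DPWG") {
  fns <- c(fn1, fn2)
  loss <- sum(fns %in% c("inactive", "reduced"))
  if (loss == 2) return("PM")
  if (loss == 1) return("IM")
  if (all(fns == "increased")) return("UM")
  if ("increased" %in% fns && guideline == "CPIC") return("UM")
  "NM"
}

toy_cohort_dir <- function() {
  system.file("extdata", "toy_cohort", package = "pgxtraj", mustWork = TRUE)
}
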