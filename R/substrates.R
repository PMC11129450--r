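#' Antidepressant CYP substrate table
#'
#' Loads the mapping from ATC code to CYP substrate class. Antidepressants
#' (ATC group N06A) are classified as metabolized by CYP2C19 only, CYP2D6
#' only, or both; any code absent from the table is treated as a substrate
#' of neither enzyme. The packaged default covers 21 antidepressants: 5
#' CYP2C19-only, 12 CYP2D6-only and 4 metabolized by both. The table is
#' shipped as data (CSV) so that users can extend it; the ATC code is the
#' key and the drug name is informational only.
#'
#' @param source Path to a CSV with columns `atc`, `name`,
#'   `substrate_class`; `NULL` loads the packaged default.
#' @return A data.frame `atc`, `name`, `substrate_class`.
#' @export
substrate_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "substrates.csv", package = "pgxtraj",
                          mustWork = TRUE)
  }
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  req <- c("atc", "name", "substrate_class")
  if (!all(req %in% names(tab))) {
    stop("substrate table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ok <- tab$substrate_class %in% c("CYP2C19_ONLY", "CYP2D6_ONLY", "BOTH", "NEITHER")
  if (!all(ok)) {
    stop("unrecognized substrate class: ",
         paste(unique(tab$substrate_class[!ok]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$atc)) {
    stop("duplicate ATC code(s) in substrate table", call. = FALSE)
  }
  tab
}

# 7-character ATC code, letter/digit layout as in the WHO scheme
check_atc <- function(atc) {
  bad <- !grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", atc)
  if (any(bad)) {
    stop("malformed ATC code(s): ", paste(unique(atc[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(atc)
}

#' CYP substrate class of a drug
#'
#' @param atc Character vector of 7-character ATC codes.
#' @param table Substrate table from [substrate_table()].
#' @return Character vector in `CYP2C19_ONLY`, `CYP2D6_ONLY`, `BOTH`,
#'   `NEITHER` (the last for any code absent from the table).
#' @examples
#' substrate_class("N06AB04") # citalopram: BOTH
#' @export
substrate_class <- function(atc, table = substrate_table()) {
  check_atc(atc)
  idx <- match(atc, table$atc)
  out <- table$substrate_class[idx]
  out[is.na(idx)] <- "NEITHER"
  out
}

#' @rdname substrate_class
#' @export
is_cyp2d6_substrate <- function(atc, table = substrate_table()) {
  substrate_class(atc, table) %in% c("CYP2D6_ONLY", "BOTH")
}

#' @rdname substrate_class
#' @export
is_cyp2c19_substrate <- function(atc, table = substrate_table()) {
  substrate_class(atc, table) %in% c("CYP2C19_ONLY", "BOTH")
}
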