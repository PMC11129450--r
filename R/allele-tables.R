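#' Allele function tables for CYP2D6 and CYP2C19
#'
#' Each star allele of a pharmacogene carries a functional class and, for
#' CYP2D6, a dose contribution used in the gene-dose (activity-score)
#' phenotype translation:
#'
#' * `full` — fully functional, dose 1
#' * `reduced` — reduced function, dose 0.5
#' * `inactive` — no function, dose 0
#' * `increased` — increased function; carries no dose and is used only by
#'   the CYP2C19 combination rules
#'
#' The built-in defaults cover the alleles typically callable from
#' genome-wide imputation in European-ancestry cohorts: CYP2D6 *1/*2 full,
#' *3/*4/*6 inactive, *10/*17/*41 reduced; CYP2C19 *1 full, *2/*3 inactive,
#' *17 increased.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @return A data.frame with columns `gene`, `allele`, `fn` (function label)
#'   and `dose` (`NA` for `increased`), of class `allele_table`.
#' @examples
#' default_allele_table("CYP2D6")
#' @export
default_allele_table <- function(gene = c("CYP2D6", "CYP2C19")) {
  gene <- match.arg(gene)
  df <- if (gene == "CYP2D6") {
    data.frame(
      gene = "CYP2D6",
      allele = c("*1", "*2", "*3", "*4", "*6", "*10", "*17", "*41"),
      fn = c("full", "full", "inactive", "inactive", "inactive",
             "reduced", "reduced", "reduced"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      gene = "CYP2C19",
      allele = c("*1", "*2", "*3", "*17"),
      fn = c("full", "inactive", "inactive", "increased"),
      stringsAsFactors = FALSE
    )
  }
  df$dose <- allele_dose(df$fn)
  class(df) <- c("allele_table", "data.frame")
  df
}

.allele_functions <- c("full", "reduced", "inactive", "increased")

# dose contribution of a functional class; increased carries none
allele_dose <- function(fn) {
  unname(c(full = 1, reduced = 0.5, inactive = 0, increased = NA_real_)[fn])
}

#' Load an allele function table
#'
#' Reads a per-gene map from star allele to functional class, either from the
#' built-in defaults or from a CSV with columns `gene`, `allele`, `function`
#' (or `fn`), with function labels in `full`, `reduced`, `inactive`,
#' `increased`.
#'
#' @param source `NULL` for the built-in defaults, or a path to a CSV file.
#' @param gene Restrict to one gene; `NULL` keeps all rows.
#' @return An `allele_table` data.frame (see [default_allele_table()]).
#' @export
load_allele_table <- function(source = NULL, gene = NULL) {
  if (is.null(source)) {
    tab <- rbind(default_allele_table("CYP2D6"), default_allele_table("CYP2C19"))
  } else {
    raw <- utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
    fn_col <- intersect(c("function", "fn"), names(raw))
    if (!all(c("gene", "allele") %in% names(raw)) || length(fn_col) == 0) {
      stop("allele table must have columns gene, allele, function", call. = FALSE)
    }
    tab <- data.frame(
      gene = as.character(raw$gene),
      allele = as.character(raw$allele),
      fn = tolower(as.character(raw[[fn_col[1]]])),
      stringsAsFactors = FALSE
    )
    bad <- setdiff(unique(tab$fn), .allele_functions)
    if (length(bad) > 0) {
      stop("unrecognized allele function label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    tab$dose <- allele_dose(tab$fn)
  }
  if (!is.null(gene)) tab <- tab[tab$gene == gene, , drop = FALSE]
  dup <- duplicated(tab[, c("gene", "allele")])
  if (any(dup)) {
    stop("duplicate allele entry: ",
         paste(unique(paste(tab$gene[dup], tab$allele[dup])), collapse = ", "),
         call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("allele_table", "data.frame")
  tab
}

# function label of one allele, or NA if absent from the table
lookup_fn <- function(allele, gene, table) {
  hit <- table$fn[table$gene == gene & table$allele == allele]
  if (length(hit) == 0) NA_character_ else hit[1]
}
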