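# Residue table and terminus chemistry.
#
# Each residue is an *internal* chain unit: nucleoside 3'-monophosphate
# minus one water (the repeat unit of a 5'-OH / 3'-phosphate chain). A
# molecule's neutral formula is sum(residues) + 5'-terminus delta +
# 3'-terminus delta, with deltas chosen so that e.g. "G" with 5'-OH and a
# linear 3'-phosphate is exactly GMP (C10H14N5O8P).

.pkg_env <- new.env(parent = emptyenv())

#' Residue definition table
#'
#' The packaged table covers the unmodified ribonucleotides (A, C, G, U)
#' and the modified residues encountered in tRNA-Phe profiling work
#' (\code{m5C}, \code{m7G}, \code{m1A}, \code{m22G}, dihydrouridine
#' \code{D}). Each modification maps to exactly one parent base, which is
#' used for dinucleotide classification. Users can extend the table with
#' [read_residue_table()] and pass the result to the parsing functions.
#'
#' @param path Optional path to a user TSV with columns
#'   \code{code}, \code{parent_base}, \code{formula}, \code{base_formula};
#'   rows are appended to (and override) the packaged table.
#' @return data.frame with columns \code{code}, \code{parent_base},
#'   \code{formula}, \code{base_formula}, \code{description},
#'   \code{monoisotopic_mass}, \code{average_mass}.
#' @export
residue_table <- function(path = NULL) {
  if (is.null(.pkg_env$residues)) {
    .pkg_env$residues <- read_residue_table(
      system.file("extdata", "residue_table.tsv", package = "rnasespec",
                  mustWork = TRUE))
  }
  tab <- .pkg_env$residues
  if (!is.null(path)) {
    extra <- read_residue_table(path)
    tab <- rbind(tab[!tab$code %in% extra$code, ], extra)
    rownames(tab) <- NULL
  }
  tab
}

#' Read a residue definition TSV
#'
#' Numeric masses are derived from the elemental formulas at load time, so
#' the formula column is the single source of truth.
#'
#' @param path TSV file with columns \code{code}, \code{parent_base},
#'   \code{formula}, \code{base_formula} (and optionally
#'   \code{description}).
#' @return data.frame as described in [residue_table()].
#' @export
read_residue_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "parent_base", "formula", "base_formula")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("residue table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !tab$parent_base %in% c("A", "C", "G", "U")
  if (any(bad)) {
    stop("residue(s) with invalid parent_base: ",
         paste(tab$code[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$code)) {
    stop("duplicated residue code(s) in ", path, call. = FALSE)
  }
  if (is.null(tab$description)) tab$description <- tab$code
  tab$monoisotopic_mass <- vapply(tab$formula, formula_mass, numeric(1),
                                  kind = "monoisotopic")
  tab$average_mass <- vapply(tab$formula, formula_mass, numeric(1),
                             kind = "average")
  tab
}

# Terminus deltas relative to the bare residue chain, as signed formulas.
.TERMINUS_DELTA <- list(
  `5prime` = list(
    hydroxyl        = "H",       # cap the 5'-O with H
    phosphate       = "H2O3P"    # 5'-monophosphate
  ),
  `3prime` = list(
    hydroxyl         = "HO-2P-1", # strip the residue's 3'-phosphate, cap with OH
    phosphate        = "HO",      # complete the linear 3'-phosphate
    cyclic_phosphate = "H-1"      # 2',3'-cyclic phosphate = linear - H2O
  )
)

#' Terminus chemistry mass delta
#'
#' Mass contribution of an end group relative to the bare residue chain
#' (see the package convention in [residue_table()]). A 2',3'-cyclic
#' phosphate is one water lighter than a linear 3'-phosphate and is only
#' valid at the 3' end.
#'
#' @param kind \code{"hydroxyl"}, \code{"phosphate"}, or
#'   \code{"cyclic_phosphate"}.
#' @param end \code{"5prime"} or \code{"3prime"}.
#' @param as \code{"formula"} (signed atom counts) or \code{"mass"}
#'   (monoisotopic Da).
#' @return Formula vector or mass.
#' @examples
#' terminus_delta("cyclic_phosphate", "3prime", "mass") -
#'   terminus_delta("phosphate", "3prime", "mass")  # -18.0106 (one water)
#' @export
terminus_delta <- function(kind, end = c("5prime", "3prime"),
                           as = c("formula", "mass")) {
  end <- match.arg(end)
  as <- match.arg(as)
  choices <- .TERMINUS_DELTA[[end]]
  if (!kind %in% names(choices)) {
    stop("invalid ", end, " terminus '", kind, "'; must be one of: ",
         paste(names(choices), collapse = ", "), call. = FALSE)
  }
  f <- parse_formula(choices[[kind]])
  if (as == "mass") formula_mass(f) else f
}
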