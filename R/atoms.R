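# Elemental formula arithmetic and atomic masses.
#
# Formulas are named integer vectors (element -> count); counts may be
# negative so terminus deltas (e.g. 3'-OH = "HO-2P-1" relative to the
# phosphate-bearing residue chain) are expressible. All numeric masses in
# the package derive from these tables -- one source of truth.

# IUPAC/CODATA monoisotopic and standard atomic weights (Da).
.ATOMIC_MASS <- list(
  monoisotopic = c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069),
  average      = c(H = 1.00794, C = 12.0107, N = 14.0067,
                   O = 15.9994, P = 30.973762, S = 32.065)
)

# Mass of a proton (Da); used for negative-mode m/z.
.PROTON_MASS <- 1.00727646688

#' Parse an elemental formula
#'
#' Parses strings such as \code{"C10H14N5O8P"} into a named integer vector of
#' atom counts. Signed counts are allowed (\code{"HO-2P-1"}), which is how
#' terminus mass deltas relative to the residue chain are stored.
#'
#' @param text Formula string. Element symbols (one uppercase letter plus
#'   optional lowercase letters) each followed by an optional signed integer
#'   count (default 1).
#' @return Named integer vector of atom counts.
#' @examples
#' parse_formula("C10H14N5O8P")
#' parse_formula("HO-2P-1")  # 3'-hydroxyl delta
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  rx <- gregexpr("([A-Z][a-z]*)(-?[0-9]+)?", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(rx))[[1]]
  if (sum(attr(rx, "match.length")) != nchar(text)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  elems <- sub("^([A-Z][a-z]*).*$", "\\1", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Z][a-z]*", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elems, names(.ATOMIC_MASS$monoisotopic))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  f <- tapply(counts, elems, sum)
  storage.mode(f) <- "integer"
  f[f != 0L]
}

#' Combine elemental formulas
#'
#' @param ... Named integer vectors as returned by [parse_formula()], or
#'   formula strings (parsed on the fly).
#' @return A single combined named integer vector.
#' @export
formula_sum <- function(...) {
  fs <- lapply(list(...), function(f) if (is.character(f)) parse_formula(f) else f)
  all_el <- unique(unlist(lapply(fs, names)))
  out <- stats::setNames(integer(length(all_el)), all_el)
  for (f in fs) out[names(f)] <- out[names(f)] + f
  out[out != 0L]
}

#' Scale an elemental formula
#' @param f Named integer vector or formula string.
#' @param k Integer multiplier (may be negative).
#' @return Scaled formula.
#' @export
formula_scale <- function(f, k) {
  if (is.character(f)) f <- parse_formula(f)
  out <- f * as.integer(k)
  out[out != 0L]
}

#' Mass of an elemental formula
#'
#' @param f Named integer vector or formula string.
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' formula_mass("H2O")            # 18.0106
#' formula_mass("C10H14N5O8P")    # GMP, 363.0580
#' @export
formula_mass <- function(f, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  if (is.character(f)) f <- parse_formula(f)
  if (!length(f)) return(0)
  sum(.ATOMIC_MASS[[kind]][names(f)] * f)
}

#' Format an elemental formula as a string
#' @param f Named integer vector.
#' @return Character formula in Hill-ish order (C, H, then alphabetical).
#' @export
format_formula <- function(f) {
  f <- f[f != 0L]
  ord <- c(intersect(c("C", "H"), names(f)),
           sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(ord, function(e) {
    paste0(e, if (f[[e]] != 1L) f[[e]] else "")
  }, character(1)), collapse = "")
}
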