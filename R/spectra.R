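# m/z computation, fragment ladders, and peak matching.
#
# Negative-mode ESI conventions throughout: an [M - zH]^z- ion at charge
# -z has m/z = (M - z * m_proton) / z.
#
# Fragment-series conventions (5' fragments keep the product's 5'
# terminus, 3' fragments its 3' terminus):
#   c_i : 5' fragment with a linear 3'-phosphate
#   a_i : 5' fragment with 3'-OH (c - HPO3)
#   b_i : a - H2O
#   a-B : a with loss of the 3'-terminal nucleobase of the fragment
#   y_j : 3' fragment with 5'-OH
#   w_j : y + HPO3 (5'-phosphate)
#   x_j : w - H2O
#   z_j : y - H2O
# Complementary pairs built from one cleavage obey
# mass(c_i) + mass(y_{n-i}) = M + H2O for every i.

#' m/z of a negative ion
#'
#' @param neutral_mass Neutral monoisotopic (or average) mass in Da.
#' @param charge Negative integer charge state (z <= -1).
#' @return m/z value(s); vectorized over both arguments.
#' @examples
#' mz(1000, -1)  # 998.9927
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge >= 0) || any(charge != round(charge))) {
    stop("charge must be a negative integer (negative-mode ESI)",
         call. = FALSE)
  }
  z <- abs(charge)
  (neutral_mass - z * .PROTON_MASS) / z
}

.SERIES_5P <- c("a", "a-B", "b", "c")
.SERIES_3P <- c("w", "x", "y", "z")

#' CID fragment ladder of an oligonucleotide product
#'
#' Returns the n-1 ions of each requested linear series (see the
#' conventions in the package source header). The defaults are the
#' dominant RNA collision-induced dissociation channels (c, y, w, a-B);
#' the remaining series (a, b, x, z) sit behind the same flag.
#'
#' @param product An \code{rna_sequence} of length >= 2 (length-1 input
#'   yields an empty ladder).
#' @param series Character subset of
#'   \code{c("c", "y", "w", "a-B", "a", "b", "x", "z")}.
#' @param kind Mass kind.
#' @param residues Residue table.
#' @return data.frame with columns \code{series}, \code{index},
#'   \code{neutral_mass}, \code{description} (residues covered), and
#'   \code{lost_base} (a-B only, NA otherwise).
#' @examples
#' uu <- parse_rna("UU", terminus3 = "cyclic_phosphate")
#' fragment_ladder(uu, series = "c")$neutral_mass  # 324.0359 (U + 3'-p)
#' @export
fragment_ladder <- function(product, series = c("c", "y", "w", "a-B"),
                            kind = c("monoisotopic", "average"),
                            residues = residue_table()) {
  kind <- match.arg(kind)
  stopifnot(inherits(product, "rna_sequence"))
  bad <- setdiff(series, c(.SERIES_5P, .SERIES_3P))
  if (length(bad)) {
    stop("unknown fragment series: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(product)
  empty <- data.frame(series = character(0), index = integer(0),
                      neutral_mass = numeric(0), description = character(0),
                      lost_base = character(0))
  if (n < 2L) return(empty)
  ridx <- match(product$codes, residues$code)
  rmass <- vapply(residues$formula[ridx], formula_mass, numeric(1),
                  kind = kind)
  bmass <- vapply(residues$base_formula[ridx], formula_mass, numeric(1),
                  kind = kind)
  am <- .ATOMIC_MASS[[kind]]
  h2o <- 2 * am[["H"]] + am[["O"]]
  hpo3 <- am[["H"]] + am[["P"]] + 3 * am[["O"]]
  d5 <- formula_mass(terminus_delta(product$terminus5, "5prime"), kind)
  d3 <- formula_mass(terminus_delta(product$terminus3, "3prime"), kind)
  pre <- cumsum(rmass)[-n] + d5         # 5' fragments, length 1..n-1
  suf <- cumsum(rev(rmass))[-n] + d3    # 3' fragments, length 1..n-1
  oh <- am[["H"]] + am[["O"]]
  idx5 <- seq_len(n - 1L)
  tok <- ifelse(nchar(product$codes) > 1L,
                paste0("[", product$codes, "]"), product$codes)
  desc5 <- vapply(idx5, function(i) paste0(tok[1:i], collapse = ""),
                  character(1))
  desc3 <- vapply(idx5, function(j) {
    paste0(tok[(n - j + 1L):n], collapse = "")
  }, character(1))
  out <- list()
  add <- function(s, mass, desc, lost = NA_character_) {
    out[[length(out) + 1L]] <<- data.frame(
      series = s, index = idx5, neutral_mass = mass,
      description = desc, lost_base = lost, stringsAsFactors = FALSE)
  }
  for (s in intersect(series, .SERIES_5P)) {
    switch(s,
      "c" = add("c", pre + oh, desc5),
      "a" = add("a", pre + oh - hpo3, desc5),
      "b" = add("b", pre + oh - hpo3 - h2o, desc5),
      "a-B" = add("a-B", pre + oh - hpo3 - bmass[idx5], desc5,
                  lost = product$codes[idx5]))
  }
  for (s in intersect(series, .SERIES_3P)) {
    switch(s,
      "y" = add("y", suf + am[["H"]], desc3),
      "w" = add("w", suf + am[["H"]] + hpo3, desc3),
      "x" = add("x", suf + am[["H"]] + hpo3 - h2o, desc3),
      "z" = add("z", suf + am[["H"]] - h2o, desc3))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match candidate products against a deconvoluted peak list
#'
#' Each peak is assigned to at most one candidate per charge: the match
#' with the smallest absolute ppm error wins, then (for charge-less peaks
#' tried at several charges) the higher charge magnitude. Candidates of
#' identical mass within numerical precision are all reported for the
#' same peak and flagged ambiguous -- sequence isomers are isobaric.
#'
#' @param candidates data.frame with a \code{neutral_mass} column (see
#'   [products_with_mass()]) plus any identifier columns; row order is the
#'   candidate id.
#' @param peaks data.frame with columns \code{mz} and optionally
#'   \code{intensity} and \code{charge} (negative integers; peaks with
#'   missing charge are tried at every value of \code{charges}).
#' @param tol_ppm Match tolerance in ppm.
#' @param charges Charge states tried for charge-less peaks.
#' @return List with \code{matches} (data.frame: \code{peak},
#'   \code{mz}, \code{charge}, \code{candidate}, \code{ppm_error},
#'   \code{ambiguous}) and \code{unmatched} (peak indices).
#' @export
match_products <- function(candidates, peaks, tol_ppm = 10,
                           charges = -(1:6)) {
  stopifnot(is.data.frame(candidates), "neutral_mass" %in% names(candidates),
            is.data.frame(peaks), "mz" %in% names(peaks))
  if (is.null(peaks$charge)) peaks$charge <- NA_integer_
  rows <- list()
  unmatched <- integer(0)
  for (k in seq_len(nrow(peaks))) {
    zs <- if (is.na(peaks$charge[k])) charges else peaks$charge[k]
    best <- NULL
    for (z in zs) {
      theo <- mz(candidates$neutral_mass, z)
      ppm <- (peaks$mz[k] - theo) / theo * 1e6
      ok <- which(abs(ppm) <= tol_ppm)
      if (!length(ok)) next
      o <- ok[order(abs(ppm[ok]))]
      top <- o[abs(abs(ppm[o]) - abs(ppm[o[1]])) < 1e-9]
      cand <- data.frame(peak = k, mz = peaks$mz[k], charge = z,
                         candidate = top, ppm_error = ppm[top],
                         ambiguous = length(top) > 1L)
      better <- is.null(best) ||
        abs(cand$ppm_error[1]) < abs(best$ppm_error[1]) - 1e-9 ||
        (abs(abs(cand$ppm_error[1]) - abs(best$ppm_error[1])) <= 1e-9 &&
           abs(cand$charge[1]) > abs(best$charge[1]))
      if (better) best <- cand
    }
    if (is.null(best)) unmatched <- c(unmatched, k) else {
      rows[[length(rows) + 1L]] <- best
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = integer(0), mz = numeric(0), charge = integer(0),
               candidate = integer(0), ppm_error = numeric(0),
               ambiguous = logical(0))
  rownames(matches) <- NULL
  list(matches = matches, unmatched = unmatched)
}

#' Attach neutral masses to a product table
#'
#' @param products data.frame from [enumerate_products()] /
#'   [expected_abundances()] (columns \code{sequence}, \code{terminus5},
#'   \code{terminus3}).
#' @param kind Mass kind.
#' @param residues Residue table.
#' @return The input with a \code{neutral_mass} column appended.
#' @export
products_with_mass <- function(products, kind = c("monoisotopic", "average"),
                               residues = residue_table()) {
  kind <- match.arg(kind)
  products$neutral_mass <- vapply(seq_len(nrow(products)), function(k) {
    s <- parse_rna(products$sequence[k],
                   terminus5 = products$terminus5[k],
                   terminus3 = products$terminus3[k],
                   residues = residues)
    neutral_mass(s, kind = kind, residues = residues)
  }, numeric(1))
  products
}

#' Read a deconvoluted peak list CSV
#'
#' Expected columns: \code{mz}, \code{intensity}, optional \code{charge}.
#' Raw mzML parsing is deliberately out of scope; deconvolution is the
#' adapter seam to instrument software.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_peaks <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(pk)) {
    stop("peak list ", path, " lacks an 'mz' column", call. = FALSE)
  }
  if (!is.numeric(pk$mz) || any(pk$mz <= 0)) {
    stop("peak list ", path, ": mz must be positive numeric", call. = FALSE)
  }
  pk
}
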