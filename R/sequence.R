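# RNA sequences with bracketed modification codes.
#
# Coordinates are 1-based; bond i (1 <= i <= n-1) is the phosphodiester
# between residues i and i+1, indexed by its 5' residue.

#' Parse an RNA sequence string
#'
#' Accepts plain bases (\code{A}, \code{C}, \code{G}, \code{U}) and
#' bracketed modification codes (\code{"A[m5C]U"}). Unknown codes raise an
#' error naming the offending token and its character offset.
#'
#' @param text Sequence string, optionally with bracketed codes.
#' @param terminus5,terminus3 Terminus chemistry; defaults are 5'-hydroxyl
#'   and 3'-hydroxyl (synthetic RNA as purchased). See [terminus_delta()].
#' @param id Optional label.
#' @param residues Residue table (see [residue_table()]).
#' @return An object of class \code{rna_sequence}: residue \code{codes},
#'   \code{terminus5}, \code{terminus3}, \code{id}.
#' @examples
#' parse_rna("GCAUCAGAAAUACACCCGUAGGGCUUUGAGA")
#' parse_rna("A[m5C]U")
#' @export
parse_rna <- function(text, terminus5 = "hydroxyl", terminus3 = "hydroxyl",
                      id = NULL, residues = residue_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(text, "")[[1]]
  codes <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close)) {
        stop("unbalanced '[' at offset ", i, " in '", text, "'", call. = FALSE)
      }
      close <- close[1]
      tok <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!nzchar(tok)) stop("empty '[]' at offset ", i, call. = FALSE)
      codes <- c(codes, tok)
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' at offset ", i, " in '", text, "'", call. = FALSE)
    } else {
      codes <- c(codes, ch)
      i <- i + 1L
    }
  }
  offsets <- cumsum(c(1L, nchar(codes) + ifelse(nchar(codes) > 1L, 2L, 0L)))
  bad <- which(!codes %in% residues$code)
  if (length(bad)) {
    b <- bad[1]
    stop("unknown residue code '", codes[b], "' at offset ", offsets[b],
         " in '", text, "'", call. = FALSE)
  }
  new_rna_sequence(codes, terminus5, terminus3, id, residues)
}

new_rna_sequence <- function(codes, terminus5 = "hydroxyl",
                             terminus3 = "hydroxyl", id = NULL,
                             residues = residue_table()) {
  stopifnot(length(codes) >= 1L, all(codes %in% residues$code))
  terminus_delta(terminus5, "5prime")  # validates
  terminus_delta(terminus3, "3prime")
  structure(list(codes = codes, terminus5 = terminus5,
                 terminus3 = terminus3, id = id),
            class = "rna_sequence")
}

#' @export
length.rna_sequence <- function(x) length(x$codes)

#' Serialize an RNA sequence to its canonical string
#'
#' Modified residues are bracketed; parse and format round-trip.
#'
#' @param seq An \code{rna_sequence}.
#' @return Character string.
#' @export
format_rna <- function(seq) {
  stopifnot(inherits(seq, "rna_sequence"))
  paste0(ifelse(nchar(seq$codes) > 1L, paste0("[", seq$codes, "]"), seq$codes),
         collapse = "")
}

#' @export
as.character.rna_sequence <- function(x, ...) format_rna(x)

#' @export
print.rna_sequence <- function(x, ...) {
  cat("rna_sequence", if (!is.null(x$id)) paste0("'", x$id, "'") else "",
      "(", length(x), "nt )\n")
  cat("  5'-", format_rna(x), "-3'\n", sep = "")
  cat("  termini: 5'-", x$terminus5, ", 3'-", x$terminus3, "\n", sep = "")
  invisible(x)
}

#' Parent bases of a sequence
#'
#' Maps every residue (including modifications) to its parent base, used
#' for dinucleotide classification.
#'
#' @inheritParams format_rna
#' @param residues Residue table.
#' @return Character vector of \code{A}/\code{C}/\code{G}/\code{U}.
#' @export
parent_bases <- function(seq, residues = residue_table()) {
  residues$parent_base[match(seq$codes, residues$code)]
}

# "CpU" for plain bases, "[m5C]pU" when modified.
dinuc_label <- function(code5, code3) {
  tok <- function(x) ifelse(nchar(x) > 1L, paste0("[", x, "]"), x)
  paste0(tok(code5), "p", tok(code3))
}

#' Extract a sub-sequence (digestion product view)
#'
#' @inheritParams format_rna
#' @param start,end 1-based inclusive residue positions.
#' @param terminus5,terminus3 Termini of the extracted product; defaults
#'   preserve the parent terminus at a molecule boundary and use
#'   5'-hydroxyl / 2',3'-cyclic phosphate at internal cut sites.
#' @return An \code{rna_sequence}.
#' @export
subseq_rna <- function(seq, start, end,
                       terminus5 = NULL, terminus3 = NULL) {
  n <- length(seq)
  stopifnot(start >= 1L, end <= n, start <= end)
  if (is.null(terminus5)) {
    terminus5 <- if (start == 1L) seq$terminus5 else "hydroxyl"
  }
  if (is.null(terminus3)) {
    terminus3 <- if (end == n) seq$terminus3 else "cyclic_phosphate"
  }
  new_rna_sequence(seq$codes[start:end], terminus5, terminus3,
                   id = paste0(seq$id %||% "seq", "[", start, "-", end, "]"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neutral elemental formula of an oligonucleotide
#'
#' @inheritParams parent_bases
#' @return Named integer atom-count vector.
#' @export
oligo_formula <- function(seq, residues = residue_table()) {
  stopifnot(inherits(seq, "rna_sequence"))
  fs <- lapply(residues$formula[match(seq$codes, residues$code)], parse_formula)
  do.call(formula_sum, c(fs, list(terminus_delta(seq$terminus5, "5prime"),
                                  terminus_delta(seq$terminus3, "3prime"))))
}

#' Neutral mass of an oligonucleotide
#'
#' Sum of residue masses plus terminus deltas; depends only on the residue
#' composition and termini (order-independent), so sequence isomers are
#' isobaric.
#'
#' @inheritParams parent_bases
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' g <- parse_rna("G", terminus5 = "hydroxyl", terminus3 = "phosphate")
#' neutral_mass(g)  # 363.0580, GMP
#' @export
neutral_mass <- function(seq, kind = c("monoisotopic", "average"),
                         residues = residue_table()) {
  kind <- match.arg(kind)
  formula_mass(oligo_formula(seq, residues), kind = kind)
}

#' Read RNA sequences from FASTA
#'
#' Sequence lines may contain bracketed modification codes, which standard
#' FASTA readers reject; this reader is otherwise conventional (\code{>}
#' headers, free line wrapping, whitespace ignored).
#'
#' @param path FASTA file.
#' @inheritParams parse_rna
#' @return Named list of \code{rna_sequence} objects.
#' @export
read_rna_fasta <- function(path, terminus5 = "hydroxyl",
                           terminus3 = "hydroxyl",
                           residues = residue_table()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("not a FASTA file: ", path, call. = FALSE)
  }
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  out <- lapply(split(seq_along(lines), idx), function(ii) {
    id <- sub("^>\\s*", "", lines[ii[1]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- paste0(lines[ii[-1]], collapse = "")
    if (!nzchar(body)) stop("empty record '", id, "' in ", path, call. = FALSE)
    parse_rna(body, terminus5, terminus3, id = id, residues = residues)
  })
  stats::setNames(out, vapply(out, function(s) s$id, character(1)))
}

#' Write RNA sequences to FASTA
#'
#' @param seqs An \code{rna_sequence} or list of them.
#' @param path Output file.
#' @param width Line-wrap width (plain-base characters may exceed this when
#'   a bracketed code straddles the boundary; codes are never split).
#' @return Invisibly, \code{path}.
#' @export
write_rna_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    id <- s$id %||% names(seqs)[k] %||% paste0("seq", k)
    writeLines(paste0(">", id), con)
    toks <- ifelse(nchar(s$codes) > 1L, paste0("[", s$codes, "]"), s$codes)
    grp <- ceiling(seq_along(toks) / width)
    writeLines(vapply(split(toks, grp), paste0, character(1), collapse = ""),
               con)
  }
  invisible(path)
}
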