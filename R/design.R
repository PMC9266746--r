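# Probe substrate design and validation.
#
# A useful specificity probe must contain every ordered dinucleotide
# (4^2 = 16) so that each NpN bond class has at least one observable
# cleavage site, plus homopolymer runs to expose tandem-repeat behaviour
# (e.g. cusativin not cutting CpC). "Homopolymer" here means a maximal
# run of >= 3 identical bases; length-2 repeats are already counted as
# XpX dinucleotides.

#' Dinucleotide and homopolymer coverage of a sequence
#'
#' Modified residues are classified by their parent base.
#'
#' @param seq An \code{rna_sequence} or sequence string.
#' @param residues Residue table.
#' @return A \code{coverage_report}: \code{dinucleotides_present}
#'   (character, "XpY"), \code{n_distinct}, \code{homopolymer_runs}
#'   (data.frame base/start/length, maximal runs of length >= 3), and
#'   \code{length}.
#' @examples
#' coverage("GCAUCAGAAAUACACCCGUAGGGCUUUGAGA")$n_distinct  # 16
#' @export
coverage <- function(seq, residues = residue_table()) {
  if (is.character(seq)) seq <- parse_rna(seq, residues = residues)
  b <- parent_bases(seq, residues)
  n <- length(b)
  dinucs <- if (n >= 2L) {
    unique(paste0(b[-n], "p", b[-1L]))
  } else character(0)
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 3L
  runs <- data.frame(base = r$values[keep], start = starts[keep],
                     length = r$lengths[keep], stringsAsFactors = FALSE)
  structure(list(dinucleotides_present = sort(dinucs),
                 n_distinct = length(dinucs),
                 homopolymer_runs = runs,
                 length = n),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("coverage_report:", x$length, "nt,", x$n_distinct,
      "of 16 dinucleotides\n")
  missing <- setdiff(all_dinucleotides(), x$dinucleotides_present)
  if (length(missing)) cat("  missing:", paste(missing, collapse = " "), "\n")
  if (nrow(x$homopolymer_runs)) {
    cat("  homopolymer runs (>=3):",
        paste0(x$homopolymer_runs$base, "x", x$homopolymer_runs$length,
               "@", x$homopolymer_runs$start, collapse = " "), "\n")
  } else cat("  no homopolymer runs\n")
  invisible(x)
}

#' All 16 ordered dinucleotide labels
#' @return Character vector "ApA" ... "UpU".
#' @export
all_dinucleotides <- function() {
  b <- c("A", "C", "G", "U")
  as.vector(t(outer(b, b, function(x, y) paste0(x, "p", y))))
}

# Order-n de Bruijn cycle over an alphabet, by Lyndon-word concatenation
# (standard recursive construction); returns the cyclic symbol vector.
debruijn_cycle <- function(alphabet, n = 2L) {
  k <- length(alphabet)
  a <- integer(k * n + 1L)
  out <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j < k) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  alphabet[out + 1L]
}

#' Design a probe sequence covering all 16 dinucleotides
#'
#' Builds a linearized order-2 de Bruijn sequence over \{A,C,G,U\} (17 nt:
#' the 16-symbol cycle plus one overlap residue, the information-theoretic
#' floor), then greedily extends homopolymer runs to any required lengths.
#' Extending a doubled base \code{XX} to \code{XXX...} adds only \code{XpX}
#' pairs, which the de Bruijn core already contains, so full coverage is
#' preserved by construction and re-checked before returning.
#'
#' @param require_runs Named integer vector of minimum run lengths per
#'   base, e.g. \code{c(A = 3, C = 3, G = 3, U = 3)}; \code{NULL} for none.
#' @param forbidden_motifs Character vector of motifs the result must not
#'   contain (e.g. \code{"GGGG"}).
#' @param seed Integer; fixes the alphabet permutation and hence the
#'   output. Identical seeds give identical probes.
#' @param max_attempts Alternative constructions tried before declaring
#'   the constraints unsatisfiable.
#' @return An \code{rna_sequence} with \code{coverage()$n_distinct == 16}.
#' @examples
#' probe <- design_probe(require_runs = c(A = 3, C = 3, G = 3, U = 3),
#'                       seed = 1)
#' coverage(probe)$n_distinct  # 16
#' @export
design_probe <- function(require_runs = NULL, forbidden_motifs = NULL,
                         seed = 1L, max_attempts = 64L) {
  bases <- c("A", "C", "G", "U")
  if (!is.null(require_runs)) {
    if (is.null(names(require_runs)) ||
        !all(names(require_runs) %in% bases)) {
      stop("require_runs must be named with bases A/C/G/U", call. = FALSE)
    }
    # a required run that itself contains a forbidden motif can never work
    for (b in names(require_runs)) {
      run <- strrep(b, require_runs[[b]])
      hit <- vapply(forbidden_motifs, function(m) grepl(m, run, fixed = TRUE),
                    logical(1))
      if (any(hit)) {
        stop("unsatisfiable constraints: required run ", run,
             " contains forbidden motif ",
             forbidden_motifs[which(hit)[1]], call. = FALSE)
      }
    }
  }
  for (attempt in seq_len(max_attempts)) {
    s <- local({
      set.seed(seed + attempt - 1L)
      alpha <- sample(bases)
      cyc <- debruijn_cycle(alpha, 2L)
      sym <- c(cyc, cyc[1L])  # linearize: cycle + 1 overlap nt
      if (!is.null(require_runs)) {
        for (b in names(require_runs)) {
          r <- rle(sym)
          longest <- which.max(ifelse(r$values == b, r$lengths, -1L))
          have <- r$lengths[longest]
          need <- require_runs[[b]]
          if (r$values[longest] != b) next  # cannot happen over ACGU
          if (have < need) {
            pos <- cumsum(r$lengths)[longest]
            sym <- append(sym, rep(b, need - have), after = pos)
          }
        }
      }
      sym
    })
    txt <- paste0(s, collapse = "")
    ok_motifs <- !any(vapply(forbidden_motifs,
                             function(m) grepl(m, txt, fixed = TRUE),
                             logical(1)))
    cov <- coverage(txt)
    runs_ok <- TRUE
    if (!is.null(require_runs)) {
      for (b in names(require_runs)) {
        have <- cov$homopolymer_runs$length[cov$homopolymer_runs$base == b]
        if (require_runs[[b]] >= 3L &&
            (!length(have) || max(have) < require_runs[[b]])) runs_ok <- FALSE
      }
    }
    if (ok_motifs && runs_ok && cov$n_distinct == 16L) {
      return(parse_rna(txt, id = sprintf("probe_seed%d", seed)))
    }
  }
  stop("could not satisfy design constraints after ", max_attempts,
       " attempts; constraints may be unsatisfiable", call. = FALSE)
}
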