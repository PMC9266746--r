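# Cleavage models and in-silico digestion.
#
# The generative assumption is the independent-cut model: each scissile
# bond of each molecule is cut independently with a bond-specific
# probability. A digestion product [i, j] is the result of two
# endonucleolytic cuts (or a molecule end): its probability is
#   P(i, j) = cut(i-1) * cut(j) * prod_{i <= k < j} (1 - cut(k)),
# with cut(0) = cut(n) = 1 at the molecule ends.

#' Construct a cleavage model
#'
#' Specificity is expressed uniformly as bond-level cut probabilities on
#' ordered (5' base, 3' base) pairs, so "cleaves 5' of U" (MC1-like) and
#' "cleaves 3' of C" (cusativin-like) are both just rows/columns of the
#' same 4x4 matrix. Exact-code overrides (e.g. \code{"[m1A]pU" = 0})
#' take precedence over the parent-base entry for bonds involving
#' modified residues.
#'
#' @param p Named numeric vector of cut probabilities with "XpY" names
#'   (e.g. \code{c(ApU = 0.9, CpU = 0.9)}); unnamed pairs default to 0.
#'   Alternatively a 4x4 matrix with rownames = 5' base, colnames = 3' base.
#' @param overrides Named numeric vector keyed on exact residue codes,
#'   bracketed when modified, e.g. \code{c("[m1A]pU" = 0, "[D]p[D]" = 0.66)}.
#' @param product_terminus3 3' chemistry of internal cut products:
#'   \code{"cyclic_phosphate"} (transesterification default) or
#'   \code{"phosphate"} (post-hydrolysis linear form).
#' @param name Optional model label.
#' @return A \code{cleavage_model}.
#' @examples
#' t1 <- cleavage_model(c(GpA = 1, GpC = 1, GpG = 1, GpU = 1),
#'                      name = "RNase T1")
#' @export
cleavage_model <- function(p, overrides = NULL,
                           product_terminus3 = c("cyclic_phosphate",
                                                 "phosphate"),
                           name = NULL) {
  product_terminus3 <- match.arg(product_terminus3)
  bases <- c("A", "C", "G", "U")
  if (is.matrix(p)) {
    stopifnot(identical(rownames(p), bases), identical(colnames(p), bases))
    pm <- p
  } else {
    pm <- matrix(0, 4, 4, dimnames = list(bases, bases))
    if (length(p)) {
      if (is.null(names(p))) stop("p must be named 'XpY'", call. = FALSE)
      parts <- strsplit(names(p), "p", fixed = TRUE)
      for (k in seq_along(p)) {
        pr <- parts[[k]]
        if (length(pr) != 2L || !all(pr %in% bases)) {
          stop("invalid dinucleotide name '", names(p)[k], "'", call. = FALSE)
        }
        pm[pr[1], pr[2]] <- p[[k]]
      }
    }
  }
  if (any(pm < 0 | pm > 1)) {
    stop("cut probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(overrides)) {
    if (is.list(overrides)) overrides <- unlist(overrides)
    if (any(overrides < 0 | overrides > 1)) {
      stop("override probabilities must lie in [0, 1]", call. = FALSE)
    }
    codes <- unlist(lapply(strsplit(names(overrides), "p(?![^\\[]*\\])",
                                    perl = TRUE), identity))
    codes <- gsub("\\[|\\]", "", codes)
    bad <- setdiff(codes, residue_table()$code)
    if (length(bad)) {
      stop("override(s) reference unknown residue code(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(p = pm, overrides = overrides,
                 product_terminus3 = product_terminus3, name = name),
            class = "cleavage_model")
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat("cleavage_model", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  3' product terminus:", x$product_terminus3, "\n")
  print(round(x$p, 4))
  if (length(x$overrides)) {
    cat("  overrides:",
        paste0(names(x$overrides), "=", x$overrides, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-bond cut probabilities for a parent sequence
#'
#' Bond i lies between residues i and i+1. Exact-code overrides are
#' consulted first, then the parent-base matrix entry.
#'
#' @param parent An \code{rna_sequence}.
#' @param model A \code{cleavage_model}.
#' @param residues Residue table.
#' @return Numeric vector of length \code{n - 1}.
#' @export
bond_probabilities <- function(parent, model, residues = residue_table()) {
  stopifnot(inherits(parent, "rna_sequence"),
            inherits(model, "cleavage_model"))
  n <- length(parent)
  if (n < 2L) return(numeric(0))
  pb <- parent_bases(parent, residues)
  p <- model$p[cbind(pb[-n], pb[-1L])]
  if (length(model$overrides)) {
    lab <- dinuc_label(parent$codes[-n], parent$codes[-1L])
    hit <- match(lab, names(model$overrides))
    p[!is.na(hit)] <- model$overrides[hit[!is.na(hit)]]
  }
  unname(p)
}

#' Enumerate candidate digestion products
#'
#' Bonds with cut probability at least \code{min_probability} are treated
#' as cleavable sites. Candidates are all segments delimited by sites (or
#' molecule ends) containing at most \code{max_missed} internal sites
#' (missed cleavages), annotated with the exact independent-cut
#' probability -- which is 0 for a candidate that requires missing a
#' probability-1 bond, as in a strictly complete digest. Internal cut
#' boundaries get 5'-hydroxyl and the model's 3' product terminus; the
#' parent's own termini are preserved at positions 1 and n.
#'
#' @inheritParams bond_probabilities
#' @param max_missed Maximum internal cleavable sites left uncut.
#' @param min_probability Sites with model probability below this are not
#'   enumerated as cut points (keeps product lists finite for
#'   low-probability models).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{sequence}, \code{terminus5}, \code{terminus3}, \code{length},
#'   \code{n_missed}, \code{probability}.
#' @examples
#' parent <- parse_rna("GCAUCAGAAAUACACCCGUAGGGCUUUGAGA")
#' t1 <- preset_model("rnase_t1")
#' nrow(enumerate_products(parent, t1, max_missed = 0))  # 9 products
#' @export
enumerate_products <- function(parent, model, max_missed = 2L,
                               min_probability = 1e-4,
                               residues = residue_table()) {
  stopifnot(max_missed >= 0L)
  n <- length(parent)
  if (n < 1L) stop("empty parent", call. = FALSE)
  bp <- bond_probabilities(parent, model, residues)
  sites <- which(bp >= min_probability)
  starts <- c(0L, sites)          # cut after bond s -> product starts at s+1
  ends_all <- c(sites, n)
  rows <- vector("list", 0L)
  for (s in starts) {
    after <- ends_all[ends_all > s]
    # the (max_missed + 1) nearest sites, plus the 3' molecule end if the
    # number of sites skipped to reach it is within budget
    n_sites_after <- sum(sites > s)
    keep <- after[after != n][seq_len(min(max_missed + 1L,
                                          sum(after != n)))]
    if (n_sites_after <= max_missed) keep <- c(keep, n)
    for (e in keep) {
      internal <- sites[sites > s & sites < e]
      pcut0 <- if (s == 0L) 1 else bp[s]
      pcut1 <- if (e == n) 1 else bp[e]
      span <- seq.int(s + 1L, length.out = e - s - 1L)
      prob <- pcut0 * pcut1 * prod(1 - bp[span])
      rows[[length(rows) + 1L]] <- data.frame(
        start = s + 1L, end = e,
        n_missed = length(internal), probability = prob)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$terminus5 <- ifelse(out$start == 1L, parent$terminus5, "hydroxyl")
  out$terminus3 <- ifelse(out$end == n, parent$terminus3,
                          model$product_terminus3)
  out$length <- out$end - out$start + 1L
  out$sequence <- vapply(seq_len(nrow(out)), function(k) {
    format_rna(subseq_rna(parent, out$start[k], out$end[k]))
  }, character(1))
  rownames(out) <- NULL
  out[, c("start", "end", "sequence", "terminus5", "terminus3",
          "length", "n_missed", "probability")]
}

#' Expected product abundances under the independent-cut model
#'
#' Exact noiseless expectation for every segment with nonzero probability
#' (no missed-cleavage cap). Mass conservation holds exactly:
#' \code{sum(length * expected_count) == length(parent) * n_molecules}.
#'
#' @inheritParams bond_probabilities
#' @param n_molecules Number of parent molecules digested.
#' @return data.frame like [enumerate_products()] plus
#'   \code{expected_count}.
#' @export
expected_abundances <- function(parent, model, n_molecules = 1,
                                residues = residue_table()) {
  n <- length(parent)
  if (n < 1L) stop("empty parent", call. = FALSE)
  bp <- bond_probabilities(parent, model, residues)
  cut <- c(1, bp, 1)  # cut[i + 1] = cut prob of bond i; ends always "cut"
  log1m <- suppressWarnings(log(1 - bp))  # -Inf at p = 1 is fine
  rows <- vector("list", 0L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      span <- seq.int(i, length.out = j - i)
      prob <- cut[i] * cut[j + 1L] *
        (if (length(span)) exp(sum(log1m[span])) else 1)
      if (is.nan(prob)) prob <- 0
      if (prob > 0) {
        rows[[length(rows) + 1L]] <- data.frame(start = i, end = j,
                                                probability = prob)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$terminus5 <- ifelse(out$start == 1L, parent$terminus5, "hydroxyl")
  out$terminus3 <- ifelse(out$end == n, parent$terminus3,
                          model$product_terminus3)
  out$length <- out$end - out$start + 1L
  out$sequence <- vapply(seq_len(nrow(out)), function(k) {
    format_rna(subseq_rna(parent, out$start[k], out$end[k]))
  }, character(1))
  out$expected_count <- out$probability * n_molecules
  rownames(out) <- NULL
  out[, c("start", "end", "sequence", "terminus5", "terminus3",
          "length", "probability", "expected_count")]
}

#' Read / write a cleavage model as JSON
#'
#' The JSON object has fields \code{name}, \code{p} (named "XpY" ->
#' probability), optional \code{overrides}, and \code{product_terminus3}.
#'
#' @param path JSON file.
#' @return A \code{cleavage_model}.
#' @export
read_cleavage_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$p)) stop("model JSON ", path, " lacks field 'p'", call. = FALSE)
  cleavage_model(unlist(j$p),
                 overrides = if (length(j$overrides)) unlist(j$overrides),
                 product_terminus3 = j$product_terminus3 %||%
                   "cyclic_phosphate",
                 name = j$name %||% NULL)
}

#' @rdname read_cleavage_model
#' @param model A \code{cleavage_model}.
#' @export
write_cleavage_model <- function(model, path) {
  bases <- c("A", "C", "G", "U")
  p <- as.vector(t(model$p))
  names(p) <- as.vector(t(outer(bases, bases,
                                function(x, y) paste0(x, "p", y))))
  jsonlite::write_json(
    list(name = model$name, p = as.list(p[p > 0]),
         overrides = as.list(model$overrides),
         product_terminus3 = model$product_terminus3),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped cleavage-model presets
#'
#' \describe{
#'   \item{\code{"rnase_t1"}}{Guanosine-specific: p(GpN) = 1 for all N
#'     (complete digest, no missed cleavages under optimal conditions).}
#'   \item{\code{"mc1"}}{Cleaves 5' of uridine; probabilities are the
#'     midpoints of the reported per-dinucleotide efficiency bands, with
#'     modified-residue overrides ([m1A]pU, [m7G]pU, Gp[D] blocked;
#'     [D] behaves like U).}
#'   \item{\code{"cusativin"}}{Cleaves 3' of cytidine plus UpA and, at
#'     lower efficiency, [A/U]pU; CpC is not cleaved.}
#'   \item{\code{"uniform"}}{p for every bond (argument \code{p}).}
#' }
#'
#' @param name Preset name.
#' @param p Probability for the \code{"uniform"} preset.
#' @return A \code{cleavage_model}.
#' @export
preset_model <- function(name = c("rnase_t1", "mc1", "cusativin", "uniform"),
                         p = 0.5) {
  name <- match.arg(name)
  if (name == "uniform") {
    bases <- c("A", "C", "G", "U")
    return(cleavage_model(matrix(p, 4, 4, dimnames = list(bases, bases)),
                          name = sprintf("uniform(%g)", p)))
  }
  read_cleavage_model(system.file("extdata", "models",
                                  paste0(name, ".json"),
                                  package = "rnasespec", mustWork = TRUE))
}
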