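# Mapping identified products onto the parent and scoring per-bond
# cleavage efficiency.
#
# Every observed digestion product is the result of two endonucleolytic
# cuts (or a molecule end). A product ending at residue i supports a cut
# at bond i; one starting at residue i+1 supports the same cut; one
# spanning the bond internally is an undercut. The efficiency statistic
# at bond i is
#   efficiency = 100 * x / (x + y)
# with x = (sum of abundance ending at i + sum starting at i+1) / 2 and
# y = spanning (undercut) abundance. The 1/2 average of the two
# cut-generated ends avoids double counting and makes the estimator
# exactly unbiased under the independent-cut model (each cut produces one
# 5'-boundary and one 3'-boundary product, each of total expectation
# n * p). x + y = 0 is reported as "no coverage" (NA), never as 0.

#' Read an identification table
#'
#' CSV columns: \code{sequence} (bracketed modification codes allowed),
#' \code{abundance} (peak area, >= 0), \code{replicate}; optional
#' \code{terminus5}, \code{terminus3}, \code{start} (1-based anchor).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_identifications <- function(path) {
  ids <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "abundance", "replicate")
  miss <- setdiff(need, names(ids))
  if (length(miss)) {
    stop("identification table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ab <- suppressWarnings(as.numeric(ids$abundance))
  bad <- which(is.na(ab) | ab < 0)
  if (length(bad)) {
    stop("identification table ", path, ", row ", bad[1],
         ": abundance '", ids$abundance[bad[1]],
         "' is not a non-negative number", call. = FALSE)
  }
  ids$abundance <- ab
  ids
}

#' Place identified products on the parent sequence
#'
#' Anchored records (non-missing \code{start}) are validated against the
#' parent; unanchored records are placed at every exact occurrence of
#' their residue-code string. In \code{"split"} mode the abundance of a
#' multi-placement product is divided equally among its placements; in
#' \code{"unique_only"} mode such products are excluded from efficiency
#' scoring and returned separately.
#'
#' @param parent An \code{rna_sequence}.
#' @param ids Identification data.frame (see [read_identifications()]).
#' @param mode \code{"split"} or \code{"unique_only"}.
#' @param residues Residue table.
#' @return A \code{placement_result}: \code{placed} (data.frame
#'   \code{start}, \code{end}, \code{sequence}, \code{abundance},
#'   \code{replicate}, \code{n_placements}), \code{unmapped} (rows whose
#'   sequence is not a substring of the parent), \code{excluded}
#'   (multi-placement rows dropped in unique_only mode).
#' @examples
#' parent <- parse_rna("GCAUCAGAAAUACACCCGUAGGGCUUUGAGA")
#' ids <- data.frame(sequence = "UUGAGA", abundance = 100, replicate = 1)
#' place_products(parent, ids)$placed[, c("start", "end")]  # 26 31
#' @export
place_products <- function(parent, ids, mode = c("split", "unique_only"),
                           residues = residue_table()) {
  mode <- match.arg(mode)
  stopifnot(inherits(parent, "rna_sequence"))
  if (!nrow(ids)) {
    stop("empty identification table", call. = FALSE)
  }
  if (is.null(ids$replicate)) ids$replicate <- 1L
  if (is.null(ids$start)) ids$start <- NA_integer_
  placed <- list()
  unmapped <- integer(0)
  excluded <- integer(0)
  for (k in seq_len(nrow(ids))) {
    codes <- parse_rna(ids$sequence[k], residues = residues)$codes
    m <- length(codes)
    if (!is.na(ids$start[k])) {
      s <- as.integer(ids$start[k])
      fits <- s >= 1L && s + m - 1L <= length(parent) &&
        identical(parent$codes[s:(s + m - 1L)], codes)
      if (!fits) { unmapped <- c(unmapped, k); next }
      occ <- s
    } else {
      occ <- find_occurrences(parent$codes, codes)
      if (!length(occ)) { unmapped <- c(unmapped, k); next }
      if (length(occ) > 1L && mode == "unique_only") {
        excluded <- c(excluded, k)
        next
      }
    }
    placed[[length(placed) + 1L]] <- data.frame(
      start = occ, end = occ + m - 1L,
      sequence = ids$sequence[k],
      abundance = ids$abundance[k] / length(occ),
      replicate = ids$replicate[k],
      n_placements = length(occ),
      stringsAsFactors = FALSE)
  }
  placed <- if (length(placed)) do.call(rbind, placed) else
    data.frame(start = integer(0), end = integer(0), sequence = character(0),
               abundance = numeric(0), replicate = integer(0),
               n_placements = integer(0))
  rownames(placed) <- NULL
  structure(list(placed = placed,
                 unmapped = ids[unmapped, , drop = FALSE],
                 excluded = ids[excluded, , drop = FALSE],
                 mode = mode),
            class = "placement_result")
}

# All start positions where `pattern` occurs in `codes` (exact match).
find_occurrences <- function(codes, pattern) {
  m <- length(pattern)
  n <- length(codes)
  if (m > n) return(integer(0))
  cand <- which(codes == pattern[1])
  cand <- cand[cand + m - 1L <= n]
  cand[vapply(cand, function(s) {
    identical(codes[s:(s + m - 1L)], pattern)
  }, logical(1))]
}

#' Four-level cleavage-efficiency category
#'
#' \code{< 5} extremely_low; \code{[5, 25)} low; \code{[25, 50]} moderate;
#' \code{> 50} efficient. Exact boundary values fall into the band whose
#' printed range starts there (5 -> low, 25 -> moderate), and exactly 50
#' is moderate.
#'
#' @param efficiency Numeric vector of percentages (NA allowed).
#' @return Character vector of categories (NA for NA input).
#' @export
efficiency_category <- function(efficiency) {
  out <- rep(NA_character_, length(efficiency))
  ok <- !is.na(efficiency)
  e <- efficiency[ok]
  out[ok] <- ifelse(e < 5, "extremely_low",
             ifelse(e < 25, "low",
             ifelse(e <= 50, "moderate", "efficient")))
  out
}

#' Per-bond cleavage efficiencies from placed products
#'
#' @param parent An \code{rna_sequence}.
#' @param placed Placement data.frame (the \code{placed} element of
#'   [place_products()], or any data.frame with \code{start}, \code{end},
#'   \code{abundance} and optionally \code{replicate} /
#'   \code{expected_count}).
#' @param replicate If given, only rows of this replicate are used.
#' @param residues Residue table.
#' @return data.frame with one row per bond: \code{bond}, \code{dinuc}
#'   (parent-base class), \code{dinuc_exact} (modification-aware label),
#'   \code{x}, \code{y}, \code{efficiency} (NA when x + y = 0),
#'   \code{category}, \code{covered}.
#' @export
bond_efficiencies <- function(parent, placed, replicate = NULL,
                              residues = residue_table()) {
  stopifnot(inherits(parent, "rna_sequence"))
  if (inherits(placed, "placement_result")) placed <- placed$placed
  if (is.null(placed$abundance) && !is.null(placed$expected_count)) {
    placed$abundance <- placed$expected_count
  }
  stopifnot(all(c("start", "end", "abundance") %in% names(placed)))
  if (!is.null(replicate) && !is.null(placed$replicate)) {
    placed <- placed[placed$replicate == replicate, , drop = FALSE]
  }
  n <- length(parent)
  pb <- parent_bases(parent, residues)
  bonds <- seq_len(n - 1L)
  end_ab <- vapply(bonds, function(i) {
    sum(placed$abundance[placed$end == i])
  }, numeric(1))
  start_ab <- vapply(bonds, function(i) {
    sum(placed$abundance[placed$start == i + 1L])
  }, numeric(1))
  span_ab <- vapply(bonds, function(i) {
    sum(placed$abundance[placed$start <= i & placed$end > i])
  }, numeric(1))
  x <- (end_ab + start_ab) / 2
  y <- span_ab
  eff <- ifelse(x + y > 0, 100 * x / (x + y), NA_real_)
  data.frame(bond = bonds,
             dinuc = paste0(pb[bonds], "p", pb[bonds + 1L]),
             dinuc_exact = dinuc_label(parent$codes[bonds],
                                       parent$codes[bonds + 1L]),
             x = x, y = y, efficiency = eff,
             category = efficiency_category(eff),
             covered = x + y > 0,
             stringsAsFactors = FALSE)
}

#' Aggregate bond efficiencies across replicates
#'
#' Reports bonds individually and pooled per dinucleotide class. The
#' per-class pooled efficiency of a replicate is
#' \code{100 * sum(x) / sum(x + y)} over the covered bonds of the class;
#' mean, sd and min-max are then taken across replicates. Because it is
#' not obvious whether published ranges run across replicates or across
#' bonds of the same class, both are reported
#' (\code{rep_min}/\code{rep_max} vs \code{bond_min}/\code{bond_max}).
#'
#' @param bond_tables Either a list of per-replicate data.frames from
#'   [bond_efficiencies()], or one such data.frame (single replicate).
#' @return An \code{efficiency_profile}: \code{per_bond} (mean/sd/range
#'   across replicates for every bond), \code{per_dinuc} (replicate stats
#'   of the pooled class efficiency plus across-bond range and category of
#'   the mean), \code{n_replicates}.
#' @examples
#' # three replicates of a single fully covered bond at 80/90/100 percent
#' reps <- lapply(c(80, 90, 100), function(e) {
#'   data.frame(bond = 1, dinuc = "CpU", dinuc_exact = "CpU",
#'              x = e, y = 100 - e, efficiency = e,
#'              category = efficiency_category(e), covered = TRUE)
#' })
#' aggregate_profiles(reps)$per_dinuc[, c("mean", "rep_min", "rep_max")]
#' @export
aggregate_profiles <- function(bond_tables) {
  if (is.data.frame(bond_tables)) bond_tables <- list(bond_tables)
  stopifnot(length(bond_tables) >= 1L)
  nrep <- length(bond_tables)
  sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  # per bond across replicates
  all_eff <- vapply(bond_tables, function(tb) tb$efficiency,
                    numeric(nrow(bond_tables[[1]])))
  all_eff <- matrix(all_eff, nrow = nrow(bond_tables[[1]]))
  tb1 <- bond_tables[[1]]
  per_bond <- data.frame(
    bond = tb1$bond, dinuc = tb1$dinuc, dinuc_exact = tb1$dinuc_exact,
    mean = apply(all_eff, 1, function(v) mean(v[!is.na(v)])),
    sd = apply(all_eff, 1, function(v) sd_or_na(v[!is.na(v)])),
    min = apply(all_eff, 1, function(v) suppressWarnings(min(v, na.rm = TRUE))),
    max = apply(all_eff, 1, function(v) suppressWarnings(max(v, na.rm = TRUE))),
    n_covered = apply(all_eff, 1, function(v) sum(!is.na(v))),
    stringsAsFactors = FALSE)
  per_bond$mean[is.nan(per_bond$mean)] <- NA_real_
  per_bond$min[!is.finite(per_bond$min)] <- NA_real_
  per_bond$max[!is.finite(per_bond$max)] <- NA_real_
  per_bond$category <- efficiency_category(per_bond$mean)
  # pooled per dinucleotide class (modification-aware), per replicate
  classes <- unique(tb1$dinuc_exact)
  pooled <- sapply(bond_tables, function(tb) {
    vapply(classes, function(d) {
      rows <- tb$dinuc_exact == d & tb$covered
      if (!any(rows)) return(NA_real_)
      100 * sum(tb$x[rows]) / sum(tb$x[rows] + tb$y[rows])
    }, numeric(1))
  })
  pooled <- matrix(pooled, nrow = length(classes),
                   dimnames = list(classes, NULL))
  per_dinuc <- data.frame(
    dinuc_exact = classes,
    dinuc = tb1$dinuc[match(classes, tb1$dinuc_exact)],
    n_bonds = as.integer(table(tb1$dinuc_exact)[classes]),
    mean = apply(pooled, 1, function(v) mean(v[!is.na(v)])),
    sd = apply(pooled, 1, function(v) sd_or_na(v[!is.na(v)])),
    rep_min = apply(pooled, 1,
                    function(v) suppressWarnings(min(v, na.rm = TRUE))),
    rep_max = apply(pooled, 1,
                    function(v) suppressWarnings(max(v, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  per_dinuc$mean[is.nan(per_dinuc$mean)] <- NA_real_
  per_dinuc$rep_min[!is.finite(per_dinuc$rep_min)] <- NA_real_
  per_dinuc$rep_max[!is.finite(per_dinuc$rep_max)] <- NA_real_
  bm <- tapply(per_bond$mean, per_bond$dinuc_exact,
               function(v) if (all(is.na(v))) c(NA_real_, NA_real_) else
                 range(v, na.rm = TRUE))
  per_dinuc$bond_min <- vapply(per_dinuc$dinuc_exact,
                               function(d) bm[[d]][1], numeric(1))
  per_dinuc$bond_max <- vapply(per_dinuc$dinuc_exact,
                               function(d) bm[[d]][2], numeric(1))
  per_dinuc$category <- efficiency_category(per_dinuc$mean)
  rownames(per_dinuc) <- NULL
  structure(list(per_bond = per_bond, per_dinuc = per_dinuc,
                 n_replicates = nrep),
            class = "efficiency_profile")
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat("efficiency_profile:", nrow(x$per_bond), "bonds,",
      x$n_replicates, "replicate(s)\n")
  cat("x = mean of 5'/3' cut-boundary abundances;",
      "categories: <5 extremely_low, 5-25 low, 25-50 moderate,",
      ">50 efficient\n")
  print(x$per_dinuc[order(-replace(x$per_dinuc$mean,
                                   is.na(x$per_dinuc$mean), -1)), ],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an efficiency profile to disk
#'
#' Emits a per-bond TSV, a per-dinucleotide TSV, and a JSON summary whose
#' header records the scoring conventions (x definition, category
#' boundaries, placement mode) so results are self-describing.
#'
#' @param profile An \code{efficiency_profile}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param mode Placement mode recorded in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_profile <- function(profile, dir, prefix = "profile",
                          mode = "split") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- file.path(dir, paste0(prefix, "_bonds.tsv"))
  pd <- file.path(dir, paste0(prefix, "_dinucleotides.tsv"))
  pj <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.table(profile$per_bond, pb, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(profile$per_dinuc, pd, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    conventions = list(
      coordinates = "1-based residues; bond i joins residues i and i+1",
      x_definition = paste("mean of summed product abundance ending at the",
                           "bond and starting just after it"),
      efficiency = "100 * x / (x + y); x+y = 0 reported as no coverage",
      categories = list(extremely_low = "<5", low = "[5,25)",
                        moderate = "[25,50]", efficient = ">50"),
      placement_mode = mode),
    n_replicates = profile$n_replicates,
    per_dinuc = profile$per_dinuc), pj,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(pb, pd, pj))
}
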