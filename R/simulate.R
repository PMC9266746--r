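# Digestion simulator with known ground truth.
#
# Peak areas are positive and roughly proportional to amount, so
# replicate noise is modelled as multiplicative lognormal per product per
# replicate. Mononucleotides escape LC-MS detection; the detection floor
# (min_detectable_length, default 2 nt) reproduces that censoring.

#' Build a simulation configuration
#'
#' @param parent An \code{rna_sequence}.
#' @param model Ground-truth \code{cleavage_model}.
#' @param n_molecules Parent molecules digested per replicate.
#' @param noise_sigma Lognormal sd of multiplicative abundance noise
#'   (0 = noiseless).
#' @param n_replicates Independent replicates.
#' @param min_detectable_length Products shorter than this are dropped
#'   (the undetectable-mononucleotide floor).
#' @param seed Integer; fixes the full output.
#' @return A \code{simulation_config}.
#' @export
simulation_config <- function(parent, model, n_molecules = 1e4,
                              noise_sigma = 0.2, n_replicates = 4L,
                              min_detectable_length = 2L, seed = 1L) {
  stopifnot(inherits(parent, "rna_sequence"),
            inherits(model, "cleavage_model"),
            n_molecules > 0, noise_sigma >= 0, n_replicates >= 1L,
            min_detectable_length >= 1L)
  structure(list(parent = parent, model = model,
                 n_molecules = n_molecules, noise_sigma = noise_sigma,
                 n_replicates = as.integer(n_replicates),
                 min_detectable_length = as.integer(min_detectable_length),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a partial digest into identification tables
#'
#' Expected abundances under the independent-cut model are perturbed by
#' lognormal noise per product per replicate, then censored at the
#' detection floor. Identical configurations (including seed) produce
#' identical output.
#'
#' @param config A \code{simulation_config}.
#' @param anchored If TRUE the identification tables carry the true
#'   \code{start} anchors; default FALSE mimics real identifications,
#'   which must be placed by sequence matching.
#' @return A \code{simulated_digest}: \code{ids} (data.frame
#'   \code{sequence}, \code{terminus5}, \code{terminus3},
#'   \code{abundance}, \code{replicate}, and \code{start} when anchored)
#'   and \code{truth} (the config plus the exact expected-abundance
#'   table), so recovery tests never re-derive the ground truth.
#' @export
simulate_digest <- function(config, anchored = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  exp_tab <- expected_abundances(config$parent, config$model,
                                 n_molecules = config$n_molecules)
  detectable <- exp_tab[exp_tab$length >= config$min_detectable_length, ,
                        drop = FALSE]
  set.seed(config$seed)
  ids <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    noise <- stats::rlnorm(nrow(detectable), meanlog = 0,
                           sdlog = config$noise_sigma)
    data.frame(sequence = detectable$sequence,
               terminus5 = detectable$terminus5,
               terminus3 = detectable$terminus3,
               abundance = detectable$expected_count * noise,
               replicate = r,
               start = detectable$start,
               stringsAsFactors = FALSE)
  }))
  if (!anchored) ids$start <- NULL
  rownames(ids) <- NULL
  structure(list(ids = ids,
                 truth = list(config = config, expected = exp_tab)),
            class = "simulated_digest")
}

#' Write simulated identification tables and ground truth
#'
#' One CSV per replicate plus \code{ground_truth.json} (model, config,
#' exact expectations).
#'
#' @param sim A \code{simulated_digest}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulated_digest <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(sim$truth$config$n_replicates), function(r) {
    p <- file.path(dir, sprintf("ids_rep%d.csv", r))
    utils::write.csv(sim$ids[sim$ids$replicate == r, , drop = FALSE],
                     p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  cfg <- sim$truth$config
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    parent = format_rna(cfg$parent),
    model = list(name = cfg$model$name,
                 p = as.list(stats::setNames(as.vector(t(cfg$model$p)),
                                             all_dinucleotides())),
                 overrides = as.list(cfg$model$overrides),
                 product_terminus3 = cfg$model$product_terminus3),
    n_molecules = cfg$n_molecules, noise_sigma = cfg$noise_sigma,
    n_replicates = cfg$n_replicates,
    min_detectable_length = cfg$min_detectable_length, seed = cfg$seed,
    expected = sim$truth$expected), gt,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, gt))
}

#' Simulate a deconvoluted peak list from products
#'
#' Each product/charge pair yields one peak; observed m/z is the
#' theoretical value jittered multiplicatively by
#' \code{Normal(0, ppm_jitter)} ppm. At tolerance >= 3 * jitter nearly all
#' peaks round-trip through [match_products()].
#'
#' @param products data.frame with \code{sequence}, \code{terminus5},
#'   \code{terminus3} and an abundance-like column (\code{abundance} or
#'   \code{expected_count}; defaults to 1).
#' @param charges Negative integer charge states to emit.
#' @param ppm_jitter Gaussian m/z jitter in ppm.
#' @param seed Integer seed.
#' @param residues Residue table.
#' @return data.frame \code{mz}, \code{intensity}, \code{charge}.
#' @export
simulate_peaks <- function(products, charges = -(1:3), ppm_jitter = 0,
                           seed = 1L, residues = residue_table()) {
  stopifnot(all(charges <= -1), ppm_jitter >= 0)
  withmass <- products_with_mass(products, residues = residues)
  ab <- withmass$abundance %||% withmass$expected_count %||%
    rep(1, nrow(withmass))
  set.seed(seed)
  out <- do.call(rbind, lapply(charges, function(z) {
    theo <- mz(withmass$neutral_mass, z)
    data.frame(mz = theo * (1 + stats::rnorm(length(theo), 0,
                                             ppm_jitter) * 1e-6),
               intensity = ab, charge = z)
  }))
  rownames(out) <- NULL
  out
}
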