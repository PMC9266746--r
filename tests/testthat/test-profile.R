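# Product placement, the x/(x+y) estimator, and replicate aggregation.

probe <- parse_rna(PROBE31)

test_that("known products place at their unique positions", {
  ids <- data.frame(sequence = c("UUGAGA", "UUUGAGA", "UACACCCGUAGGGCU"),
                    abundance = c(100, 80, 60), replicate = 1)
  pl <- place_products(probe, ids)
  expect_equal(pl$placed$start, c(26, 25, 11))
  expect_equal(pl$placed$end, c(31, 31, 25))
  expect_equal(pl$placed$n_placements, rep(1L, 3))
  expect_equal(nrow(pl$unmapped), 0)
})

test_that("ambiguous and absent products are split, excluded, or reported", {
  ids <- data.frame(sequence = c("G", "AAAAAA"), abundance = c(8, 5),
                    replicate = 1)
  pl <- place_products(probe, ids, mode = "split")
  g <- pl$placed[pl$placed$sequence == "G", ]
  expect_equal(g$start, c(1, 7, 18, 21, 22, 23, 28, 30))
  expect_equal(g$abundance, rep(1, 8))  # 1/8 of 8 per placement
  expect_equal(pl$unmapped$sequence, "AAAAAA")
  # unique_only drops the multi-placement product instead
  pl2 <- place_products(probe, ids, mode = "unique_only")
  expect_equal(pl2$excluded$sequence, "G")
  expect_equal(nrow(pl2$placed), 0)
  # anchored records are validated against the parent
  ids3 <- data.frame(sequence = "UUGAGA", abundance = 1, replicate = 1,
                     start = c(26, 2))
  pl3 <- place_products(probe, ids3)
  expect_equal(pl3$placed$start, 26)
  expect_equal(nrow(pl3$unmapped), 1)
})

test_that("the efficiency formula matches its defining example", {
  # cut at bond 2 of ACGU: products AC| and |GU at 80 each, spanning 20
  s <- parse_rna("ACGU")
  placed <- data.frame(start = c(1, 3, 1), end = c(2, 4, 4),
                       abundance = c(80, 80, 20))
  be <- bond_efficiencies(s, placed)
  expect_equal(be$efficiency[2], 100 * 80 / (80 + 20))
  expect_equal(be$x[2], 80)  # mean of the two cut-boundary sums
  expect_equal(be$y[2], 20)
  expect_equal(be$category[2], "efficient")
  # bonds strictly inside products are pure undercuts: efficiency 0
  expect_equal(be$efficiency[1], 0)
  expect_equal(be$y[1], 100)
})

test_that("noiseless expectations recover exactly 100*p at every bond", {
  m <- cleavage_model(c(ApC = 0.5))
  ea <- expected_abundances(parse_rna("AC"), m)
  be <- bond_efficiencies(parse_rna("AC"), ea)
  expect_equal(be$efficiency, 50, tolerance = 1e-12)
  set.seed(77)
  for (rep in 1:10) {
    parent <- random_parent(sample(2:8, 1))
    model <- random_grid_model(grid = c(0, 0.25, 0.5, 0.75, 1))
    ea <- expected_abundances(parent, model, n_molecules = 1)
    be <- bond_efficiencies(parent, ea)
    p <- bond_probabilities(parent, model)
    expect_equal(be$efficiency, 100 * p, tolerance = 1e-9)
  }
})

test_that("efficiencies are invariant to abundance rescaling", {
  m <- cleavage_model(c(ApU = 0.9, CpU = 0.9, UpU = 0.5, CpA = 0.15))
  ea <- expected_abundances(probe, m, n_molecules = 1000)
  be1 <- bond_efficiencies(probe, ea)
  ea$expected_count <- ea$expected_count * 3.7e5
  be2 <- bond_efficiencies(probe, ea)
  expect_equal(be1$efficiency, be2$efficiency, tolerance = 1e-12)
})

test_that("no coverage is NA, distinct from an observed 0%", {
  s <- parse_rna("ACGU")
  placed <- data.frame(start = 1, end = 2, abundance = 10)
  be <- bond_efficiencies(s, placed)
  expect_true(is.na(be$efficiency[3]))   # nothing touches bond 3
  expect_false(be$covered[3])
  expect_true(is.na(be$category[3]))
  expect_equal(be$efficiency[1], 0)      # spanned but never cut: true 0%
  expect_true(be$covered[1])
  expect_equal(be$efficiency[2], 100)    # product boundary at bond 2
})

test_that("the detection floor biases only bonds next to mononucleotides", {
  m <- cleavage_model(c(GpA = 0.5, GpC = 0.5, GpG = 0.5, GpU = 0.5))
  ea <- expected_abundances(probe, m, n_molecules = 1)
  full <- bond_efficiencies(probe, ea)
  cens <- bond_efficiencies(probe, ea[ea$length >= 2, ])
  p <- bond_probabilities(probe, m)
  # bonds not adjacent to a length-1 product position are unbiased
  mono_pos <- ea$start[ea$length == 1]
  near <- unique(c(mono_pos - 1L, mono_pos))
  far <- setdiff(which(p > 0), near)
  expect_equal(cens$efficiency[far], 100 * p[far], tolerance = 1e-9)
  # adjacent bonds lose only the missing end term: bias is downward and
  # bounded by half the boundary abundance
  expect_true(all(cens$efficiency[intersect(near, which(p > 0))] <=
                    full$efficiency[intersect(near, which(p > 0))] + 1e-9))
})

test_that("replicate aggregation reports range, sd, and categories", {
  reps <- lapply(c(80, 90, 100), function(e) {
    data.frame(bond = 1, dinuc = "CpU", dinuc_exact = "CpU",
               x = e, y = 100 - e, efficiency = e,
               category = efficiency_category(e), covered = TRUE)
  })
  prof <- aggregate_profiles(reps)
  expect_equal(prof$per_dinuc$mean, 90)
  expect_equal(prof$per_dinuc$rep_min, 80)
  expect_equal(prof$per_dinuc$rep_max, 100)
  expect_equal(prof$per_dinuc$sd, stats::sd(c(80, 90, 100)))
  expect_equal(prof$per_dinuc$category, "efficient")
  # single replicate: sd unavailable, range collapses to the point
  prof1 <- aggregate_profiles(reps[[1]])
  expect_true(is.na(prof1$per_dinuc$sd))
  expect_equal(prof1$per_dinuc$rep_min, prof1$per_dinuc$rep_max)
})

test_that("category boundaries follow the printed band edges", {
  expect_equal(efficiency_category(c(0, 1.25, 4.999)),
               rep("extremely_low", 3))
  expect_equal(efficiency_category(c(5, 24.999)), c("low", "low"))
  expect_equal(efficiency_category(c(25, 50)), c("moderate", "moderate"))
  expect_equal(efficiency_category(c(50.001, 100)),
               c("efficient", "efficient"))
  expect_true(is.na(efficiency_category(NA_real_)))
})

test_that("modified bonds aggregate under their exact-code dinucleotide", {
  s <- parse_rna("A[m5C]UCU")
  placed <- data.frame(start = c(1, 3, 1, 4, 1), end = c(2, 5, 5, 5, 3),
                       abundance = c(50, 50, 50, 10, 10))
  be <- bond_efficiencies(s, placed)
  expect_equal(be$dinuc[2], "CpU")
  expect_equal(be$dinuc_exact[2], "[m5C]pU")
  prof <- aggregate_profiles(be)
  expect_true(all(c("[m5C]pU", "CpU") %in% prof$per_dinuc$dinuc_exact))
})

test_that("identification tables validate abundance with row diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,abundance,replicate",
               "UUGAGA,100,1", "UAG,-3,1"), path)
  expect_error(read_identifications(path), "row 2")
  writeLines(c("sequence,abundance", "UUGAGA,100"), path)
  expect_error(read_identifications(path), "replicate")
})
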