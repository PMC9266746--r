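# Cleavage models, product enumeration, and expected abundances.

probe <- parse_rna(PROBE31)

test_that("a guanosine-specific complete digest yields the 9 known products", {
  t1 <- preset_model("rnase_t1")
  prods <- enumerate_products(probe, t1, max_missed = 0)
  expect_equal(prods$sequence,
               c("G", "CAUCAG", "AAAUACACCCG", "UAG", "G", "G",
                 "CUUUG", "AG", "A"))
  expect_equal(prods$probability, rep(1, 9))
  expect_equal(prods$n_missed, rep(0L, 9))
  # internal products carry 5'-OH / cyclic phosphate; parent ends preserved
  expect_true(all(prods$terminus5 == "hydroxyl"))
  expect_equal(prods$terminus3,
               c(rep("cyclic_phosphate", 8), "hydroxyl"))
  # cross-check the product set against the brute-force cut-pattern oracle
  bp <- bond_probabilities(probe, t1)
  orc <- oracle_expected(bp)
  expect_equal(nrow(orc), 9)
  expect_equal(orc$start, prods$start)
  expect_equal(orc$end, prods$end)
})

test_that("missed-cleavage enumeration recovers the known partial products", {
  # cleaves 5' of U; CpU missed cleavage exposes the 11-25 product
  m <- cleavage_model(c(ApU = 1, CpU = 1, UpU = 0.5), name = "mc1-like")
  prods <- enumerate_products(probe, m, max_missed = 2)
  get <- function(s) prods[prods$sequence == s, ]
  expect_equal(c(get("UUGAGA")$start, get("UUGAGA")$end), c(26, 31))
  expect_equal(get("UUGAGA")$n_missed, 1L)
  expect_equal(c(get("UUUGAGA")$start, get("UUUGAGA")$end), c(25, 31))
  expect_equal(get("UUUGAGA")$n_missed, 2L)
  u <- get("UACACCCGUAGGGCU")
  expect_equal(c(u$start, u$end), c(11, 25))
  expect_equal(u$n_missed, 1L)   # the missed CpU at bond 24
  expect_equal(u$probability, 0) # a p = 1 bond left uncut never occurs
  # tighter budget excludes the two-missed product
  prods1 <- enumerate_products(probe, m, max_missed = 1)
  expect_false("UUUGAGA" %in% prods1$sequence)
  # a single-residue parent digests to itself
  one <- enumerate_products(parse_rna("A"), m)
  expect_equal(nrow(one), 1)
  expect_equal(one$probability, 1)
})

test_that("modified-residue overrides take precedence over parent bases", {
  m <- cleavage_model(c(ApU = 1, CpU = 1),
                      overrides = c("[m1A]pU" = 0, "[m5C]pU" = 1))
  s <- parse_rna("G[m1A]UA[m5C]U")
  bp <- bond_probabilities(s, m)
  expect_equal(bp, c(0, 0, 0, 0, 1))  # [m1A]pU blocked, [m5C]pU cleaved
  expect_error(cleavage_model(c(ApU = 1), overrides = c("[foo]pU" = 0)),
               "foo")
  expect_error(cleavage_model(c(ApU = 1.2)), "\\[0, 1\\]")
})

test_that("expected abundances match hand-computable cases", {
  # no cuts: the parent survives intact
  none <- cleavage_model(numeric(0))
  ea <- expected_abundances(probe, none, n_molecules = 50)
  expect_equal(nrow(ea), 1)
  expect_equal(ea$expected_count, 50)
  expect_equal(ea$sequence, PROBE31)
  # one bond at p = 0.5 splits half the molecules
  m <- cleavage_model(c(CpG = 0.5))
  ea2 <- expected_abundances(parse_rna("ACGU"), m, n_molecules = 1000)
  expect_equal(ea2$expected_count[ea2$sequence == "ACGU"], 500)
  expect_equal(ea2$expected_count[ea2$sequence == "AC"], 500)
  expect_equal(ea2$expected_count[ea2$sequence == "GU"], 500)
  # complete guanosine digest of the 31-mer: G at positions 1, 22, 23
  t1 <- preset_model("rnase_t1")
  ea3 <- expected_abundances(probe, t1, n_molecules = 100)
  expect_equal(sum(ea3$expected_count[ea3$sequence == "G"]), 300)
  expect_equal(sort(ea3$start[ea3$sequence == "G"]), c(1, 22, 23))
})

test_that("expected abundances equal exhaustive cut-pattern enumeration", {
  set.seed(101)
  for (rep in 1:8) {
    parent <- random_parent(sample(2:8, 1))
    model <- random_grid_model()
    bp <- bond_probabilities(parent, model)
    ea <- expected_abundances(parent, model, n_molecules = 1)
    orc <- oracle_expected(bp)
    expect_equal(nrow(ea), nrow(orc))
    expect_equal(ea$start, orc$start)
    expect_equal(ea$end, orc$end)
    expect_equal(ea$expected_count, orc$expected, tolerance = 1e-12)
  }
})

test_that("mass conservation holds for arbitrary models", {
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(2:20, 1)
    parent <- random_parent(n)
    model <- random_grid_model(grid = stats::runif(16))
    ea <- expected_abundances(parent, model, n_molecules = 1e4)
    expect_equal(sum(ea$length * ea$expected_count), n * 1e4,
                 tolerance = 1e-8)
  }
})

test_that("raising one bond probability never lowers cut-product mass there", {
  set.seed(303)
  parent <- random_parent(8)
  model <- random_grid_model(grid = c(0.2, 0.4, 0.6))
  bp <- bond_probabilities(parent, model)
  for (i in seq_along(bp)) {
    lo <- oracle_expected(bp)
    bp2 <- bp; bp2[i] <- min(1, bp[i] + 0.3)
    hi <- oracle_expected(bp2)
    ends <- function(tab) sum(tab$expected[tab$end == i]) +
      sum(tab$expected[tab$start == i + 1])
    expect_gte(ends(hi), ends(lo) - 1e-12)
  }
})

test_that("cleavage models round-trip through JSON", {
  m <- cleavage_model(c(ApU = 0.9, CpU = 0.9, UpU = 0.5, GpU = 0.0125),
                      overrides = c("[m1A]pU" = 0),
                      product_terminus3 = "phosphate", name = "demo")
  path <- withr::local_tempfile(fileext = ".json")
  write_cleavage_model(m, path)
  back <- read_cleavage_model(path)
  expect_equal(back$p, m$p)
  expect_equal(back$overrides, m$overrides)
  expect_equal(back$product_terminus3, "phosphate")
})
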