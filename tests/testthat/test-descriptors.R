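test_that("ethanol fragments match hand enumeration", {
  expect_equal(enumerate_fragments("CCO", fragment_scheme("sequence", 2, 2)),
               c("C-C" = 1L, "C-O" = 1L))
  expect_equal(enumerate_fragments("CCO", fragment_scheme("sequence", 3, 3)),
               c("C-C-O" = 1L))
  expect_equal(enumerate_fragments("CCO", fragment_scheme("atom_pair", 2, 2)),
               c("C.C.1" = 1L, "C.O.1" = 1L, "C.O.2" = 1L))
  expect_equal(enumerate_fragments("C", fragment_scheme("sequence", 2, 4)),
               integer())
})

test_that("triplet labels are canonical and counted once per combination", {
  # ethanol C1-C2-O3: orderings (C2,C1,O3) and (C2,O3,C1) give labels
  # C.C.O.1.1.2 and C.O.C.1.1.2; the lexicographic minimum is C.C.O.1.1.2
  out <- enumerate_fragments("CCO", fragment_scheme("triplet", 2, 2))
  expect_equal(out, c("C.C.O.1.1.2" = 1L))
  # propane: one triplet, two identical end atoms
  out2 <- enumerate_fragments("CCC", fragment_scheme("triplet", 2, 2))
  expect_equal(sum(out2), 1L)
})

test_that("fragment counts are invariant to SMILES atom ordering", {
  pairs <- list(c("CCO", "OCC"),
                c("CC(C)O", "OC(C)C"),
                c("CN(CCO)CCO", "OCCN(C)CCO"),
                c("CCN1CCC(O)C1", "OC1CCN(CC)C1"))
  for (sch in list(fragment_scheme("sequence", 2, 5),
                   fragment_scheme("atom_pair", 2, 6),
                   fragment_scheme("triplet", 2, 6))) {
    for (p in pairs) {
      a <- enumerate_fragments(p[1], sch)
      b <- enumerate_fragments(p[2], sch)
      expect_equal(a[order(names(a))], b[order(names(b))])
    }
  }
})

test_that("two-atom sequence counts equal the number of bonds", {
  smiles <- c("CCO", "CCN(CC)CC", "CN1CCCCC1", "c1ccccc1", "CC(=O)N(C)C")
  for (s in smiles) {
    g <- mol_graph(s)
    counts <- enumerate_fragments(s, fragment_scheme("sequence", 2, 2))
    expect_equal(sum(counts), nrow(g$bonds))
  }
})

test_that("sequence counts agree with a brute-force all-paths oracle", {
  smiles <- c("CCN(CC)CC", "CN1CCCCC1", "OCCN(CCO)CCO", "CC1CCC(O)CC1",
              "CSCCN(C)C", "c1ccncc1", "CC(O)CN1CCC(O)C1")
  for (s in smiles) {
    mine <- enumerate_fragments(s, fragment_scheme("sequence", 2, 6))
    oracle <- oracle_sequence_counts(s, 2, 6)
    expect_equal(mine[order(names(mine))], oracle[order(names(oracle))],
                 info = s)
  }
})

test_that("atoms_only coloration drops bond orders from labels", {
  ab <- enumerate_fragments("C=CC", fragment_scheme("sequence", 2, 2))
  ao <- enumerate_fragments("C=CC", fragment_scheme("sequence", 2, 2,
                                                    coloration = "atoms_only"))
  expect_setequal(names(ab), c("C-C", "C=C"))
  expect_equal(ao, c("C.C" = 2L))
})

test_that("build_matrix unions labels, fills zeros and prunes constants", {
  std <- tibble::tibble(id = c("eth", "meoh"), smiles_std = c("CCO", "CO"))
  m <- suppressMessages(build_matrix(std, fragment_scheme("sequence", 2, 2)))
  expect_equal(m$`C-C`, c(1, 0))
  # identical molecules prune to zero feature columns
  dup <- tibble::tibble(id = c("a", "b"), smiles_std = c("CCO", "CCO"))
  expect_message(m2 <- build_matrix(dup, fragment_scheme("sequence", 2, 2)),
                 "pruned")
  expect_equal(setdiff(names(m2), "id"), character())
  expect_error(build_matrix(std[0, ], fragment_scheme("sequence", 2, 2)),
               "empty")
})

test_that("concat_spaces prefixes names and enforces id alignment", {
  std <- tibble::tibble(id = c("a", "b"), smiles_std = c("CCO", "CCN(CC)CC"))
  f <- suppressMessages(build_matrix(std, fragment_scheme("sequence", 2, 3)))
  p <- build_matrix(std, default_property_provider(), prune = FALSE)
  merged <- concat_spaces(list(f, p))
  expect_equal(nrow(merged), 2)
  expect_equal(ncol(merged) - 1, (ncol(f) - 1) + (ncol(p) - 1))
  expect_identical(concat_spaces(list(f)), f)
  swapped <- p[c(2, 1), ]
  expect_error(concat_spaces(list(f, swapped)), "ids")
})

test_that("default property provider computes structural properties", {
  std <- standardize_library(tibble::tibble(id = "mpip", smiles = "CN1CCCCC1"))
  m <- build_matrix(std, default_property_provider(), prune = FALSE)
  expect_equal(m$ring_count, 1)
  expect_equal(m$heavy_atoms, 7)
  expect_equal(m$hbd, 0)
  expect_gt(m$mw, 99)
  # pKa passthrough requires the column
  expect_error(
    build_matrix(std, default_property_provider(pka_column = "pka"),
                 prune = FALSE),
    "pKa")
  std$pka <- 10.1
  m2 <- build_matrix(std, default_property_provider(pka_column = "pka"),
                     prune = FALSE)
  expect_equal(m2$pka, 10.1)
})

test_that("scheme validation rejects out-of-range parameters", {
  expect_error(fragment_scheme("sequence", 1, 3), "min_length")
  expect_error(fragment_scheme("sequence", 2, 9), "max_length")
  expect_error(fragment_scheme("sequence", 4, 3), "max_length")
})
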