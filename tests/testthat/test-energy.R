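test_that("unpaired input has zero free energy", {
  expect_identical(energy("AAAAAA", NULL), 0)
  expect_identical(energy("ACGUACGU", matrix(integer(0), 0, 2)), 0)
})

test_that("adding a stacked GC/GC pair strictly lowers the energy", {
  # 4-bp GC stem vs the same hairpin with one more stacked GC pair
  e4 <- energy("GGGGAAAAACCCC", cbind(0:3, 12:9))
  e5 <- energy("GGGGGAAAAACCCCC", cbind(0:4, 14:10))
  expect_lt(e5, e4)
  # holds along a ladder of stem lengths
  prev <- e4
  for (k in 5:8) {
    seq <- paste0(strrep("G", k), "AAAAA", strrep("C", k))
    cur <- energy(seq, cbind(0:(k - 1), (2 * k + 4):(k + 5)))
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("energies of disjoint stems are additive", {
  set.seed(31)
  for (k in 1:10) {
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    h1 <- paste0(strrep("G", n1), "AAAAA", strrep("C", n1))
    h2 <- paste0(strrep("C", n2), "AAAA", strrep("G", n2))
    p1 <- cbind(0:(n1 - 1), (2 * n1 + 4):(n1 + 5))
    p2 <- cbind(0:(n2 - 1), (2 * n2 + 3):(n2 + 4)) + nchar(h1)
    joint <- energy(paste0(h1, h2), rbind(p1, p2))
    expect_equal(joint, energy(h1, p1 - 0L) + energy(h2, p2 - nchar(h1)), tolerance = 1e-9)
  }
})

test_that("hairpin loops shorter than 3 nt are structurally impossible", {
  expect_identical(energy("GGGACCC", cbind(0:2, 6:4)), Inf)
})

test_that("malformed pairing maps raise structural errors", {
  expect_error(energy("ACGU", cbind(0L, 9L)), "outside the sequence")
  expect_error(energy("GGGAAACCC", rbind(c(0L, 8L), c(0L, 7L))), "paired twice")
  expect_error(energy("GGGAAACCC", rbind(c(0L, 5L), c(2L, 8L))), "crossing")
  expect_error(energy("GAGAAACUC", cbind(0L, 5L)), "not a canonical")
})

test_that("fixed-structure energies agree with the frozen reference foldings", {
  # 20 candidate-like structures; reference values computed once with a
  # reference folding program constrained to the same structure and frozen
  for (case in energy_fixture_cases) {
    mine <- energy(case$seq, db_pairs(case$db))
    expect_lt(abs(mine - case$ref), 2.0)
    expect_identical(sign(mine), sign(case$ref))
  }
})
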