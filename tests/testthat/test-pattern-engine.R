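test_that("the pattern dialect parses rules, segments, backrefs and alternations", {
  spec <- parse_pattern(
    "r1={au,ua,gc,cg,gu,ug} p1=3...10 GAA p2=3...6 3...19 r1~p2[0,1,1] A r1~p1[1,1,1]"
  )
  kinds <- vapply(spec$elements, function(e) e$kind, character(1))
  expect_identical(kinds, c(
    "segment", "literal", "segment", "segment",
    "backref", "literal", "backref"
  ))
  expect_identical(spec$elements[[1]]$name, "p1")
  expect_identical(c(spec$elements[[1]]$min, spec$elements[[1]]$max), c(3L, 10L))
  expect_true(is.na(spec$elements[[4]]$name)) # anonymous 3...19
  br <- spec$elements[[5]]
  expect_identical(c(br$m, br$d, br$i), c(0L, 1L, 1L))
  expect_identical(br$segment, "p2")
  # the pairing rule is the ordered wobble-inclusive set
  r1 <- spec$rules$r1
  expect_true(all(r1[cbind(c("A", "U", "G", "C", "G", "U"), c("U", "A", "C", "G", "U", "G"))]))
  expect_false(r1["A", "A"])
  expect_false(r1["A", "G"])

  expect_identical(parse_pattern("GAA")$elements[[1]]$kind, "literal")
  expect_error(parse_pattern("r1~p9[0,0,0]"), "undeclared")
  expect_error(parse_pattern("r1={au} r2~p1[0,0,0]"), "parse error")
  expect_error(parse_pattern("p1=10...3"), "min_len")
})

test_that("match_all finds literal and strict/wobble reverse-complement stems", {
  m <- match_all(parse_pattern("GAA"), "UGAAC")
  expect_length(m, 1)
  expect_identical(c(m[[1]]$start, m[[1]]$end), c(1L, 4L))

  spec <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=3...3 r1~p1[0,0,0]")
  m <- match_all(spec, "GACGUC")
  expect_length(m, 1)
  expect_identical(m[[1]]$bindings$p1$string, "GAC")
  expect_identical(to_dot_bracket(m[[1]]), "((()))")

  # wobble G.U pairs are permitted by r1, so GUU also partners GAC
  m <- match_all(spec, "GACGUU")
  expect_length(m, 1)
  expect_identical(m[[1]]$bindings$p1$string, "GAC")
  expect_identical(m[[1]]$backrefs[[2]]$mismatches, 0L)
})

test_that("adjacent backrefs pair with the immediately following substring", {
  # with segment and backref adjacent there is no room for a loop: GGGG
  # would have to pair with AAAA, which fails even with one mismatch
  # allowed (verified against the exhaustive reference enumerator)
  spec <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=4...4 r1~p1[1,0,0]")
  expect_length(match_all(spec, "GGGGAAAACCCA"), 0)
  expect_length(match_all_naive(spec, "GGGGAAAACCCA"), 0)

  # an intervening 4-nt loop lets GGGG pair with CCCA (one non-pairing
  # position consuming the mismatch budget)
  spec2 <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=4...4 4...4 r1~p1[1,0,0]")
  m <- match_all(spec2, "GGGGAAAACCCA")
  expect_length(m, 1)
  expect_identical(m[[1]]$bindings$p1$string, "GGGG")
  expect_identical(m[[1]]$backrefs[[3]]$mismatches, 1L)
  expect_identical(match_keys(m), match_keys(match_all_naive(spec2, "GGGGAAAACCCA")))
})

test_that("indel budgets shorten or lengthen the stem partner", {
  # deletion: partner one shorter than the segment
  spec_d <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=4...4 3...3 r1~p1[0,1,0]")
  m <- match_all(spec_d, "GGGGAAACCC")
  expect_true(any(vapply(m, function(x) {
    x$bindings$p1$string == "GGGG" && (x$intervals[3, 2] - x$intervals[3, 1]) == 3
  }, logical(1))))
  # insertion: partner one longer
  spec_i <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=3...3 3...3 r1~p1[0,0,1]")
  m <- match_all(spec_i, "GGGAAACCCC")
  expect_true(any(vapply(m, function(x) {
    x$bindings$p1$string == "GGG" && (x$intervals[3, 2] - x$intervals[3, 1]) == 4
  }, logical(1))))
})

test_that("matcher equals the exhaustive enumerator on random sequences", {
  set.seed(101)
  pats <- truncated_patterns()
  for (k in 1:40) {
    seq <- random_rna(sample(20:60, 1), gc = stats::runif(1, 0.3, 0.7))
    for (spec in pats) {
      expect_identical(match_keys(match_all(spec, seq)), match_keys(match_all_naive(spec, seq)))
    }
  }
})

test_that("enlarging any backref budget never removes a match", {
  set.seed(202)
  base_text <- "r1={au,ua,gc,cg,gu,ug} p1=3...5 2...6 r1~p1[%d,%d,%d]"
  for (k in 1:25) {
    seq <- random_rna(sample(15:40, 1))
    base <- match_keys(match_all(parse_pattern(sprintf(base_text, 0, 0, 0)), seq))
    for (budget in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 1, 1))) {
      wider <- match_keys(match_all(
        parse_pattern(sprintf(base_text, budget[1], budget[2], budget[3])), seq
      ))
      expect_true(all(base %in% wider))
    }
  }
})

test_that("match output is deterministic and ordered by start", {
  set.seed(303)
  spec <- truncated_patterns()$eSECIS_I
  seq <- random_rna(60)
  a <- match_all(spec, seq)
  b <- match_all(spec, seq)
  expect_identical(match_keys(a), match_keys(b))
  starts <- vapply(a, function(m) m$start, integer(1))
  expect_true(!is.unsorted(starts))
})

test_that("sequence N matches pattern N but never a pairing rule", {
  expect_length(match_all(parse_pattern("GNA"), "GNA"), 1)
  expect_length(match_all(parse_pattern("GCA"), "GNA"), 0)
  spec <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=3...3 r1~p1[0,0,0]")
  expect_length(match_all(spec, "GNCGUC"), 0)
})

test_that("dot-bracket renders paired positions and leaves budget positions unpaired", {
  spec <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=4...4 4...4 r1~p1[1,0,0]")
  # the one non-pairing column (5'-most G against the trailing A) stays
  # unpaired; the three pairing columns are bracketed
  m <- match_all(spec, "GGGGAAAACCCA")[[1]]
  expect_identical(to_dot_bracket(m), ".(((....))).")
  lit <- match_all(parse_pattern("GAAA"), "GAAA")[[1]]
  expect_identical(to_dot_bracket(lit), "....")
})
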