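test_that("the built-in patterns encode the three structural models", {
  pats <- builtin_patterns()
  expect_named(pats, c("eSECIS_I", "eSECIS_II", "eaSECIS"))

  t1 <- pats$eSECIS_I
  expect_identical(t1$elements[[1]]$chars, "NNGAN")
  expect_identical(c(t1$elements[[3]]$min, t1$elements[[3]]$max), c(8L, 20L))
  expect_identical(c(t1$elements[[2]]$min, t1$elements[[2]]$max), c(7L, 15L))
  expect_identical(t1$elements[[4]]$kind, "backref")
  expect_identical(sort(t1$elements[[5]]$branches), c("NAANN", "NGANN"))

  t2 <- pats$eSECIS_II
  expect_length(t2$elements, 9)
  expect_identical(c(t2$elements[[2]]$min, t2$elements[[2]]$max), c(6L, 14L))
  expect_identical(c(t2$elements[[4]]$min, t2$elements[[4]]$max), c(2L, 8L))

  ea <- pats$eaSECIS
  expect_identical(ea$elements[[2]]$chars, "GAA")
  last <- ea$elements[[length(ea$elements)]]
  expect_identical(last$segment, "p1")
  expect_identical(c(last$m, last$d, last$i), c(1L, 1L, 1L))
})

test_that("the worked type I structure validates and boundary violations are reported", {
  cand <- candidate_from_seq(worked_type1_string(), "eSECIS_I")
  expect_identical(cand$core5, "AUGA")
  expect_identical(cand$core3, "GA")
  expect_identical(cand$upper_stem_len, 7L)
  expect_identical(nchar(cand$apical_loop), 8L)
  v <- validate_candidate(cand)
  expect_true(v$accept)
  expect_length(v$reasons, 0)

  # loop shortened below the model range
  short <- cand
  short$apical_loop <- substr(cand$apical_loop, 1, 7)
  v <- validate_candidate(short)
  expect_false(v$accept)
  expect_match(v$reasons, "apical loop 8-20", all = FALSE)

  # stem mismatch budget exceeded
  noisy <- cand
  noisy$upper_stem_mismatches <- 3L
  v <- validate_candidate(noisy)
  expect_false(v$accept)
  expect_match(v$reasons, "mismatches <=2", all = FALSE)
})

test_that("scan_window recovers planted elements and rejects structureless input", {
  set.seed(71)
  cfg <- sim_config(stem_gc = 1.0)
  for (cls in c("eSECIS_I", "eSECIS_II", "eaSECIS")) {
    pl <- plant_in_window(cls, cfg)
    cands <- scan_window(pl$window)
    hit <- Filter(function(x) {
      x$model_class == cls && x$start < pl$end && x$end > pl$start
    }, cands)
    expect_gt(length(hit), 0)
  }
  expect_length(scan_window(strrep("A", 630)), 0)
})

test_that("every scan_window candidate passes validation and the energy filter", {
  set.seed(72)
  cfg <- sim_config(stem_gc = 0.9)
  for (k in 1:6) {
    cls <- sample(c("eSECIS_I", "eSECIS_II", "eaSECIS"), 1)
    pl <- plant_in_window(cls, cfg)
    for (cand in scan_window(pl$window)) {
      expect_true(validate_candidate(cand)$accept)
      expect_lt(cand$dG, -5.0)
      expect_equal(cand$dG, energy(pl$window, cand$pairs), tolerance = 1e-9)
    }
  }
})

test_that("canonical euryarchaeal features are flagged from the pairing list", {
  set.seed(73)
  cfg <- sim_config(stem_gc = 1.0)
  pl <- plant_in_window("eaSECIS", cfg)
  cands <- scan_window(pl$window,
    models = secis_models()["eaSECIS"],
    patterns = builtin_patterns()["eaSECIS"]
  )
  hit <- Filter(function(x) x$start < pl$end && x$end > pl$start, cands)
  expect_gt(length(hit), 0)
  flags <- classify_euryarchaeal(hit[[1]])
  # all-GC upper stems of >= 3 bp always carry an S-S triplet
  expect_true(flags$has_SS_triplet)

  # brute-force flag over the pairing list agrees
  brute_ss <- function(cand) {
    prs <- cand$upper_stem_pairs
    s <- strsplit(cand$sequence, "")[[1]]
    if (is.null(prs) || nrow(prs) < 3) {
      return(FALSE)
    }
    prs <- prs[order(prs[, 1]), , drop = FALSE]
    for (a in 1:(nrow(prs) - 2)) {
      win <- prs[a:(a + 2), , drop = FALSE]
      bases <- s[c(win[, 1], win[, 2]) - cand$start + 1]
      if (all(bases %in% c("C", "G"))) {
        return(TRUE)
      }
    }
    FALSE
  }
  set.seed(74)
  cfg_mixed <- sim_config(stem_gc = 0.5)
  for (k in 1:12) {
    pl <- plant_in_window("eaSECIS", cfg_mixed)
    for (cand in scan_window(pl$window,
      models = secis_models()["eaSECIS"],
      patterns = builtin_patterns()["eaSECIS"]
    )) {
      expect_identical(classify_euryarchaeal(cand)$has_SS_triplet, brute_ss(cand))
    }
  }
})

test_that("core-motif variants are read from the bulge-flanking context", {
  cand <- candidate_from_seq(worked_type1_string(), "eSECIS_I")
  expect_identical(classify_euryarchaeal(cand)$core_motif, "AUGA_GA")
  gu <- cand
  gu$core5 <- "GUGA"
  expect_identical(classify_euryarchaeal(gu)$core_motif, "GUGA_GA")
  other <- cand
  other$core5 <- "CCGA"
  expect_identical(classify_euryarchaeal(other)$core_motif, "other")
})

test_that("composition profiles count aligned positions and normalise columns", {
  mk <- function(core5, core3, run) {
    structure(
      list(model_class = "eSECIS_I", core5 = core5, core3 = core3, adenine_run = run),
      class = "secis_candidate"
    )
  }
  prof <- composition_profiles(list(mk("AUGA", "GA", "AAAAA"), mk("GUGA", "GA", "AAAAA")), "core")
  expect_equal(unname(prof$freq["A", 1]), 0.5)
  expect_equal(unname(prof$freq["G", 1]), 0.5)
  expect_equal(unname(prof$freq["U", 2]), 1)
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-9))

  loops <- composition_profiles(
    replicate(100, mk("AUGA", "GA", "AAAAA"), simplify = FALSE),
    "apical_adenines"
  )
  expect_true(all(loops$freq["A", ] == 1))

  empty <- composition_profiles(list(), "core")
  expect_true(empty$empty)
  expect_true(all(empty$counts == 0))
  expect_true(all(is.na(empty$freq)))
})

test_that("type I and type II reported on one locus are flagged as coexisting", {
  # a type II element is also matched by the looser type I pattern when its
  # ministem sits inside the 8-20 nt apical range; scan both models
  set.seed(75)
  cfg <- sim_config(stem_gc = 1.0)
  found <- FALSE
  for (k in 1:20) {
    pl <- plant_in_window("eSECIS_II", cfg)
    cands <- scan_window(pl$window)
    cls <- vapply(cands, function(x) x$model_class, character(1))
    co <- vapply(cands, function(x) isTRUE(x$coexisting), logical(1))
    if (any(co[cls == "eSECIS_I"]) && any(co[cls == "eSECIS_II"])) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
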