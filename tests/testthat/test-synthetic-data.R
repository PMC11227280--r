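test_that("simulation output is byte-identical under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_genome(sim_config(seed = 7), out_dir = d1)
  simulate_genome(sim_config(seed = 7), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  simulate_genome(sim_config(seed = 8), out_dir = d3)
  expect_false(identical(
    readLines(file.path(d1, "synth1.fasta")),
    readLines(file.path(d3, "synth1.fasta"))
  ))
})

test_that("every planted SECIS re-validates under its own model", {
  sim <- simulate_genome(sim_config(seed = 3, secis_mix = c(eSECIS_I = 1, eSECIS_II = 1, eaSECIS = 1)))
  secis <- sim$truth[sim$truth$kind == "secis", ]
  expect_gt(nrow(secis), 0)
  for (k in seq_len(nrow(secis))) {
    row <- secis[k, ]
    g <- secisscan:::contig_seq(sim$genome, row$contig_id)
    el <- substr(g, row$start + 1L, row$end)
    if (row$strand == "-") el <- dna_revcomp(el)
    cands <- scan_window(chartr("T", "U", el),
      models = secis_models()[row$secis_class],
      patterns = builtin_patterns()[row$secis_class]
    )
    expect_gt(length(cands), 0)
    expect_true(any(vapply(cands, function(x) validate_candidate(x)$accept, logical(1))))
  }
})

test_that("every planted gene re-translates with Sec at the declared codon", {
  sim <- simulate_genome(sim_config(seed = 4))
  genes <- sim$truth[sim$truth$kind == "gene", ]
  expect_gt(nrow(genes), 0)
  for (k in seq_len(nrow(genes))) {
    row <- genes[k, ]
    g <- secisscan:::contig_seq(sim$genome, row$contig_id)
    cds <- substr(g, row$start + 1L, row$end)
    if (row$strand == "-") cds <- dna_revcomp(cds)
    prot <- translate_readthrough(cds, 0, TRUE)
    qid <- grep(paste0("^", row$label, "\\|"), names(sim$queries), value = TRUE)
    expect_true(prot %in% sim$queries[qid])
    # the declared Sec codon reads TGA on the coding strand
    codon <- substr(g, row$sec_codon_start + 1L, row$sec_codon_end)
    if (row$strand == "-") codon <- dna_revcomp(codon)
    expect_identical(codon, "TGA")
    # and maps onto the U of the protein
    sec_off <- if (row$strand == "+") {
      (row$sec_codon_start - row$start) / 3 + 1
    } else {
      (row$end - row$sec_codon_end) / 3 + 1
    }
    expect_identical(substr(prot, sec_off, sec_off), "U")
  }
})

test_that("co-planted hdrA-frhD pairs are adjacent and detectable", {
  sim <- simulate_genome(sim_config(seed = 5, operon_gap = 20L))
  pairs <- detect_operon_pairs(sim$annotations)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$gap, 20L)
  expect_identical(sort(c(pairs$label1, pairs$label2)), c("frhD", "hdrA"))
  # gaps beyond the configured maximum are not reported
  expect_identical(nrow(detect_operon_pairs(sim$annotations, max_gap_nt = 10L)), 0L)
})

test_that("infeasible packing raises a capacity error", {
  expect_error(
    simulate_genome(sim_config(seed = 1, n_contigs = 1L, contig_length = 900L)),
    "capacity error"
  )
})

test_that("dinucleotide shuffling preserves composition and is seed-stable", {
  set.seed(55)
  seqs <- c(a = secisscan:::random_dna(400, 0.45), b = secisscan:::random_dna(630, 0.6))
  sh1 <- shuffle_negative_controls(seqs, seed = 9)
  sh2 <- shuffle_negative_controls(seqs, seed = 9)
  expect_identical(sh1, sh2)
  expect_false(identical(sh1, seqs))
  dinucs <- function(s) {
    v <- strsplit(s, "")[[1]]
    table(paste0(v[-length(v)], v[-1]))
  }
  for (nm in names(seqs)) {
    expect_identical(nchar(sh1[[nm]]), nchar(seqs[[nm]]))
    expect_identical(
      table(strsplit(sh1[[nm]], "")[[1]]),
      table(strsplit(seqs[[nm]], "")[[1]])
    )
    expect_identical(dinucs(sh1[[nm]]), dinucs(seqs[[nm]]))
  }
})

test_that("shuffling destroys planted SECIS structure", {
  set.seed(56)
  cfg <- sim_config(stem_gc = 1.0)
  locus_recall <- function(window, cls, lo, hi) {
    any(vapply(scan_window(window), function(x) {
      x$model_class == cls && x$start < hi && x$end > lo
    }, logical(1)))
  }
  planted_hits <- 0L
  shuffled_hits <- 0L
  n <- 15L
  for (k in seq_len(n)) {
    cls <- c("eSECIS_I", "eSECIS_II", "eaSECIS")[1L + (k %% 3L)]
    pl <- plant_in_window(cls, cfg)
    planted_hits <- planted_hits + locus_recall(pl$window, cls, pl$start, pl$end)
    shuf <- shuffle_negative_controls(chartr("U", "T", pl$window), seed = k)
    shuffled_hits <- shuffled_hits + locus_recall(shuf[[1]], cls, pl$start, pl$end)
  }
  expect_identical(planted_hits, n)
  # the shuffle preserves composition but destroys the planted structure:
  # recall at the planted locus collapses
  expect_lte(shuffled_hits, n %/% 2L)
})
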