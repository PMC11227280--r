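aln_line <- function(qseqid = "SelD|q1", sseqid = "c1", pident = 100, len = 3,
                     mism = 0, gapopen = 0, qstart = 1, qend = 3, sstart = 10,
                     send = 18, evalue = 1e-20, bitscore = 50, qlen = 3,
                     slen = 60, qseq = "MKU", sseq = "MK*") {
  paste(
    qseqid, sseqid, pident, len, mism, gapopen, qstart, qend, sstart, send,
    evalue, bitscore, qlen, slen, qseq, sseq,
    sep = "\t"
  )
}

test_that("tabular alignments parse with strand decoding and threshold flags", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    aln_line(),
    aln_line(sstart = 60, send = 52, evalue = 0.5)
  ), p)
  aln <- read_tabular_alignments(p)
  expect_identical(nrow(aln), 2L)
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$below_threshold, c(FALSE, TRUE))

  writeLines(substr(aln_line(), 1, 30), p)
  expect_error(read_tabular_alignments(p), "row 1")

  # plain 12-column outfmt 6 lacks the aligned sequence strings
  writeLines(paste(strsplit(aln_line(), "\t")[[1]][1:12], collapse = "\t"), p)
  expect_error(read_tabular_alignments(p), "dialect lacks qseq/sseq")
})

test_that("Sec/TGA pairs are verified against the genome on both strands", {
  genome <- c(c1 = paste0("AAAAAAAAA", "ATGAAATGA", "CCCCCC"))
  rec <- list(
    qseqid = "q", sseqid = "c1", qstart = 1L, sstart = 10L, send = 18L,
    qseq = "MKU", sseq = "MK*"
  )
  prs <- find_sec_tga_pairs(rec, genome)
  expect_identical(nrow(prs), 1L)
  expect_identical(c(prs$codon_start, prs$codon_end), c(16L, 18L))
  expect_identical(prs$query_sec_pos, 3L)

  # the aligned stop is TAA, not TGA: no Sec/TGA pair
  genome_taa <- c(c1 = paste0("AAAAAAAAA", "ATGAAATAA", "CCCCCC"))
  expect_identical(nrow(find_sec_tga_pairs(rec, genome_taa)), 0L)

  # query U over a subject gap column is skipped
  rec_gap <- within(rec, {
    qseq <- "MKU"
    sseq <- "MK-"
  })
  expect_identical(nrow(find_sec_tga_pairs(rec_gap, genome)), 0L)

  # minus strand: same gene cassette reverse-complemented
  fwd <- "ATGAAATGAGGGTAA"
  genome_rc <- c(c1 = paste0("GGGGG", dna_revcomp(fwd), "TTTTT"))
  rec_rc <- list(
    qseqid = "q", sseqid = "c1", qstart = 1L,
    sstart = 5L + nchar(fwd), send = 5L + nchar(fwd) - 8L,
    qseq = "MKU", sseq = "MK*"
  )
  prs <- find_sec_tga_pairs(rec_rc, genome_rc)
  expect_identical(nrow(prs), 1L)
  expect_identical(prs$strand, "-")
  cd <- dna_revcomp(substr(genome_rc[["c1"]], prs$codon_start, prs$codon_end))
  expect_identical(cd, "TGA")
})

test_that("ORF extension reads through TGA and honours start/stop bounds", {
  genome <- c(c1 = "CCCATGAAATGAGGGTAACCC")
  orf <- extend_orf(genome, codon_start = 10L, strand = "+", contig_id = "c1")
  expect_identical(orf$protein, "MKUG")
  expect_identical(c(orf$orf_start, orf$orf_end), c(4L, 18L))
  expect_false(orf$start_missing)
  expect_false(orf$stop_missing)

  # no upstream start in frame: flagged, ORF begins at the bound
  genome2 <- c(c1 = "CCCCCCAAATGAGGGTAA")
  orf <- extend_orf(genome2, codon_start = 10L, strand = "+", contig_id = "c1")
  expect_true(orf$start_missing)
  expect_identical(substr(orf$protein, nchar(orf$protein) - 1, nchar(orf$protein)), "UG")

  # minus strand mirror of the first case
  genome3 <- c(c1 = dna_revcomp("CCCATGAAATGAGGGTAACCC"))
  L <- nchar(genome3[["c1"]])
  orf <- extend_orf(genome3, codon_start = L - 11L, strand = "-", contig_id = "c1")
  expect_identical(orf$protein, "MKUG")

  expect_error(extend_orf(genome, codon_start = 4L, strand = "+", contig_id = "c1"), "no TGA")
})

test_that("family labels derive from queries; duplicates merge; short proteins flagged", {
  hits <- data.frame(
    contig_id = c("c1", "c1", "c2"),
    codon_start = c(100L, 100L, 7L), codon_end = c(102L, 102L, 9L),
    strand = c("+", "+", "-"),
    query_id = c("SelD|a", "SelD|b", "PrxL|a"),
    protein = c(strrep("A", 40), strrep("A", 40), strrep("A", 30)),
    stringsAsFactors = FALSE
  )
  out <- assign_family(hits)
  expect_identical(nrow(out), 2L)
  expect_identical(out$family, c("SelD", "PrxL"))
  merged <- out[out$contig_id == "c1", ]
  expect_identical(merged$n_support, 2L)
  expect_identical(merged$supports, "SelD|a,SelD|b")
  expect_identical(out$short, c(FALSE, TRUE))
})

test_that("the two-part trait criterion and its strict-tRNA variant are exact", {
  full <- c("SecS", "EFSec", "PSTK", "SelD", "tRNA-Sec")
  expect_identical(classify_sec_trait(full, 1)$verdict, "Sec+")
  expect_identical(classify_sec_trait(c("SecS", "EFSec"), 3)$verdict, "Sec-")
  expect_identical(classify_sec_trait(full, 0)$verdict, "Sec-")

  # exhaustive truth table: 2^5 machinery subsets x {0,1,2} selenoproteins
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(combos) <- full
  for (r in seq_len(nrow(combos))) {
    present <- full[unlist(combos[r, ])]
    for (nsel in 0:2) {
      expected <- if (length(present) >= 3 && nsel >= 1) "Sec+" else "Sec-"
      expect_identical(classify_sec_trait(present, nsel)$verdict, expected)
      strict_expected <- if (length(present) >= 3 && nsel >= 1 && "tRNA-Sec" %in% present) {
        "Sec+"
      } else {
        "Sec-"
      }
      strict <- classify_sec_trait(present, nsel, strict_trna = TRUE)$verdict
      expect_identical(strict, strict_expected)
    }
  }
})

test_that("operon pairs require both labels, one strand, and a short gap", {
  ann <- gene_annotation(
    contig_id = "c1", start = c(99L, 1029L), end = c(999L, 1599L),
    strand = "+", gene_id = c("g1", "g2"), product_label = c("hdrA", "frhD")
  )
  pairs <- detect_operon_pairs(ann)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$gap, 30L)

  opposite <- ann
  opposite$strand <- c("+", "-")
  expect_identical(nrow(detect_operon_pairs(opposite)), 0L)

  distant <- ann
  distant$start[2] <- 1499L
  distant$end[2] <- 2099L
  expect_identical(nrow(detect_operon_pairs(distant)), 0L)
})

test_that("operon detection equals a brute-force all-pairs scan", {
  brute <- function(ann, labels = c("hdrA", "frhD"), max_gap = 60L) {
    found <- 0L
    ann <- as.data.frame(ann)
    for (a in seq_len(nrow(ann))) {
      for (b in seq_len(nrow(ann))) {
        if (a == b) next
        x <- ann[a, ]
        y <- ann[b, ]
        if (x$contig_id != y$contig_id || x$strand != y$strand) next
        if (x$start >= y$start) next
        if (!setequal(c(x$product_label, y$product_label), labels)) next
        if (y$start - x$end > max_gap) next
        # adjacency: no same-strand gene starts between them
        between <- ann$contig_id == x$contig_id & ann$strand == x$strand &
          ann$start > x$start & ann$start < y$start
        if (any(between)) next
        found <- found + 1L
      }
    }
    found
  }
  set.seed(91)
  labels_pool <- c("hdrA", "frhD", "selD", "frhA", NA)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    starts <- sort(sample(seq(0, 5000, by = 10), n))
    ends <- starts + sample(seq(60, 300, by = 3), n, replace = TRUE)
    ends <- pmin(ends, c(starts[-1], 6000L) - 1L)
    keep <- ends > starts & (ends - starts) %% 3 == 0
    if (!any(keep)) next
    ann <- gene_annotation(
      contig_id = sample(c("c1", "c2"), sum(keep), replace = TRUE),
      start = starts[keep], end = ends[keep],
      strand = sample(c("+", "-"), sum(keep), replace = TRUE),
      gene_id = paste0("g", seq_len(sum(keep))),
      product_label = sample(labels_pool, sum(keep), replace = TRUE)
    )
    expect_identical(nrow(detect_operon_pairs(ann)), brute(ann))
  }
})

test_that("six-frame local alignment recovers identity and strand", {
  set.seed(92)
  prot <- "MKLVEEGAUCDWHKNRSTYFPQ"
  cds <- secisscan:::reverse_translate(prot)
  genome <- c(c1 = paste0(
    secisscan:::random_dna(90, 0.5), cds,
    secisscan:::random_dna(60, 0.5)
  ))
  rec <- local_align_protein_vs_sixframe(prot, genome, query_id = "Fam|x")
  expect_identical(rec$strand, "+")
  expect_false(grepl("-", rec$qseq, fixed = TRUE))
  expect_identical(rec$qseq, prot)
  expect_identical(chartr("*", "U", rec$sseq), prot)
  # subject coordinates point at the CDS (minus its stop codon)
  expect_identical(rec$sstart, 91L)
  expect_identical(rec$send, 90L + 3L * nchar(prot))

  # reverse-strand placement gives a minus alignment with the same content
  genome_rc <- c(c1 = dna_revcomp(genome[["c1"]]))
  rec_rc <- local_align_protein_vs_sixframe(prot, genome_rc, query_id = "Fam|x")
  expect_identical(rec_rc$strand, "-")
  expect_gt(rec_rc$sstart, rec_rc$send)
  expect_identical(rec_rc$qseq, prot)
})

test_that("self-alignment scores dominate shuffled-query scores", {
  set.seed(93)
  prot <- "MSEKVLILAGHSNKALEAVRGLEPGDUAVIVTDRPE"
  cds <- secisscan:::reverse_translate(prot)
  genome <- c(c1 = paste0(
    secisscan:::random_dna(50, 0.5), cds,
    secisscan:::random_dna(50, 0.5)
  ))
  self_score <- local_align_protein_vs_sixframe(prot, genome)$bitscore
  for (k in 1:50) {
    shuffled <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    expect_gte(self_score, local_align_protein_vs_sixframe(shuffled, genome)$bitscore)
  }
})
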