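test_that("FASTA reading normalises U/lowercase and rejects malformed records", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">a", p)
  cat(">a\nACGU\n", file = p)
  rec <- read_fasta(p)
  expect_identical(as.character(rec[["a"]]), "ACGT")

  cat(">a\nacgt\n>b\nNNN\n", file = p)
  rec <- read_fasta(p)
  expect_identical(unname(as.character(rec)), c("ACGT", "NNN"))
  expect_identical(names(rec), c("a", "b"))

  cat(">a\n\n", file = p)
  expect_error(read_fasta(p), "empty sequence")
  cat(">a\nACGT\n>a\nACGT\n", file = p)
  expect_error(read_fasta(p), "duplicated")
})

test_that("3'-UTR windows follow the -30/+600 convention with boundary clamps", {
  genome <- Biostrings::DNAStringSet(c(ctg = paste(rep("ACGT", 500), collapse = "")))
  gene_plus <- list(contig_id = "ctg", start = 100L, end = 400L, strand = "+")
  w <- extract_utr3_window(genome, gene_plus)
  expect_identical(c(w$genomic_start, w$genomic_end), c(370L, 1000L))
  expect_identical(nchar(w$sequence), 630L)
  expect_identical(w$offset_of_stop, 30L)

  gene_minus <- list(contig_id = "ctg", start = 100L, end = 400L, strand = "-")
  w <- extract_utr3_window(genome, gene_minus)
  expect_identical(c(w$genomic_start, w$genomic_end), c(0L, 130L))
  expect_identical(nchar(w$sequence), 130L)

  gene_at_end <- list(contig_id = "ctg", start = 1700L, end = 2000L, strand = "+")
  w <- extract_utr3_window(genome, gene_at_end)
  expect_identical(nchar(w$sequence), 30L)

  bad <- list(contig_id = "ctg", start = 1990L, end = 2300L, strand = "+")
  expect_error(extract_utr3_window(genome, bad), "coordinate error")
})

test_that("windows are strand-consistent under genome reverse complement", {
  set.seed(11)
  for (k in 1:10) {
    len <- 500L
    seq <- secisscan:::random_dna(len, 0.5)
    s <- sample(50:300, 1)
    e <- s + 3L * sample(10:40, 1)
    w_plus <- extract_utr3_window(seq, list(contig_id = NULL, start = s, end = e, strand = "+"))
    # mirrored gene on the reverse-complemented genome
    w_mirror <- extract_utr3_window(
      dna_revcomp(seq),
      list(contig_id = NULL, start = len - e, end = len - s, strand = "-")
    )
    expect_identical(w_plus$sequence, w_mirror$sequence)
  }
})

test_that("read-through translation decodes TGA as Sec and keeps TAA/TAG as stops", {
  expect_identical(translate_readthrough("ATGTGATAA", 0, TRUE), "MU")
  expect_identical(translate_readthrough("ATGTGATAA", 0, FALSE), "M")
  expect_identical(translate_readthrough("ATGNNNTGA", 0, TRUE), "MXU")
  expect_identical(translate_readthrough("CATGAAA", 1, TRUE), "MK")
  # without TGA, read-through equals standard translation
  set.seed(13)
  for (k in 1:20) {
    nt <- paste(sample(names(secisscan:::GENETIC_CODE_TABLE)[
      !names(secisscan:::GENETIC_CODE_TABLE) %in% c("TGA", "TAA", "TAG")
    ], 12, replace = TRUE), collapse = "")
    expect_identical(
      translate_readthrough(nt, 0, TRUE),
      translate_readthrough(nt, 0, FALSE)
    )
  }
})

test_that("reports round-trip through TSV, JSON and BED", {
  df <- data.frame(
    contig_id = c("c1", "c2"), start = c(10L, 40L), end = c(30L, 90L),
    name = c("eSECIS_I", "eaSECIS"), score = c(0L, 0L), strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_report(df, tsv, "tsv")
  expect_identical(read_report(tsv, "tsv"), df)
  write_report(df, js, "json")
  expect_identical(read_report(js, "json"), df)
  write_report(df, bed, "bed")
  back <- read_report(bed, "bed")
  expect_identical(back$start, df$start)
  expect_identical(back$name, df$name)
  # empty collection: header-only TSV
  write_report(df[0, ], tsv, "tsv")
  expect_identical(nrow(read_report(tsv, "tsv")), 0L)
  expect_identical(names(read_report(tsv, "tsv")), names(df))
})

test_that("GFF3 round-trips annotations with product labels and coordinates", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 300)))
  ann <- gene_annotation(
    contig_id = c("c1", "c1"), start = c(99L, 600L), end = c(399L, 693L),
    strand = c("+", "-"), gene_id = c("g1", "g2"),
    product_label = c("selD", "tRNA-Sec"), coding = c(TRUE, FALSE),
    genome = genome
  )
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, p)
  back <- read_gff3(p, genome)
  expect_identical(back$start, ann$start)
  expect_identical(back$end, ann$end)
  expect_identical(back$strand, ann$strand)
  expect_identical(back$product_label, ann$product_label)
  expect_identical(back$coding, ann$coding)
})

test_that("annotation invariants are enforced", {
  expect_error(
    gene_annotation("c", 10L, 10L, "+", "g"),
    "start < end"
  )
  expect_error(
    gene_annotation("c", 0L, 10L, "+", "g", coding = TRUE),
    "multiple of 3"
  )
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  expect_error(
    gene_annotation("c1", 0L, 12L, "+", "g", genome = genome),
    "beyond contig"
  )
})
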