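#' @importFrom Biostrings readBStringSet readAAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement AAStringSet
#' @importFrom methods as is
#' @importFrom utils read.delim write.table
NULL

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read genome sequences from FASTA
#'
#' Sequences are stored internally in the DNA alphabet: input is uppercased
#' and `U` is mapped to `T`; anything outside `{A,C,G,T,N}` is rejected.
#' Record ids (first whitespace-delimited word of the header) must be unique
#' and every record must be non-empty.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  widths <- nchar(seqs)
  if (any(widths == 0L)) {
    k <- which(widths == 0L)[1]
    line <- fasta_header_line(path, ids[k])
    stop(sprintf(
      "FASTA format error at line %s: record '%s' has an empty sequence",
      line, ids[k]
    ))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf(
      "FASTA format error: record '%s' contains characters outside {A,C,G,T,N,U}",
      ids[k]
    ))
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicated record id '", ids[anyDuplicated(ids)], "'")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# line number of a record header, for error messages
fasta_header_line <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(startsWith(lines, ">") & sub("\\s.*$", "", sub("^>", "", lines)) == id)
  if (length(hit) > 0) hit[1] else "?"
}

#' Write sequences to FASTA
#'
#' @param seqs a named `XStringSet` or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    # protein sets may carry U (selenocysteine); route through the AA container
    if (any(grepl("[^ACGTUN]", toupper(seqs)))) {
      seqs <- Biostrings::AAStringSet(seqs)
    } else {
      seqs <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
    }
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read protein queries from FASTA
#'
#' `U` (selenocysteine) is kept as-is.
#'
#' @param path path to a protein FASTA file.
#' @return named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(raw))
  names(out) <- sub("\\s.*$", "", names(raw))
  if (any(nchar(out) == 0L)) stop("FASTA format error: empty protein record")
  out
}

# ---------------------------------------------------------------------------
# Annotations (internal: 0-based half-open; GFF3 I/O converts to 1-based)
# ---------------------------------------------------------------------------

#' Construct a gene annotation table
#'
#' Internal coordinates are 0-based half-open.  `product_label` carries the
#' functional label used elsewhere in the package (e.g. `"selD"`, `"hdrA"`,
#' `"frhD"`, `"tRNA-Sec"`).
#'
#' @param contig_id,start,end,strand,gene_id,product_label,coding vectors of
#'   equal length (`coding` marks CDS rows, whose length must be a multiple
#'   of 3).
#' @param genome optional `DNAStringSet`; when given, intervals are checked
#'   against contig bounds.
#' @return a `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(contig_id, start, end, strand, gene_id,
                            product_label = NA_character_, coding = TRUE,
                            genome = NULL) {
  n <- length(start)
  df <- data.frame(
    contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), gene_id = as.character(gene_id),
    product_label = rep_len(as.character(product_label), n),
    coding = rep_len(as.logical(coding), n),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0L | df$start >= df$end)) {
    stop("annotation error: need 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("annotation error: strand must be + or -")
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    if (!all(df$contig_id %in% names(len))) {
      stop("annotation error: contig id absent from genome: ",
        paste(setdiff(df$contig_id, names(len)), collapse = ","))
    }
    if (any(df$end > len[df$contig_id])) stop("annotation error: interval beyond contig end")
  }
  if (any(df$coding & (df$end - df$start) %% 3L != 0L)) {
    stop("annotation error: coding interval length not a multiple of 3")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotations from GFF3
#'
#' Converts from GFF3 1-based inclusive coordinates to the package's
#' 0-based half-open convention.  The `product` attribute populates
#' `product_label`; rows of type `CDS` or `gene` are flagged coding, `tRNA`
#' rows are not.
#'
#' @param path path to a GFF3 file.
#' @param genome optional genome for bounds checking.
#' @return a `gene_annotation` data.frame.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  product <- if ("product" %in% names(md)) as.character(md$product) else NA_character_
  gid <- if ("ID" %in% names(md)) as.character(md$ID) else paste0("gene", seq_along(gr))
  type <- if ("type" %in% names(md)) as.character(md$type) else "gene"
  gene_annotation(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid,
    product_label = product,
    coding = !(type %in% c("tRNA", "rRNA", "ncRNA")),
    genome = genome
  )
}

#' Write gene annotations to GFF3
#'
#' @param ann a `gene_annotation` data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(ann$coding, "gene", "tRNA")
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$product <- ann$product_label
  S4Vectors::mcols(gr)$source <- "secisscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# 3'-UTR windows
# ---------------------------------------------------------------------------

#' Extract the 3'-UTR scan window of a gene
#'
#' Returns the region `upstream` nt before to `downstream` nt after the
#' annotated 3' end of the gene (the CDS end, stop codon included), clamped
#' at contig boundaries, as a transcript-oriented RNA string (minus-strand
#' genes are reverse-complemented).
#'
#' @param genome a `DNAStringSet` (or single `DNAString`/character).
#' @param gene a single-row `gene_annotation` (or list with `contig_id`,
#'   `start`, `end`, `strand`).
#' @param upstream,downstream window extent in nt (defaults 30 and 600).
#' @return a `utr3_window`: list with `contig_id`, `genomic_start`,
#'   `genomic_end` (0-based half-open genomic slice), `strand`, `sequence`
#'   (RNA, 5'->3' on the transcript) and `offset_of_stop` (index within the
#'   window of the first base 3' of the gene).
#' @export
extract_utr3_window <- function(genome, gene, upstream = 30L, downstream = 600L) {
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    gene <- as.list(gene)
  }
  seq <- contig_seq(genome, gene$contig_id)
  len <- nchar(seq)
  if (gene$start < 0L || gene$end > len) {
    stop("coordinate error: gene lies outside contig '", gene$contig_id, "'")
  }
  if (gene$strand == "+") {
    ws <- max(0L, gene$end - upstream)
    we <- min(len, gene$end + downstream)
    s <- substr(seq, ws + 1L, we)
    offset <- gene$end - ws
  } else {
    ws <- max(0L, gene$start - downstream)
    we <- min(len, gene$start + upstream)
    s <- dna_revcomp(substr(seq, ws + 1L, we))
    offset <- we - gene$start
  }
  structure(
    list(
      contig_id = gene$contig_id, genomic_start = ws, genomic_end = we,
      strand = gene$strand, sequence = chartr("T", "U", s),
      offset_of_stop = offset
    ),
    class = "utr3_window"
  )
}

# map an interval in window coordinates back to the genome (0-based half-open)
window_to_genomic <- function(window, a, b) {
  if (window$strand == "+") {
    c(window$genomic_start + a, window$genomic_start + b)
  } else {
    c(window$genomic_end - b, window$genomic_end - a)
  }
}

contig_seq <- function(genome, contig_id = NULL) {
  if (is.character(genome) && length(genome) == 1L && is.null(contig_id)) {
    return(toupper(genome))
  }
  if (is(genome, "DNAString")) {
    return(as.character(genome))
  }
  if (is.character(genome)) {
    if (!is.null(contig_id) && !is.null(names(genome))) {
      if (!contig_id %in% names(genome)) stop("coordinate error: unknown contig '", contig_id, "'")
      return(toupper(genome[[contig_id]]))
    }
    return(toupper(genome[[1]]))
  }
  # DNAStringSet
  if (is.null(contig_id)) {
    return(as.character(genome[[1]]))
  }
  if (!contig_id %in% names(genome)) stop("coordinate error: unknown contig '", contig_id, "'")
  as.character(genome[[contig_id]])
}

#' Reverse-complement a DNA string
#'
#' @param x single DNA character string (N allowed).
#' @return the reverse complement.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---------------------------------------------------------------------------
# Translation with UGA read-through
# ---------------------------------------------------------------------------

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

#' Translate with optional UGA (Sec) read-through
#'
#' Standard genetic code; when `readthrough_tga` is `TRUE`, `TGA` is decoded
#' as `U` (selenocysteine) and translation continues, while `TAA`/`TAG`
#' always terminate.  Codons containing `N` give `X`.  A trailing partial
#' codon is ignored.
#'
#' @param nt nucleotide string (DNA or RNA).
#' @param frame reading-frame offset, 0, 1 or 2.
#' @param readthrough_tga decode TGA as Sec instead of stop.
#' @return amino-acid string (possibly empty), stop codon not included.
#' @examples
#' translate_readthrough("ATGTGATAA", readthrough_tga = TRUE)  # "MU"
#' @export
translate_readthrough <- function(nt, frame = 0L, readthrough_tga = TRUE) {
  stopifnot(frame %in% 0:2)
  codons <- split_codons(nt, frame)
  out <- character(0)
  for (cd in codons) {
    if (cd %in% c("TAA", "TAG")) {
      break
    }
    if (cd == "TGA") {
      if (!readthrough_tga) break
      out <- c(out, "U")
      next
    }
    aa <- unname(GENETIC_CODE_TABLE[cd])
    out <- c(out, if (is.na(aa)) "X" else aa)
  }
  paste(out, collapse = "")
}

# full-length translation, all stops rendered '*' (six-frame alignment view)
translate_full <- function(nt, frame = 0L) {
  codons <- split_codons(nt, frame)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(nt, frame) {
  nt <- chartr("U", "T", toupper(nt))
  n <- nchar(nt)
  if (n - frame < 3L) {
    return(character(0))
  }
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  substring(nt, starts, starts + 2L)
}

# ---------------------------------------------------------------------------
# Reports
# ---------------------------------------------------------------------------

#' Write a report table
#'
#' @param records a data.frame.  For BED output it must carry `contig_id`,
#'   `start`, `end` (0-based half-open) and optionally `name`, `score`,
#'   `strand` columns.
#' @param path output path.
#' @param format one of `"tsv"`, `"bed"`, `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "bed", "json")) {
  format <- match.arg(tolower(format[1]), c("tsv", "bed", "json"))
  records <- as.data.frame(records)
  if (format == "tsv") {
    write.table(records, path,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
    )
  } else if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA, pretty = TRUE)
  } else {
    need <- c("contig_id", "start", "end")
    if (!all(need %in% names(records))) {
      stop("BED output needs columns: ", paste(need, collapse = ", "))
    }
    bed <- data.frame(
      chrom = records$contig_id,
      chromStart = as.integer(records$start),
      chromEnd = as.integer(records$end),
      name = if ("name" %in% names(records)) records$name else ".",
      score = if ("score" %in% names(records)) records$score else 0,
      strand = if ("strand" %in% names(records)) records$strand else ".",
      stringsAsFactors = FALSE
    )
    writeLines(
      paste(bed$chrom, bed$chromStart, bed$chromEnd, bed$name, bed$score,
        bed$strand,
        sep = "\t"
      ),
      path
    )
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path input path.
#' @param format `"tsv"`, `"bed"` or `"json"`.
#' @return a data.frame.
#' @export
read_report <- function(path, format = c("tsv", "bed", "json")) {
  format <- match.arg(tolower(format[1]), c("tsv", "bed", "json"))
  if (format == "tsv") {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  } else if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- read.delim(path,
      header = FALSE, sep = "\t", stringsAsFactors = FALSE,
      col.names = c("contig_id", "start", "end", "name", "score", "strand")
    )
    df
  }
}
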