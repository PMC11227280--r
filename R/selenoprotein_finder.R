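# Selenoprotein gene finding from Sec/TGA alignment pairs, UGA read-through
# ORF extension, Sec-machinery inventory and the two-part Sec-utilization
# criterion, plus hdrA-frhD operon adjacency detection.

SEC_MACHINERY <- c("SecS", "EFSec", "PSTK", "SelD", "tRNA-Sec")

#' Default homology-search thresholds
#'
#' @param tblastn_evalue primary search e-value cutoff (default 0.01).
#' @param min_alignment_coverage minimum aligned fraction of query or
#'   subject (default 0.25).
#' @param hmm_evalue profile-HMM search cutoff (default 0.05).
#' @param ortholog_evalue bidirectional-best-hit cutoff (default 0.001).
#' @param min_protein_len_aa proteins shorter than this are flagged and
#'   excluded from downstream phylogenetic use (default 35).
#' @return a `search_thresholds` list.
#' @export
search_thresholds <- function(tblastn_evalue = 0.01, min_alignment_coverage = 0.25,
                              hmm_evalue = 0.05, ortholog_evalue = 0.001,
                              min_protein_len_aa = 35L) {
  stopifnot(
    tblastn_evalue > 0, hmm_evalue > 0, ortholog_evalue > 0,
    min_alignment_coverage > 0, min_alignment_coverage <= 1,
    min_protein_len_aa > 0
  )
  structure(
    list(
      tblastn_evalue = tblastn_evalue,
      min_alignment_coverage = min_alignment_coverage,
      hmm_evalue = hmm_evalue, ortholog_evalue = ortholog_evalue,
      min_protein_len_aa = as.integer(min_protein_len_aa)
    ),
    class = "search_thresholds"
  )
}

ALN_COLUMNS <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore",
  "qlen", "slen", "qseq", "sseq"
)

#' Read protein-vs-nucleotide alignments from extended tabular output
#'
#' Parses BLAST-outfmt-6-like TSV extended with `qlen slen qseq sseq`
#' columns (the full dialect is `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore qlen slen qseq sseq`;
#' `qlen` in aa, `slen` in nt).
#' `qseq`/`sseq` are the aligned query and translated-subject strings with
#' `-` gaps; they are required, since Sec/TGA pairing reads alignment
#' columns.  Records failing the thresholds are retained but flagged
#' `below_threshold`.
#'
#' @param path TSV path (no header).
#' @param thresholds a [search_thresholds()] list.
#' @param dialect column layout; only `"outfmt6x"` is defined.
#' @return data.frame of alignment records with derived `strand`, `frame`,
#'   `qcov`, `scov` and `below_threshold` columns.
#' @export
read_tabular_alignments <- function(path, thresholds = search_thresholds(),
                                    dialect = "outfmt6x") {
  if (dialect != "outfmt6x") stop("unknown alignment dialect: ", dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_alignment_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf == 12L)) {
    stop("dialect lacks qseq/sseq columns (found a 12-column outfmt 6 row); ",
      "rerun the search with -outfmt '6 ", paste(ALN_COLUMNS, collapse = " "), "'")
  }
  bad <- which(nf != length(ALN_COLUMNS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "alignment parse error at row %d: expected %d fields, found %d",
      bad[1], length(ALN_COLUMNS), nf[bad[1]]
    ))
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- ALN_COLUMNS
  num <- c("pident", "evalue", "bitscore")
  int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send", "qlen", "slen")
  df[num] <- lapply(df[num], as.numeric)
  df[int] <- lapply(df[int], as.integer)
  df$qseq <- toupper(df$qseq)
  df$sseq <- toupper(df$sseq)
  if (any(nchar(df$qseq) != nchar(df$sseq))) {
    stop("alignment parse error: qseq and sseq differ in length at row ",
      which(nchar(df$qseq) != nchar(df$sseq))[1])
  }
  annotate_alignments(df, thresholds)
}

empty_alignment_table <- function() {
  df <- as.data.frame(stats::setNames(
    c(
      lapply(c("qseqid", "sseqid"), function(x) character(0)),
      lapply(c("pident"), function(x) numeric(0)),
      lapply(c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send"),
        function(x) integer(0)),
      lapply(c("evalue", "bitscore"), function(x) numeric(0)),
      lapply(c("qlen", "slen"), function(x) integer(0)),
      lapply(c("qseq", "sseq"), function(x) character(0))
    ),
    ALN_COLUMNS
  ), stringsAsFactors = FALSE)
  annotate_alignments(df, search_thresholds())
}

annotate_alignments <- function(df, thresholds) {
  df$strand <- ifelse(df$sstart <= df$send, "+", "-")
  df$frame <- ifelse(df$strand == "+", (df$sstart - 1L) %% 3L, NA_integer_)
  df$qcov <- (abs(df$qend - df$qstart) + 1L) / df$qlen
  df$scov <- (abs(df$send - df$sstart) + 1L) / df$slen
  df$scov[!is.finite(df$scov)] <- NA_real_
  covered <- pmax(df$qcov, df$scov, na.rm = TRUE)
  df$below_threshold <- df$evalue > thresholds$tblastn_evalue |
    covered < thresholds$min_alignment_coverage
  df
}

# ---------------------------------------------------------------------------
# Sec/TGA pairs
# ---------------------------------------------------------------------------

#' Locate Sec/TGA pairs in one alignment record
#'
#' Walks the aligned columns; wherever the query carries `U`
#' (selenocysteine) against a non-gap subject column, the column is mapped
#' to genomic coordinates and kept only if the coding-strand codon there is
#' literally `TGA`.
#'
#' @param aln one alignment record (single-row data.frame or list) with
#'   `sseqid`, `sstart`, `send`, `qstart`, `qseq`, `sseq`.
#' @param genome genome sequences containing the subject contig.
#' @return data.frame with `query_sec_pos` (1-based aa in the query),
#'   `codon_start`, `codon_end` (1-based inclusive genomic), `strand`.
#' @export
find_sec_tga_pairs <- function(aln, genome) {
  if (is.data.frame(aln)) {
    stopifnot(nrow(aln) == 1L)
    aln <- as.list(aln)
  }
  seq <- contig_seq(genome, aln$sseqid)
  qa <- strsplit(aln$qseq, "")[[1]]
  sa <- strsplit(aln$sseq, "")[[1]]
  if (length(qa) != length(sa)) stop("alignment-inconsistency error: ragged alignment strings")
  minus <- aln$sstart > aln$send
  qpos <- aln$qstart - 1L
  tpos <- 0L # subject aa offset within the alignment
  out <- list()
  for (col in seq_along(qa)) {
    if (qa[col] != "-") qpos <- qpos + 1L
    if (sa[col] != "-") tpos <- tpos + 1L
    if (qa[col] != "U" || sa[col] == "-") next
    if (!minus) {
      cs <- aln$sstart + 3L * (tpos - 1L)
      ce <- cs + 2L
      codon <- substr(seq, cs, ce)
    } else {
      ce <- aln$sstart - 3L * (tpos - 1L)
      cs <- ce - 2L
      codon <- dna_revcomp(substr(seq, cs, ce))
    }
    if (cs < 1L || ce > nchar(seq)) {
      stop("alignment-inconsistency error: codon coordinates leave contig '", aln$sseqid, "'")
    }
    if (codon == "TGA") {
      out[[length(out) + 1L]] <- data.frame(
        query_sec_pos = qpos, codon_start = cs, codon_end = ce,
        strand = if (minus) "-" else "+", stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      query_sec_pos = integer(0), codon_start = integer(0),
      codon_end = integer(0), strand = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# ORF extension around a Sec codon
# ---------------------------------------------------------------------------

#' Extend an open reading frame around a TGA (Sec) codon
#'
#' Extends in frame downstream to the first `TAA`/`TAG` (reading `TGA`
#' through as Sec) and upstream to the nearest `ATG`/`GTG`/`TTG` start,
#' bounded by the first in-frame `TAA`/`TAG`.  Missing start or stop at a
#' contig edge sets a flag rather than raising an error.
#'
#' @param genome genome sequences.
#' @param codon_start 1-based genomic start of the TGA codon on the coding
#'   strand (its lowest coordinate).
#' @param strand `"+"` or `"-"`.
#' @param contig_id contig containing the codon (may be omitted when
#'   `genome` is a single sequence).
#' @return list with `orf_start`, `orf_end` (1-based inclusive genomic),
#'   `strand`, `protein` (with `U` at every TGA), `start_missing`,
#'   `stop_missing`.
#' @export
extend_orf <- function(genome, codon_start, strand, contig_id = NULL) {
  seq <- contig_seq(genome, contig_id)
  n <- nchar(seq)
  if (strand == "+") {
    codon_at <- function(k) substr(seq, codon_start + 3L * k, codon_start + 3L * k + 2L)
    max_down <- (n - (codon_start + 2L)) %/% 3L
    max_up <- (codon_start - 1L) %/% 3L
  } else {
    # coding-strand codons read downstream as genomic coordinate decreases
    codon_at <- function(k) {
      dna_revcomp(substr(seq, codon_start - 3L * k, codon_start - 3L * k + 2L))
    }
    max_down <- (codon_start - 1L) %/% 3L
    max_up <- (n - (codon_start + 2L)) %/% 3L
  }
  if (codon_at(0L) != "TGA") {
    stop("coordinate error: no TGA codon on the coding strand at the stated position")
  }
  # downstream: first in-frame TAA/TAG terminates
  down <- 0L
  stop_missing <- TRUE
  while (down < max_down) {
    cd <- codon_at(down + 1L)
    if (cd %in% c("TAA", "TAG")) {
      stop_missing <- FALSE
      break
    }
    down <- down + 1L
  }
  # upstream: nearest start codon, bounded by the first in-frame stop
  up <- 0L
  k <- 1L
  start_missing <- TRUE
  while (k <= max_up) {
    cd <- codon_at(-k)
    if (cd %in% c("TAA", "TAG")) break
    if (cd %in% c("ATG", "GTG", "TTG")) {
      up <- k
      start_missing <- FALSE
      break
    }
    k <- k + 1L
  }
  if (start_missing) up <- k - 1L # window edge or codon before the stop
  codons <- vapply((-up):down, codon_at, character(1))
  protein <- vapply(seq_along(codons), function(z) {
    cd <- codons[z]
    if (cd == "TGA") {
      return("U")
    }
    if (z == 1L && !start_missing) {
      return("M")
    } # initiator
    aa <- unname(GENETIC_CODE_TABLE[cd])
    if (is.na(aa)) "X" else aa
  }, character(1))
  span_codons <- up + down + 1L + (!stop_missing) # include the terminator
  if (strand == "+") {
    orf_start <- codon_start - 3L * up
    orf_end <- orf_start + 3L * span_codons - 1L
  } else {
    orf_end <- codon_start + 2L + 3L * up
    orf_start <- orf_end - 3L * span_codons + 1L
  }
  list(
    orf_start = orf_start, orf_end = orf_end, strand = strand,
    protein = paste(protein, collapse = ""),
    start_missing = start_missing, stop_missing = stop_missing
  )
}

# ---------------------------------------------------------------------------
# Family assignment / hit table
# ---------------------------------------------------------------------------

#' Assign family labels to selenoprotein hits and deduplicate
#'
#' The family label derives from the supporting query id (text before the
#' first `|` or `_`, unless an explicit map is given).  Hits on identical
#' genomic Sec codons are merged, keeping all supports; proteins shorter
#' than the length threshold are flagged `short` (excluded from
#' phylogenetic use downstream, not dropped).
#'
#' @param hits data.frame with at least `contig_id`, `codon_start`,
#'   `codon_end`, `strand`, `query_id`, `protein`.
#' @param family_map optional named character vector query id -> family.
#' @param thresholds a [search_thresholds()] list.
#' @return deduplicated data.frame with `family`, `n_support`, `supports`,
#'   `short` columns added.
#' @export
assign_family <- function(hits, family_map = NULL, thresholds = search_thresholds()) {
  if (nrow(hits) == 0L) {
    hits$family <- character(0)
    hits$n_support <- integer(0)
    hits$supports <- character(0)
    hits$short <- logical(0)
    return(hits)
  }
  fam <- if (!is.null(family_map)) {
    unname(family_map[hits$query_id])
  } else {
    sub("[|_].*$", "", hits$query_id)
  }
  hits$family <- fam
  key <- paste(hits$contig_id, hits$codon_start, hits$strand, sep = ":")
  out <- do.call(rbind, lapply(split(seq_len(nrow(hits)), key), function(idx) {
    # representative support: strongest alignment when scores are present
    if ("bitscore" %in% names(hits)) {
      idx <- idx[order(-hits$bitscore[idx])]
    }
    first <- hits[idx[1], , drop = FALSE]
    first$n_support <- length(idx)
    first$supports <- paste(sort(unique(hits$query_id[idx])), collapse = ",")
    first
  }))
  out$short <- nchar(out$protein) < thresholds$min_protein_len_aa
  out <- out[order(out$contig_id, out$codon_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Sec-utilization trait
# ---------------------------------------------------------------------------

#' Classify the Sec-utilization trait of one organism
#'
#' The verdict is `Sec+` when (i) at least `min_machinery` of the Sec
#' encoding system components SecS, EFSec, PSTK, SelD, tRNA-Sec are
#' present, and (ii) at least `min_selenoproteins` known selenoprotein gene
#' was found.  tRNA-Sec counts toward the tally; `strict_trna = TRUE`
#' additionally makes its presence mandatory.
#'
#' @param machinery character vector of present components, or named
#'   logical vector over the five components.
#' @param n_selenoproteins selenoprotein gene count (or a hits data.frame).
#' @param strict_trna require tRNA-Sec itself.
#' @param min_machinery,min_selenoproteins criterion legs (defaults 3, 1).
#' @param organism_id optional id copied into the report.
#' @return a `sec_trait_report` list: `organism_id`, `machinery` (named
#'   logical), `machinery_count`, `n_selenoproteins`, `verdict`
#'   (`"Sec+"`/`"Sec-"`), `reasons`.
#' @export
classify_sec_trait <- function(machinery, n_selenoproteins, strict_trna = FALSE,
                               min_machinery = 3L, min_selenoproteins = 1L,
                               organism_id = NA_character_) {
  if (is.logical(machinery)) {
    stopifnot(!is.null(names(machinery)))
    present <- stats::setNames(SEC_MACHINERY %in% names(machinery)[machinery], SEC_MACHINERY)
  } else {
    bad <- setdiff(machinery, SEC_MACHINERY)
    if (length(bad) > 0L) {
      stop("unknown Sec machinery component: ", paste(bad, collapse = ","))
    }
    present <- stats::setNames(SEC_MACHINERY %in% machinery, SEC_MACHINERY)
  }
  if (is.data.frame(n_selenoproteins)) n_selenoproteins <- nrow(n_selenoproteins)
  count <- sum(present)
  reasons <- character(0)
  if (count < min_machinery) {
    reasons <- c(reasons, sprintf(
      "only %d of >=%d required Sec machinery genes present", count, min_machinery
    ))
  }
  if (n_selenoproteins < min_selenoproteins) {
    reasons <- c(reasons, sprintf(
      "%d of >=%d required selenoprotein genes found", n_selenoproteins, min_selenoproteins
    ))
  }
  if (strict_trna && !present[["tRNA-Sec"]]) {
    reasons <- c(reasons, "tRNA-Sec absent (strict mode)")
  }
  structure(
    list(
      organism_id = organism_id, machinery = present, machinery_count = count,
      n_selenoproteins = n_selenoproteins,
      verdict = if (length(reasons) == 0L) "Sec+" else "Sec-",
      reasons = reasons
    ),
    class = "sec_trait_report"
  )
}

#' @export
print.sec_trait_report <- function(x, ...) {
  cat(sprintf(
    "<sec_trait_report> %s: %s (%d machinery genes, %d selenoproteins)\n",
    x$organism_id, x$verdict, x$machinery_count, x$n_selenoproteins
  ))
  if (length(x$reasons) > 0) cat("  -", paste(x$reasons, collapse = "\n  - "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Operon adjacency
# ---------------------------------------------------------------------------

#' Detect adjacent same-strand gene pairs (hdrA-frhD style)
#'
#' Among the genes of one contig and strand ordered by start, reports
#' consecutive entries whose product labels are the two requested labels
#' (either order) with intergenic distance at most `max_gap_nt`.
#'
#' @param annotations a `gene_annotation` data.frame.
#' @param labels the two product labels (default `c("hdrA", "frhD")`).
#' @param max_gap_nt maximum intergenic gap in nt (default 60).
#' @return data.frame with one row per pair: contig, strand, the two gene
#'   ids and labels in genomic order, and `gap`.
#' @export
detect_operon_pairs <- function(annotations, labels = c("hdrA", "frhD"),
                                max_gap_nt = 60L) {
  stopifnot(length(labels) == 2L)
  empty <- data.frame(
    contig_id = character(0), strand = character(0),
    gene1 = character(0), label1 = character(0),
    gene2 = character(0), label2 = character(0),
    gap = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(annotations) == 0L) {
    return(empty)
  }
  out <- list()
  for (grp in split(
    as.data.frame(annotations),
    paste(annotations$contig_id, annotations$strand)
  )) {
    grp <- grp[order(grp$start), , drop = FALSE]
    if (nrow(grp) < 2L) next
    for (k in seq_len(nrow(grp) - 1L)) {
      a <- grp[k, ]
      b <- grp[k + 1L, ]
      lab <- c(a$product_label, b$product_label)
      if (setequal(lab, labels) && !anyNA(lab)) {
        gap <- b$start - a$end
        if (gap <= max_gap_nt) {
          out[[length(out) + 1L]] <- data.frame(
            contig_id = a$contig_id, strand = a$strand,
            gene1 = a$gene_id, label1 = a$product_label,
            gene2 = b$gene_id, label2 = b$product_label,
            gap = gap, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(empty)
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$strand, res$gene1), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Self-contained six-frame local aligner
# ---------------------------------------------------------------------------

selenoprotein_submatrix <- local({
  cache <- NULL
  function(sec_stop_bonus = 8) {
    if (!is.null(cache) && attr(cache, "bonus") == sec_stop_bonus) {
      return(cache)
    }
    b62 <- get_blosum62()
    alpha <- rownames(b62)
    mat <- b62
    # selenocysteine scores like cysteine; aligning U against a stop codon
    # (the Sec/TGA signal) earns a configurable bonus
    u_row <- b62["C", , drop = TRUE]
    mat <- rbind(mat, U = u_row)
    mat <- cbind(mat, U = c(u_row, b62["C", "C"]))
    mat["U", "*"] <- sec_stop_bonus
    mat["*", "U"] <- sec_stop_bonus
    attr(mat, "bonus") <- sec_stop_bonus
    cache <<- mat
    mat
  }
})

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Local alignment of a selenoprotein query against all six frames
#'
#' Smith-Waterman (via [Biostrings::pairwiseAlignment]) of a protein query
#' (with `U` for selenocysteine) against the six conceptual translations of
#' a genome window, with BLOSUM62 extended so that `U` scores like `C` and
#' `U`-vs-`*` (a stop codon, i.e. a potential Sec/TGA pair) earns a bonus.
#' Returns the best-frame alignment as a one-row alignment record of the
#' same dialect as [read_tabular_alignments()].
#'
#' @param query protein string with `U` allowed.
#' @param genome genome window (character / `DNAString(Set)`).
#' @param query_id,subject_id ids copied into the record.
#' @param sec_stop_bonus score for aligning `U` to `*` (default 8).
#' @param gap_opening,gap_extension affine gap penalties (defaults 11, 1).
#' @param thresholds a [search_thresholds()] list for flagging.
#' @return one-row data.frame alignment record.
#' @export
local_align_protein_vs_sixframe <- function(query, genome, query_id = "query",
                                            subject_id = NULL,
                                            sec_stop_bonus = 8,
                                            gap_opening = 11, gap_extension = 1,
                                            thresholds = search_thresholds()) {
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(names(genome))) names(genome)[1] else "subject"
  }
  seq <- contig_seq(genome, if (!is.null(names(genome))) subject_id else NULL)
  query <- toupper(query)
  if (nchar(query) == 0L || nchar(seq) == 0L) stop("empty query or window")
  mat <- selenoprotein_submatrix(sec_stop_bonus)
  rc <- dna_revcomp(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    template <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      aa <- translate_full(template, frame)
      if (nchar(aa) == 0L) next
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(query),
        subject = Biostrings::AAString(aa),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension
      )
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score) {
        best <- list(aln = aln, score = sc, strand = strand, frame = frame, aa = aa)
      }
    }
  }
  aln <- best$aln
  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  q_iv <- c(
    Biostrings::start(Biostrings::pattern(aln)),
    Biostrings::end(Biostrings::pattern(aln))
  )
  s_iv <- c(
    Biostrings::start(Biostrings::subject(aln)),
    Biostrings::end(Biostrings::subject(aln))
  )
  L <- nchar(seq)
  f <- best$frame
  if (best$strand == "+") {
    sstart <- f + 3L * (s_iv[1] - 1L) + 1L
    send <- f + 3L * s_iv[2]
  } else {
    sstart <- L - (f + 3L * (s_iv[1] - 1L))
    send <- L - (f + 3L * s_iv[2]) + 1L
  }
  cols <- strsplit(qa, "")[[1]] == strsplit(sa, "")[[1]]
  # Karlin-Altschul e-value estimate with published gapped BLOSUM62
  # (11,1) parameters, over the six-frame search space
  lambda <- 0.267
  kconst <- 0.041
  evalue <- kconst * nchar(query) * (2 * nchar(seq)) * exp(-lambda * best$score)
  df <- data.frame(
    qseqid = query_id, sseqid = subject_id,
    pident = round(100 * mean(cols), 2),
    length = nchar(qa),
    mismatch = sum(!cols & strsplit(qa, "")[[1]] != "-" & strsplit(sa, "")[[1]] != "-"),
    gapopen = sum(diff(c(FALSE, strsplit(qa, "")[[1]] == "-")) == 1L) +
      sum(diff(c(FALSE, strsplit(sa, "")[[1]] == "-")) == 1L),
    qstart = q_iv[1], qend = q_iv[2],
    sstart = sstart, send = send,
    evalue = evalue, bitscore = best$score,
    qlen = nchar(query), slen = L,
    qseq = qa, sseq = sa,
    stringsAsFactors = FALSE
  )
  annotate_alignments(df, thresholds)
}

#' All significant local alignments of a query against a genome sequence
#'
#' Iterates [local_align_protein_vs_sixframe()]: after each significant
#' alignment the matched subject region is masked with `N` and the search
#' repeats, so every copy of a multi-copy gene family is found (hdrA/frhD
#' typically occur in several copies per genome).  Stops at the first
#' alignment failing the e-value gate, or after `max_hits` rounds.
#'
#' @inheritParams local_align_protein_vs_sixframe
#' @param max_hits upper bound on alignments returned per contig.
#' @return data.frame of alignment records (possibly empty).
#' @export
local_align_all_hits <- function(query, genome, query_id = "query",
                                 subject_id = NULL, sec_stop_bonus = 8,
                                 gap_opening = 11, gap_extension = 1,
                                 thresholds = search_thresholds(),
                                 max_hits = 25L) {
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(names(genome))) names(genome)[1] else "subject"
  }
  seq <- contig_seq(genome, if (!is.null(names(genome))) subject_id else NULL)
  out <- list()
  for (round in seq_len(max_hits)) {
    rec <- local_align_protein_vs_sixframe(query, stats::setNames(seq, subject_id),
      query_id = query_id, subject_id = subject_id,
      sec_stop_bonus = sec_stop_bonus, gap_opening = gap_opening,
      gap_extension = gap_extension, thresholds = thresholds
    )
    if (rec$evalue > thresholds$tblastn_evalue || rec$bitscore <= 0) break
    out[[length(out) + 1L]] <- rec
    lo <- min(rec$sstart, rec$send)
    hi <- max(rec$sstart, rec$send)
    substr(seq, lo, hi) <- strrep("N", hi - lo + 1L)
  }
  if (length(out) == 0L) {
    return(empty_alignment_table())
  }
  do.call(rbind, out)
}
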