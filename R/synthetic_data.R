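# Deterministic benchmark-genome generator: random-background contigs with
# planted Sec machinery genes, selenoprotein genes carrying one in-frame TGA,
# and 3'-UTR SECIS elements of each structural class, with a machine-readable
# truth ledger.  All randomness flows from the single config seed.

# Synthetic protein templates per selenoprotein family (invented sequences;
# U marks the selenocysteine).  Interior residues avoid M so that the
# nearest-ATG rule of the ORF extender recovers the planted start exactly;
# codon choices below avoid GTG/TTG for the same reason.
FAMILY_TEMPLATES <- c(
  SelD = "MSEKVLILAGHSNKALEAVRGLEPGDUAVIVTDRPELAGLAEKYGIETIVGDFNNEELLRKIAEKHDVKGIV",
  FrhA = "MAKKPRVVWLHNAECTGUDACSVEIAENPDLLEAIDVRELANLVLAAGPESAWEEIKNTAEKYGRKLAVVE",
  HdrA = "MSKIAVYVUTRCDGCAKSLAEELRENLKAEGVEVEIRETGCLGLCHAEPLVEVTRPGKPRVTYGRVTPEDV",
  FrhD = "MVNAKIHVUPSACSGCSITAKLVEDALEKELGDRVEVVRTPCIGRCHSGPNVKVLPGVDVYSHVKPEDVPG",
  PrxL = "MVLKLGDKFPEVEVKTTHGVIKLPDDFKGKWFVLFSHPADFTPVUTTEFVAFQERYEDFKKLNTELIGLSV",
  AhpF = "MALEVGEKAPDFELPDQHGEKVRLSDFRGRKVVLYFYPKDDTPGUTKEACDFRDNYADFEKAGAVVLGVSP",
  DsbA = "MKKVLSVLALSLLVAGUSAAESSNDIVKVDSPKAFELAKEHGKVVLVEFFATWCGPCRALKPVLEELAEEY"
)

# fixed codon per amino acid: interior codons avoid ATG/GTG/TTG (alternative
# starts) and the stop-like codons, keeping ORF recovery exact
SIM_CODON <- c(
  A = "GCT", C = "TGC", D = "GAC", E = "GAA", F = "TTC", G = "GGC", H = "CAC",
  I = "ATC", K = "AAA", L = "CTG", M = "ATG", N = "AAC", P = "CCG", Q = "CAG",
  R = "CGT", S = "TCT", T = "ACC", V = "GTC", W = "TGG", Y = "TAC", U = "TGA"
)

MACHINERY_LABELS <- c(
  SecS = "secS", EFSec = "efSec", PSTK = "pstk", SelD = "selD",
  `tRNA-Sec` = "tRNA-Sec"
)

#' Simulation configuration
#'
#' Defaults define the benchmark conditions: a handful of mid-size contigs
#' with near-archaeal GC, one planted gene per selenoprotein family, a full
#' Sec machinery complement, hdrA-frhD co-planted as an operon with a short
#' intergenic gap, GC-biased perfect SECIS stems and an adenine-rich loop
#' prefix.
#'
#' @param seed integer; fixes all output bit-exactly.
#' @param n_contigs,contig_length genome shape.
#' @param gc background GC fraction (0-1, exclusive).
#' @param families named integer vector of planting counts per family
#'   (names from `names(FAMILY_TEMPLATES)` = SelD, FrhA, HdrA, FrhD, PrxL,
#'   AhpF, DsbA).
#' @param secis_mix named probabilities over SECIS classes for planted
#'   genes (`eSECIS_I`, `eSECIS_II`, `eaSECIS`).
#' @param machinery machinery complement to plant (labels from
#'   SecS, EFSec, PSTK, SelD, tRNA-Sec).
#' @param operon_hdrA_frhD co-plant hdrA+frhD adjacently on one strand.
#' @param operon_gap intergenic gap of the co-planted pair (nt).
#' @param stem_gc GC bias of planted SECIS stems (1 = all S-S pairs).
#' @param loop_a_prefix length of the adenine run opening apical
#'   loops/bulges of planted elements.
#' @param utr_offset_range distance range gene 3' end -> SECIS start.
#' @param mutation_rate per-nt substitution rate applied to planted CDS
#'   (0 = identity plantings).
#' @param organism_id id used in file names and the truth ledger.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_contigs = 3L, contig_length = 12000L,
                       gc = 0.45,
                       families = c(SelD = 1L, FrhA = 1L, HdrA = 1L, FrhD = 1L, PrxL = 1L),
                       secis_mix = c(eSECIS_I = 0.6, eSECIS_II = 0.25, eaSECIS = 0.15),
                       machinery = c("SecS", "EFSec", "PSTK", "SelD", "tRNA-Sec"),
                       operon_hdrA_frhD = TRUE, operon_gap = 30L,
                       stem_gc = 0.9, loop_a_prefix = 5L,
                       utr_offset_range = c(5L, 30L),
                       mutation_rate = 0,
                       organism_id = "synth1") {
  stopifnot(
    gc > 0, gc < 1, stem_gc >= 0, stem_gc <= 1,
    all(names(families) %in% names(FAMILY_TEMPLATES)),
    all(families >= 0L), mutation_rate >= 0, mutation_rate <= 1,
    all(names(secis_mix) %in% SECIS_CLASSES), sum(secis_mix) > 0
  )
  structure(
    list(
      seed = as.integer(seed), n_contigs = as.integer(n_contigs),
      contig_length = as.integer(contig_length), gc = gc,
      families = families, secis_mix = secis_mix / sum(secis_mix),
      machinery = machinery,
      operon_hdrA_frhD = operon_hdrA_frhD, operon_gap = as.integer(operon_gap),
      stem_gc = stem_gc, loop_a_prefix = as.integer(loop_a_prefix),
      utr_offset_range = as.integer(utr_offset_range),
      mutation_rate = mutation_rate, organism_id = organism_id
    ),
    class = "sim_config"
  )
}

random_dna <- function(n, gc) {
  if (n <= 0L) {
    return("")
  }
  paste(sample(c("G", "C", "A", "T"), n,
    replace = TRUE,
    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  ), collapse = "")
}

# one random stem side (5') plus its perfect reverse complement (3')
random_stem <- function(len, stem_gc) {
  side5 <- paste(sample(c("G", "C", "A", "T"), len,
    replace = TRUE,
    prob = c(stem_gc / 2, stem_gc / 2, (1 - stem_gc) / 2, (1 - stem_gc) / 2)
  ), collapse = "")
  list(side5 = side5, side3 = dna_revcomp(side5))
}

random_loop <- function(len, a_prefix) {
  a <- min(a_prefix, len)
  rest <- len - a
  paste0(
    strrep("A", a),
    if (rest > 0) paste(sample(c("A", "C", "T", "G"), rest, replace = TRUE), collapse = "") else ""
  )
}

# Build one SECIS element (DNA alphabet) for the given class, with perfect
# stems and a known pairing map.  Geometry is drawn uniformly within the
# model ranges and redrawn until the constructed element clears the model's
# own free-energy criterion: an element that cannot pass the filter it will
# be screened with is not a valid planted instance.
make_secis <- function(class, cfg, energy_threshold = -5.0, max_draws = 200L) {
  stem_pairs <- function(s5, s3, k) cbind(s5 + 0:(k - 1L), s3 + k - 1L - 0:(k - 1L))
  for (draw in seq_len(max_draws)) {
    if (class == "eSECIS_I") {
      k <- sample(7:15, 1)
      l <- sample(8:20, 1)
      st <- random_stem(k, cfg$stem_gc)
      core3 <- sample(c("GA", "AA"), 1)
      seq <- paste0(
        sample(c("A", "G"), 1), "T", "GA", sample(c("A", "C", "G", "T"), 1),
        st$side5, random_loop(l, cfg$loop_a_prefix), st$side3,
        sample(c("A", "C", "G", "T"), 1), core3,
        paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = "")
      )
      pairs <- stem_pairs(5L, 5L + k + l, k)
      params <- list(upper_stem = k, apical_loop = l, core3 = core3)
    } else if (class == "eSECIS_II") {
      k <- sample(6:14, 1)
      m <- sample(2:8, 1)
      b5 <- sample(3:6, 1)
      # apical loops below 3 nt cannot close a hairpin; sample the physical part
      ap <- sample(3:6, 1)
      b3 <- sample(1:6, 1)
      st <- random_stem(k, cfg$stem_gc)
      mini <- random_stem(m, cfg$stem_gc)
      core3 <- sample(c("GA", "AA"), 1)
      seq <- paste0(
        sample(c("A", "G"), 1), "T", "GA", sample(c("A", "C", "G", "T"), 1),
        st$side5, random_loop(b5, cfg$loop_a_prefix),
        mini$side5, random_loop(ap, 0L), mini$side3,
        random_loop(b3, 0L), st$side3,
        sample(c("A", "C", "G", "T"), 1), core3,
        paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = "")
      )
      m5s <- 5L + k + b5
      m3s <- m5s + m + ap
      s3s <- m3s + m + b3
      pairs <- rbind(stem_pairs(5L, s3s, k), stem_pairs(m5s, m3s, m))
      params <- list(
        upper_stem = k + 1L, ministem = m, bulge = b5 + b3,
        apical_loop = ap, core3 = core3
      )
    } else { # eaSECIS
      L <- sample(3:10, 1)
      U <- sample(3:6, 1)
      l <- sample(3:19, 1)
      lower <- random_stem(L, cfg$stem_gc)
      upper <- random_stem(U, cfg$stem_gc)
      seq <- paste0(
        lower$side5, "GAA", upper$side5, random_loop(l, cfg$loop_a_prefix),
        upper$side3, "A", lower$side3
      )
      u5s <- L + 3L
      u3s <- u5s + U + l
      pairs <- rbind(stem_pairs(0L, u3s + U + 1L, L), stem_pairs(u5s, u3s, U))
      params <- list(lower_stem = L, upper_stem = U, apical_loop = l)
    }
    dG <- energy(seq, pairs)
    if (is.finite(dG) && dG < energy_threshold) {
      params$dG <- dG
      return(list(seq = seq, class = class, params = params, pairs = pairs))
    }
  }
  stop(
    "could not draw a ", class, " element below ", energy_threshold,
    " kcal/mol in ", max_draws, " attempts; raise stem_gc"
  )
}

# reverse-translate a template protein; returns CDS including the TAA stop
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(SIM_CODON))
  if (length(bad) > 0) stop("template contains residues without a codon: ", paste(bad, collapse = ","))
  paste0(paste(SIM_CODON[aa], collapse = ""), "TAA")
}

mutate_cds <- function(cds, rate, sec_codon_idx) {
  if (rate <= 0) {
    return(cds)
  }
  ch <- strsplit(cds, "")[[1]]
  protected <- c(1:3, (3 * (sec_codon_idx - 1) + 1):(3 * sec_codon_idx),
    (length(ch) - 2):length(ch))
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, protected)
  for (k in hit) ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1)
  paste(ch, collapse = "")
}

#' Simulate one benchmark organism
#'
#' Generates background contigs at the configured GC, plants machinery
#' genes, selenoprotein genes (one in-frame TGA each) with a 3'-UTR SECIS
#' element of a class drawn from the configured mix, and optionally an
#' hdrA-frhD pair with a short same-strand intergenic gap.  Genes land on
#' random strands without overlap.  Every planted element is recorded in
#' the truth ledger; the emitted query proteins are the planted proteins
#' (with `U`), enabling identity-level search.
#'
#' @param config a [sim_config()].
#' @param out_dir when given, writes `<organism>.fasta`, `<organism>.gff3`,
#'   `<organism>_truth.tsv` and `<organism>_queries.fasta` there.
#' @return invisibly, a list with `genome` (DNAStringSet), `annotations`
#'   (`gene_annotation`), `truth` (data.frame), `queries` (named character),
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  cfg <- config

  # plan the cassettes -------------------------------------------------
  plan <- list()
  fams <- cfg$families
  if (cfg$operon_hdrA_frhD && all(c("HdrA", "FrhD") %in% names(fams)) &&
    fams[["HdrA"]] > 0 && fams[["FrhD"]] > 0) {
    n_op <- min(fams[["HdrA"]], fams[["FrhD"]])
    for (z in seq_len(n_op)) plan[[length(plan) + 1L]] <- list(kind = "operon")
    fams[["HdrA"]] <- fams[["HdrA"]] - n_op
    fams[["FrhD"]] <- fams[["FrhD"]] - n_op
  }
  for (fam in names(fams)) {
    for (z in seq_len(fams[[fam]])) {
      plan[[length(plan) + 1L]] <- list(kind = "sel", family = fam)
    }
  }
  for (mc in cfg$machinery) plan[[length(plan) + 1L]] <- list(kind = "machinery", component = mc)
  if (length(plan) > 0) plan <- plan[sample.int(length(plan))]

  # build cassette sequences -------------------------------------------
  truth <- list()
  ann <- list()
  queries <- character(0)
  cassettes <- list()
  sel_idx <- 0L
  for (p in plan) {
    if (p$kind == "machinery") {
      comp <- p$component
      if (comp == "tRNA-Sec") {
        cas <- list(
          seq = random_dna(93L, cfg$gc), parts = list(list(
            what = "machinery", label = "tRNA-Sec", component = comp,
            start = 0L, end = 93L, coding = FALSE
          ))
        )
      } else {
        prot <- gsub("U", "C", FAMILY_TEMPLATES[[if (comp == "SelD") "SelD" else "PrxL"]])
        prot <- substr(prot, 1, 60)
        cds <- reverse_translate(prot)
        cas <- list(seq = cds, parts = list(list(
          what = "machinery", label = MACHINERY_LABELS[[comp]], component = comp,
          start = 0L, end = nchar(cds), coding = TRUE
        )))
      }
      cassettes[[length(cassettes) + 1L]] <- cas
      next
    }
    if (p$kind == "sel") {
      cassettes[[length(cassettes) + 1L]] <- sel_gene_cassette(p$family, cfg)
      next
    }
    # operon: hdrA then frhD on the same strand, short gap, each with SECIS
    c1 <- sel_gene_cassette("HdrA", cfg)
    c2 <- sel_gene_cassette("FrhD", cfg)
    gap <- cfg$operon_gap
    shift <- function(parts, by) {
      lapply(parts, function(q) {
        q$start <- q$start + by
        q$end <- q$end + by
        if (!is.null(q$sec_start)) {
          q$sec_start <- q$sec_start + by
          q$sec_end <- q$sec_end + by
        }
        q
      })
    }
    # keep the genes adjacent: gene1, gap, gene2; both SECIS follow gene2
    g1 <- c1$parts[[1]]
    g2 <- c2$parts[[1]]
    utr1 <- substr(c1$seq, g1$end + 1L, nchar(c1$seq))
    seq <- paste0(
      substr(c1$seq, 1L, g1$end), random_dna(gap, cfg$gc), c2$seq,
      utr1
    )
    parts <- c(
      c1$parts[1], shift(c2$parts, g1$end + gap),
      shift(c1$parts[-1], gap + nchar(c2$seq))
    )
    cassettes[[length(cassettes) + 1L]] <- list(seq = seq, parts = parts, operon = TRUE)
  }

  # place cassettes on contigs ------------------------------------------
  contigs <- vapply(
    seq_len(cfg$n_contigs),
    function(k) random_dna(cfg$contig_length, cfg$gc), character(1)
  )
  names(contigs) <- sprintf("%s_contig%d", cfg$organism_id, seq_len(cfg$n_contigs))
  cursor <- stats::setNames(rep(1L, cfg$n_contigs), names(contigs))
  gene_counter <- 0L
  for (cas in cassettes) {
    strand <- sample(c("+", "-"), 1)
    len <- nchar(cas$seq)
    gap_before <- sample(80:250, 1)
    contig <- NULL
    for (ci in sample.int(cfg$n_contigs)) {
      if (cursor[ci] + gap_before + len + 50L <= cfg$contig_length) {
        contig <- ci
        break
      }
    }
    if (is.null(contig)) {
      stop("capacity error: planted cassettes exceed contig capacity; ",
        "increase contig_length or n_contigs")
    }
    at <- cursor[contig] + gap_before # 0-based insertion offset
    cname <- names(contigs)[contig]
    placed <- if (strand == "+") cas$seq else dna_revcomp(cas$seq)
    substr(contigs[contig], at + 1L, at + len) <- placed
    cursor[contig] <- at + len
    # map part coordinates
    for (q in cas$parts) {
      if (strand == "+") {
        gs <- at + q$start
        ge <- at + q$end
      } else {
        gs <- at + len - q$end
        ge <- at + len - q$start
      }
      if (q$what %in% c("gene", "machinery")) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("%s_g%03d", cfg$organism_id, gene_counter)
        ann[[length(ann) + 1L]] <- data.frame(
          contig_id = cname, start = gs, end = ge, strand = strand,
          gene_id = gid, product_label = q$label, coding = q$coding,
          stringsAsFactors = FALSE
        )
        if (q$what == "gene") {
          sel_idx <- sel_idx + 1L
          qid <- sprintf("%s|%s|%d", q$family, cfg$organism_id, sel_idx)
          queries[qid] <- q$protein
          if (strand == "+") {
            sec_s <- at + q$sec_start
            sec_e <- at + q$sec_end
          } else {
            sec_s <- at + len - q$sec_end
            sec_e <- at + len - q$sec_start
          }
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "gene", contig_id = cname, start = gs, end = ge,
            strand = strand, label = q$family, gene_id = gid,
            sec_codon_start = sec_s, sec_codon_end = sec_e,
            secis_class = NA_character_, params = NA_character_,
            stringsAsFactors = FALSE
          )
        } else {
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "machinery", contig_id = cname, start = gs, end = ge,
            strand = strand, label = q$component, gene_id = gid,
            sec_codon_start = NA_integer_, sec_codon_end = NA_integer_,
            secis_class = NA_character_, params = NA_character_,
            stringsAsFactors = FALSE
          )
        }
      } else { # secis
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "secis", contig_id = cname, start = gs, end = ge,
          strand = strand, label = q$class, gene_id = NA_character_,
          sec_codon_start = NA_integer_, sec_codon_end = NA_integer_,
          secis_class = q$class,
          params = paste(names(q$params), unlist(q$params), sep = "=", collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  genome <- Biostrings::DNAStringSet(contigs)
  annotations <- do.call(rbind, ann)
  annotations <- gene_annotation(
    annotations$contig_id, annotations$start, annotations$end,
    annotations$strand, annotations$gene_id, annotations$product_label,
    annotations$coding,
    genome = genome
  )
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(
    genome = genome, annotations = annotations, truth = truth,
    queries = queries, config = cfg
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, cfg$organism_id)
    write_fasta(genome, paste0(base, ".fasta"))
    write_gff3(annotations, paste0(base, ".gff3"))
    write_report(truth, paste0(base, "_truth.tsv"), "tsv")
    write_fasta(queries, paste0(base, "_queries.fasta"))
    out$files <- paste0(base, c(".fasta", ".gff3", "_truth.tsv", "_queries.fasta"))
  }
  invisible(out)
}

# one selenoprotein gene + its 3'-UTR SECIS, as a forward-strand cassette
sel_gene_cassette <- function(family, cfg) {
  protein <- FAMILY_TEMPLATES[[family]]
  sec_codon_idx <- regexpr("U", protein)[1]
  cds <- reverse_translate(protein)
  cds <- mutate_cds(cds, cfg$mutation_rate, sec_codon_idx)
  secis_class <- sample(names(cfg$secis_mix), 1, prob = cfg$secis_mix)
  secis <- make_secis(secis_class, cfg)
  offset <- sample(cfg$utr_offset_range[1]:cfg$utr_offset_range[2], 1)
  seq <- paste0(cds, random_dna(offset, cfg$gc), secis$seq, random_dna(20L, cfg$gc))
  parts <- list(
    list(
      what = "gene", label = tolower_first(family), family = family,
      start = 0L, end = nchar(cds), coding = TRUE, protein = protein,
      sec_start = 3L * (sec_codon_idx - 1L), sec_end = 3L * sec_codon_idx
    ),
    list(
      what = "secis", class = secis_class, params = secis$params,
      start = nchar(cds) + offset, end = nchar(cds) + offset + nchar(secis$seq)
    )
  )
  list(seq = seq, parts = parts)
}

tolower_first <- function(x) paste0(tolower(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# ---------------------------------------------------------------------------
# Negative controls
# ---------------------------------------------------------------------------

#' Dinucleotide-preserving shuffle (negative controls)
#'
#' Shuffles each sequence while preserving its exact mono- and dinucleotide
#' composition (random Eulerian walk over the dinucleotide transition
#' multigraph, Altschul-Erickson style), destroying planted structure.
#'
#' @param seqs character vector / `DNAStringSet` of windows or contigs.
#' @param seed RNG seed for reproducibility.
#' @return shuffled sequences, same type/names as the input.
#' @export
shuffle_negative_controls <- function(seqs, seed = 1L) {
  was_set <- is(seqs, "DNAStringSet")
  nm <- names(seqs)
  ch <- as.character(seqs)
  set.seed(seed)
  out <- vapply(ch, dinucleotide_shuffle_one, character(1), USE.NAMES = FALSE)
  names(out) <- nm
  if (was_set) Biostrings::DNAStringSet(out) else out
}

dinucleotide_shuffle_one <- function(s) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (n < 3L) {
    return(s)
  }
  verts <- unique(v)
  edges <- lapply(stats::setNames(verts, verts), function(u) v[which(v[-n] == u) + 1L])
  last <- v[n]
  # draw a "last edge" tree pointing toward the terminal vertex, redrawing
  # until the tree is connected (Kandel et al. swap-free Eulerian sampling)
  repeat {
    last_edge <- vapply(verts, function(u) {
      if (u == last || length(edges[[u]]) == 0L) NA_character_ else sample(edges[[u]], 1)
    }, character(1))
    ok <- TRUE
    for (u in verts) {
      if (u == last || is.na(last_edge[[u]])) next
      # follow last edges; must reach `last`
      cur <- u
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle remaining edges, append the reserved last edge
  pool <- lapply(stats::setNames(verts, verts), function(u) {
    e <- edges[[u]]
    if (u != last && !is.na(last_edge[[u]])) {
      drop <- match(last_edge[[u]], e)
      e <- e[-drop]
    }
    if (length(e) > 1L) e <- sample(e)
    if (u != last && !is.na(last_edge[[u]])) e <- c(e, last_edge[[u]])
    e
  })
  used <- stats::setNames(rep(0L, length(verts)), verts)
  out <- character(n)
  out[1] <- v[1]
  cur <- v[1]
  for (k in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- pool[[cur]][used[cur]]
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
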