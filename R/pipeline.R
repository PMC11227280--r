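# End-to-end orchestration.  Each stage is exposed as a cmd_* function with
# file inputs/outputs, deterministic primary outputs, and a JSON run
# manifest (no timestamps, so reruns are byte-identical).  A thin Rscript
# front-end over these functions lives in inst/scripts/secisscan.R.

#' Assemble a resolved run configuration
#'
#' All tunable thresholds of the pipeline live in one namespace; the
#' defaults are the published analysis values (energy threshold -5.0
#' kcal/mol, e-value/coverage cutoffs, 35 aa length filter, operon gap,
#' two-part trait criterion).  The resolved configuration is serialized
#' verbatim into the output directory for provenance.
#'
#' @param ... overrides of any default field.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    energy_threshold = -5.0,
    tblastn_evalue = 0.01,
    min_alignment_coverage = 0.25,
    hmm_evalue = 0.05,
    ortholog_evalue = 0.001,
    min_protein_len_aa = 35L,
    operon_labels = c("hdrA", "frhD"),
    operon_max_gap_nt = 60L,
    trait_min_machinery = 3L,
    trait_min_selenoproteins = 1L,
    strict_trna = FALSE,
    utr_upstream = 30L,
    utr_downstream = 600L,
    sec_stop_bonus = 8,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) stop("unknown config field: ", paste(unknown, collapse = ","))
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_thresholds <- function(cfg) {
  search_thresholds(
    tblastn_evalue = cfg$tblastn_evalue,
    min_alignment_coverage = cfg$min_alignment_coverage,
    hmm_evalue = cfg$hmm_evalue,
    ortholog_evalue = cfg$ortholog_evalue,
    min_protein_len_aa = cfg$min_protein_len_aa
  )
}

write_manifest <- function(out_dir, stage, inputs, outputs, cfg) {
  # record file names, not absolute paths, so identical runs in different
  # directories stay byte-identical
  strip <- function(x) {
    if (is.character(x)) basename(x) else x
  }
  manifest <- list(
    tool = "secisscan",
    version = as.character(utils::packageVersion("secisscan")),
    stage = stage,
    inputs = lapply(inputs, strip),
    outputs = lapply(outputs, strip),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

log_msg <- function(...) message("[secisscan] ", sprintf(...))

candidates_to_table <- function(cands) {
  if (length(cands) == 0L) {
    return(data.frame(
      contig_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0), model_class = character(0),
      core5 = character(0), core3 = character(0), dG = numeric(0),
      coexisting = logical(0), sequence = character(0),
      dot_bracket = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(cands, function(x) {
    data.frame(
      contig_id = if (is.null(x$contig_id)) NA_character_ else x$contig_id,
      start = if (is.null(x$genomic_start)) x$start else x$genomic_start,
      end = if (is.null(x$genomic_end)) x$end else x$genomic_end,
      strand = if (is.null(x$strand)) "+" else x$strand,
      gene_id = if (is.null(x$gene_id)) NA_character_ else x$gene_id,
      model_class = x$model_class, core5 = x$core5, core3 = x$core3,
      dG = x$dG, coexisting = isTRUE(x$coexisting),
      sequence = x$sequence, dot_bracket = x$dot_bracket,
      stringsAsFactors = FALSE
    )
  }))
}

#' Scan annotated genes for 3'-UTR SECIS candidates
#'
#' For every coding annotation: extract the scan window around the gene 3'
#' end, run the three structural models, filter by energy, and report
#' accepted candidates in genomic coordinates.
#'
#' @param genome_fasta genome FASTA path (or a loaded `DNAStringSet`).
#' @param annotations GFF3 path (or a `gene_annotation` data.frame).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return invisibly, the candidate table (also written as TSV and BED).
#' @export
cmd_scan_secis <- function(genome_fasta, annotations, out_dir,
                           config = run_config()) {
  genome <- if (is.character(genome_fasta)) read_fasta(genome_fasta) else genome_fasta
  ann <- if (is.character(annotations)) read_gff3(annotations, genome) else annotations
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- secis_models()
  for (cls in names(models)) models[[cls]]$energy_threshold <- config$energy_threshold
  all_cands <- list()
  genes <- ann[ann$coding, , drop = FALSE]
  for (k in seq_len(nrow(genes))) {
    w <- extract_utr3_window(genome, genes[k, ],
      upstream = config$utr_upstream, downstream = config$utr_downstream
    )
    cands <- scan_window(w, models)
    for (cand in cands) {
      cand$gene_id <- genes$gene_id[k]
      all_cands[[length(all_cands) + 1L]] <- cand
    }
  }
  tab <- candidates_to_table(all_cands)
  tsv <- file.path(out_dir, "secis_candidates.tsv")
  bed <- file.path(out_dir, "secis_candidates.bed")
  write_report(tab, tsv, "tsv")
  write_report(
    data.frame(
      contig_id = tab$contig_id, start = tab$start, end = tab$end,
      name = tab$model_class, score = rep(0, nrow(tab)), strand = tab$strand,
      stringsAsFactors = FALSE
    ),
    bed, "bed"
  )
  counts <- table(factor(tab$model_class, levels = SECIS_CLASSES))
  log_msg(
    "scan-secis: %d genes scanned; candidates: %s", nrow(genes),
    paste(names(counts), as.integer(counts), sep = "=", collapse = " ")
  )
  write_manifest(out_dir, "scan_secis",
    inputs = list(
      genome = if (is.character(genome_fasta)) genome_fasta else "<in-memory>",
      annotations = if (is.character(annotations)) annotations else "<in-memory>"
    ),
    outputs = list(tsv = tsv, bed = bed), cfg = config
  )
  invisible(tab)
}

#' Find selenoprotein genes from queries or a precomputed alignment table
#'
#' With protein queries: aligns each query against each contig in all six
#' frames (self-contained Smith-Waterman).  With a tabular alignment file:
#' reads it directly.  Alignments below the thresholds are excluded from
#' hit calling.  Sec/TGA pairs are verified against the genome, ORFs are
#' extended with UGA read-through, hits deduplicated per Sec codon.
#'
#' @param genome_fasta genome FASTA path (or `DNAStringSet`).
#' @param queries protein FASTA path / named character vector, or `NULL`.
#' @param alignment_table tabular alignment path (used when `queries` is
#'   `NULL`).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, the hit table (written as TSV; Sec codons as BED).
#' @export
cmd_find_selenoproteins <- function(genome_fasta, queries = NULL,
                                    alignment_table = NULL, out_dir,
                                    config = run_config()) {
  genome <- if (is.character(genome_fasta)) read_fasta(genome_fasta) else genome_fasta
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- config_thresholds(config)
  if (is.null(queries) && is.null(alignment_table)) {
    stop("need either protein queries or an alignment table")
  }
  aln <- if (!is.null(queries)) {
    qs <- if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
      read_protein_fasta(queries)
    } else {
      queries
    }
    do.call(rbind, unlist(lapply(names(qs), function(qid) {
      lapply(names(genome), function(cid) {
        local_align_all_hits(qs[[qid]], genome,
          query_id = qid,
          subject_id = cid, sec_stop_bonus = config$sec_stop_bonus,
          thresholds = thresholds
        )
      })
    }), recursive = FALSE))
  } else {
    read_tabular_alignments(alignment_table, thresholds)
  }
  hits <- list()
  usable <- aln[!aln$below_threshold, , drop = FALSE]
  for (k in seq_len(nrow(usable))) {
    rec <- usable[k, , drop = FALSE]
    prs <- find_sec_tga_pairs(rec, genome)
    for (z in seq_len(nrow(prs))) {
      orf <- extend_orf(genome, prs$codon_start[z], prs$strand[z],
        contig_id = rec$sseqid
      )
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = rec$sseqid, query_id = rec$qseqid,
        query_sec_pos = prs$query_sec_pos[z],
        codon_start = prs$codon_start[z], codon_end = prs$codon_end[z],
        strand = prs$strand[z],
        orf_start = orf$orf_start, orf_end = orf$orf_end,
        protein = orf$protein,
        start_missing = orf$start_missing, stop_missing = orf$stop_missing,
        evalue = rec$evalue, bitscore = rec$bitscore,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else {
    data.frame(
      contig_id = character(0), query_id = character(0),
      query_sec_pos = integer(0), codon_start = integer(0),
      codon_end = integer(0), strand = character(0), orf_start = integer(0),
      orf_end = integer(0), protein = character(0),
      start_missing = logical(0), stop_missing = logical(0),
      evalue = numeric(0), bitscore = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  hits <- assign_family(hits, thresholds = thresholds)
  # invariant: every reported Sec codon re-reads as TGA from the genome
  if (nrow(hits) > 0) {
    ok <- vapply(seq_len(nrow(hits)), function(k) {
      cd <- substr(
        contig_seq(genome, hits$contig_id[k]),
        hits$codon_start[k], hits$codon_end[k]
      )
      if (hits$strand[k] == "-") cd <- dna_revcomp(cd)
      cd == "TGA"
    }, logical(1))
    stopifnot(all(ok))
  }
  tsv <- file.path(out_dir, "selenoprotein_hits.tsv")
  bed <- file.path(out_dir, "sec_codons.bed")
  write_report(hits, tsv, "tsv")
  write_report(
    data.frame(
      contig_id = hits$contig_id, start = hits$codon_start - 1L,
      end = hits$codon_end, name = hits$family, score = rep(0, nrow(hits)),
      strand = hits$strand, stringsAsFactors = FALSE
    ),
    bed, "bed"
  )
  tally <- table(hits$family)
  log_msg(
    "find-selenoproteins: %d hits (%s)", nrow(hits),
    paste(names(tally), as.integer(tally), sep = "=", collapse = " ")
  )
  write_manifest(out_dir, "find_selenoproteins",
    inputs = list(
      genome = if (is.character(genome_fasta)) genome_fasta else "<in-memory>",
      queries = if (is.character(queries) && length(queries) == 1L) queries else "<in-memory>",
      alignment_table = alignment_table
    ),
    outputs = list(tsv = tsv, bed = bed), cfg = config
  )
  invisible(hits)
}

#' Classify the Sec-utilization trait per organism
#'
#' Machinery presence is read from annotation product labels
#' (`secS`, `efSec`, `pstk`, `selD`, `tRNA-Sec`, case-insensitive);
#' selenoprotein counts come from a hit table.  Input order is preserved.
#'
#' @param organisms named list: organism id -> list(annotations=, hits=)
#'   where `annotations` is a GFF3 path or `gene_annotation` and `hits` a
#'   hit table (data.frame) or its TSV path.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, a data.frame of verdicts (also written TSV + JSON).
#' @export
cmd_classify_trait <- function(organisms, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  label_map <- c(
    secs = "SecS", efsec = "EFSec", pstk = "PSTK", seld = "SelD",
    `trna-sec` = "tRNA-Sec"
  )
  rows <- list()
  reports <- list()
  for (org in names(organisms)) {
    spec <- organisms[[org]]
    ann <- if (is.character(spec$annotations)) read_gff3(spec$annotations) else spec$annotations
    hits <- if (is.character(spec$hits)) read_report(spec$hits, "tsv") else spec$hits
    labels <- tolower(ann$product_label)
    machinery <- unname(label_map[intersect(names(label_map), labels)])
    n_sel <- if (is.null(hits)) 0L else nrow(hits)
    rep <- classify_sec_trait(machinery, n_sel,
      strict_trna = config$strict_trna,
      min_machinery = config$trait_min_machinery,
      min_selenoproteins = config$trait_min_selenoproteins,
      organism_id = org
    )
    reports[[org]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      organism_id = org,
      t(as.integer(rep$machinery)),
      machinery_count = rep$machinery_count,
      n_selenoproteins = rep$n_selenoproteins,
      verdict = rep$verdict,
      reasons = paste(rep$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) names(tab)[2:6] <- SEC_MACHINERY
  tsv <- file.path(out_dir, "sec_trait.tsv")
  json <- file.path(out_dir, "sec_trait.json")
  write_report(tab, tsv, "tsv")
  jsonlite::write_json(
    lapply(reports, function(r) {
      list(
        organism_id = r$organism_id, machinery = as.list(r$machinery),
        machinery_count = r$machinery_count,
        n_selenoproteins = r$n_selenoproteins, verdict = r$verdict,
        reasons = r$reasons
      )
    }),
    json,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  log_msg(
    "classify-trait: %d organisms, %d Sec+", length(organisms),
    sum(vapply(reports, function(r) r$verdict == "Sec+", logical(1)))
  )
  write_manifest(out_dir, "classify_trait",
    inputs = list(organisms = names(organisms)),
    outputs = list(tsv = tsv, json = json), cfg = config
  )
  invisible(tab)
}

#' Motif-composition statistics over a candidate table
#'
#' Rebuilds core and adenine-region composition profiles from a SECIS
#' candidate table ([cmd_scan_secis()] output), overall and stratified by
#' the family label encoded in `gene_id`/`family` when present.
#'
#' @param candidates candidate table (data.frame) or its TSV path.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, the long-format profile table (written TSV).
#' @export
cmd_logo_stats <- function(candidates, out_dir, config = run_config()) {
  tab <- if (is.character(candidates)) read_report(candidates, "tsv") else candidates
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # rebuild minimal candidate objects from the table
  cands <- lapply(seq_len(NROW(tab)), function(k) {
    structure(
      list(
        model_class = tab$model_class[k], core5 = tab$core5[k],
        core3 = tab$core3[k],
        adenine_run = adenine_run_from_row(tab[k, ])
      ),
      class = "secis_candidate"
    )
  })
  strata <- c(list(all = cands), split(cands, vapply(cands, function(x) x$model_class, character(1))))
  rows <- list()
  for (st in names(strata)) {
    for (region in c("core", "apical_adenines")) {
      prof <- composition_profiles(strata[[st]], region)
      if (prof$empty) next
      for (p in seq_len(ncol(prof$freq))) {
        for (b in rownames(prof$freq)) {
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = st, region = region, position = p, base = b,
            count = prof$counts[b, p], freq = prof$freq[b, p],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    stratum = character(0), region = character(0), position = integer(0),
    base = character(0), count = integer(0), freq = numeric(0),
    stringsAsFactors = FALSE
  )
  tsv <- file.path(out_dir, "composition_profiles.tsv")
  write_report(out, tsv, "tsv")
  if (NROW(tab) == 0L) log_msg("logo-stats: empty candidate table, empty profile flagged")
  write_manifest(out_dir, "logo_stats",
    inputs = list(candidates = if (is.character(candidates)) candidates else "<in-memory>"),
    outputs = list(tsv = tsv), cfg = config
  )
  invisible(out)
}

# the adenine region is recoverable from the candidate sequence + structure
adenine_run_from_row <- function(row) {
  db <- strsplit(row$dot_bracket, "")[[1]]
  seqc <- strsplit(chartr("T", "U", row$sequence), "")[[1]]
  open <- which(db == "(")
  close <- which(db == ")")
  if (length(open) == 0L) {
    return("")
  }
  if (row$model_class == "eSECIS_II") {
    # bulge between upper stem and ministem: after the outer helix's 5' side
    helix_break <- which(diff(open) > 1L)
    first_gap_start <- if (length(helix_break) > 0) open[helix_break[1]] + 1L else max(open) + 1L
    run_end <- min(first_gap_start + 4L, length(seqc))
    paste(seqc[first_gap_start:run_end], collapse = "")
  } else {
    # apical loop: between innermost ( and innermost )
    lo <- max(open) + 1L
    hi <- min(close) - 1L
    if (lo > hi) {
      return("")
    }
    paste(seqc[lo:min(hi, lo + 4L)], collapse = "")
  }
}

#' Generate benchmark data
#'
#' Thin wrapper over [simulate_genome()] supporting several organisms with
#' derived seeds.
#'
#' @param config a [sim_config()] (or YAML path of overrides).
#' @param out_dir output directory.
#' @param n_organisms how many organisms to generate (seeds `seed`,
#'   `seed+1`, ...; ids suffixed).
#' @return invisibly, list of simulation results.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir, n_organisms = 1L) {
  if (is.character(config)) config <- do.call(sim_config, yaml::read_yaml(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_len(n_organisms), function(k) {
    cfg <- config
    cfg$seed <- config$seed + (k - 1L)
    if (n_organisms > 1L) cfg$organism_id <- sprintf("%s_%d", config$organism_id, k)
    simulate_genome(cfg, out_dir)
  })
  log_msg("simulate: %d organism(s) written to %s", n_organisms, out_dir)
  invisible(res)
}
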