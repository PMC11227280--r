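# Structural models of archaeal SECIS elements and the scan that applies
# them.  Three classes are modelled:
#
#   eSECIS_I  - eukaryote-type, no ministem: GA_[G/A]A quartet core, upper
#               stem 7-15 bp (<=2 mismatches), apical loop 8-20 nt
#   eSECIS_II - eukaryote-type with ministem: same core and upper stem,
#               ministem 2-8 bp (<=1 mismatch), 4-12 nt bulge between upper
#               stem and ministem, apical loop 2-6 nt
#   eaSECIS   - euryarchaeal-type: lower stem 3-10 bp, upper stem 3-6 bp,
#               GAA_A bulge between the stems, apical loop 3-19 nt
#
# Matching uses the three structured-motif patterns; accepted candidates
# must also validate against the model constraints and clear the free-energy
# filter (default < -5.0 kcal/mol).

SECIS_CLASSES <- c("eSECIS_I", "eSECIS_II", "eaSECIS")

BUILTIN_PATTERN_TEXT <- c(
  eSECIS_I = "r1={au,ua,gc,cg,gu,ug} NNGAN p1=7...15 8...20 r1~p1[2,1,1] (NGANN | NAANN)",
  eSECIS_II = "r1={au,ua,gc,cg,gu,ug} NNGAN p1=6...14 3...6 p2=2...8 2...6 r1~p2[1,1,1] 1...6 r1~p1[2,1,1] (NGANN | NAANN)",
  eaSECIS = "r1={au,ua,gc,cg,gu,ug} p1=3...10 GAA p2=3...6 3...19 r1~p2[0,1,1] A r1~p1[1,1,1]"
)

#' Built-in SECIS search patterns
#'
#' The three structured-motif patterns for type I / type II eukaryote-like
#' and euryarchaeal-like SECIS elements, parsed and ready for
#' [match_all()].
#'
#' @return named list of `pattern_spec` objects
#'   (`eSECIS_I`, `eSECIS_II`, `eaSECIS`).
#' @export
builtin_patterns <- function() {
  lapply(BUILTIN_PATTERN_TEXT, parse_pattern)
}

#' Default SECIS model parameters
#'
#' @param model_class one of `"eSECIS_I"`, `"eSECIS_II"`, `"eaSECIS"`.
#' @param ... overrides of individual parameter fields.
#' @return a `secis_model_params` list.
#' @export
secis_params <- function(model_class = SECIS_CLASSES, ...) {
  model_class <- match.arg(model_class)
  p <- switch(model_class,
    eSECIS_I = list(
      model_class = "eSECIS_I",
      core5 = "GA", core3 = c("GA", "AA"),
      upper_stem = c(7L, 15L), upper_stem_mismatches = 2L,
      apical_loop = c(8L, 20L),
      energy_threshold = -5.0
    ),
    eSECIS_II = list(
      model_class = "eSECIS_II",
      core5 = "GA", core3 = c("GA", "AA"),
      upper_stem = c(7L, 15L), upper_stem_mismatches = 2L,
      ministem = c(2L, 8L), ministem_mismatches = 1L,
      bulge = c(4L, 12L), apical_loop = c(2L, 6L),
      energy_threshold = -5.0
    ),
    eaSECIS = list(
      model_class = "eaSECIS",
      bulge5 = "GAA", bulge3 = "A",
      lower_stem = c(3L, 10L), upper_stem = c(3L, 6L),
      apical_loop = c(3L, 19L),
      energy_threshold = -5.0
    )
  )
  override <- list(...)
  for (nm in names(override)) p[[nm]] <- override[[nm]]
  structure(p, class = "secis_model_params")
}

#' All three SECIS models with default parameters
#' @return named list of `secis_model_params`.
#' @export
secis_models <- function() {
  stats::setNames(lapply(SECIS_CLASSES, secis_params), SECIS_CLASSES)
}

# ---------------------------------------------------------------------------
# Candidate construction from a pattern match
# ---------------------------------------------------------------------------

# element indices per class (order of elements in the built-in patterns)
.ELEM_IDX <- list(
  eSECIS_I = list(lit = 1L, p1 = 2L, apical = 3L, q1 = 4L, alt = 5L),
  eSECIS_II = list(
    lit = 1L, p1 = 2L, bulge5 = 3L, p2 = 4L, apical = 5L,
    q2 = 6L, bulge3 = 7L, q1 = 8L, alt = 9L
  ),
  eaSECIS = list(
    p1 = 1L, gaa = 2L, p2 = 3L, apical = 4L, q2 = 5L, a3 = 6L, q1 = 7L
  )
)

substr_iv <- function(seq, iv) substr(seq, iv[1] + 1L, iv[2])

# Build a secis_candidate from a pattern match on an RNA string.
build_candidate <- function(seq, match, model_class) {
  ix <- .ELEM_IDX[[model_class]]
  iv <- match$intervals
  get_bref <- function(k) match$backrefs[[k]]
  cand <- list(
    model_class = model_class,
    start = match$start, end = match$end,
    sequence = substr(seq, match$start + 1L, match$end)
  )
  if (model_class %in% c("eSECIS_I", "eSECIS_II")) {
    lit <- substr_iv(seq, iv[ix$lit, ])
    alt <- substr_iv(seq, iv[ix$alt, ])
    cand$core5 <- substr(lit, 1L, 4L)             # NNGA context (e.g. AUGA)
    cand$core3 <- substr(alt, 2L, 3L)             # GA or AA
    b1 <- get_bref(ix$q1)
    cand$upper_stem_pairs <- b1$pairs
    cand$upper_stem_len <- iv[ix$p1, 2] - iv[ix$p1, 1] +
      (if (model_class == "eSECIS_II") 1L else 0L)
    cand$upper_stem_mismatches <- b1$mismatches
    if (model_class == "eSECIS_I") {
      cand$apical_loop <- substr_iv(seq, iv[ix$apical, ])
      cand$adenine_run <- substr(cand$apical_loop, 1L, 5L)
      cand$pairs <- b1$pairs
    } else {
      b2 <- get_bref(ix$q2)
      cand$ministem_pairs <- b2$pairs
      cand$ministem_len <- iv[ix$p2, 2] - iv[ix$p2, 1]
      cand$ministem_mismatches <- b2$mismatches
      cand$bulge_len <- (iv[ix$bulge5, 2] - iv[ix$bulge5, 1]) +
        (iv[ix$bulge3, 2] - iv[ix$bulge3, 1])
      cand$apical_loop <- substr_iv(seq, iv[ix$apical, ])
      # the conserved adenines sit in the bulge between upper stem and ministem
      cand$adenine_run <- substr(substr_iv(seq, iv[ix$bulge5, ]), 1L, 5L)
      cand$pairs <- rbind(b1$pairs, b2$pairs)
    }
  } else {
    b1 <- get_bref(ix$q1)
    b2 <- get_bref(ix$q2)
    cand$lower_stem_pairs <- b1$pairs
    cand$lower_stem_len <- iv[ix$p1, 2] - iv[ix$p1, 1]
    cand$lower_stem_mismatches <- b1$mismatches
    cand$upper_stem_pairs <- b2$pairs
    cand$upper_stem_len <- iv[ix$p2, 2] - iv[ix$p2, 1]
    cand$upper_stem_mismatches <- b2$mismatches
    cand$bulge5 <- substr_iv(seq, iv[ix$gaa, ])
    cand$bulge3 <- substr_iv(seq, iv[ix$a3, ])
    # core context: 2 nt of lower stem preceding the GAA bulge, plus the GA
    # it opens with; 3' side reads the base preceding the unpaired A
    p1s <- substr_iv(seq, iv[ix$p1, ])
    cand$core5 <- paste0(
      substr(p1s, nchar(p1s) - 1L, nchar(p1s)),
      substr(cand$bulge5, 1L, 2L)
    )
    q2s <- substr_iv(seq, iv[ix$q2, ])
    cand$core3 <- paste0(substr(q2s, nchar(q2s), nchar(q2s)), cand$bulge3)
    cand$apical_loop <- substr_iv(seq, iv[ix$apical, ])
    cand$adenine_run <- substr(cand$apical_loop, 1L, 5L)
    cand$pairs <- rbind(b1$pairs, b2$pairs)
  }
  cand$match <- match
  cand$dot_bracket <- to_dot_bracket(match)
  class(cand) <- "secis_candidate"
  cand
}

#' @export
print.secis_candidate <- function(x, ...) {
  cat(sprintf(
    "<secis_candidate> %s [%d,%d) core %s..%s dG=%s\n  %s\n  %s\n",
    x$model_class, x$start, x$end, x$core5, x$core3,
    if (is.null(x$dG)) "?" else format(x$dG), x$sequence, x$dot_bracket
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation against model constraints
# ---------------------------------------------------------------------------

#' Validate a candidate structure against its SECIS model
#'
#' Checks every length range, mismatch budget and core-motif constraint of
#' the model; the reject reasons enumerate each violated constraint.
#'
#' @param cand a `secis_candidate` (from [scan_window()] internals or
#'   [build_candidate] on a match).
#' @param params a `secis_model_params`; defaults to the candidate's class
#'   defaults.
#' @return list with `accept` (logical) and `reasons` (character).
#' @export
validate_candidate <- function(cand, params = secis_params(cand$model_class)) {
  reasons <- character(0)
  chk_range <- function(val, rng, what) {
    if (val < rng[1] || val > rng[2]) {
      sprintf("%s %d-%d (got %d)", what, rng[1], rng[2], val)
    } else {
      character(0)
    }
  }
  chk_budget <- function(val, budget, what) {
    if (val > budget) sprintf("%s mismatches <=%d (got %d)", what, budget, val) else character(0)
  }
  if (cand$model_class %in% c("eSECIS_I", "eSECIS_II")) {
    if (substr(cand$core5, 3L, 4L) != params$core5) {
      reasons <- c(reasons, sprintf("core must read %s on the 5' side", params$core5))
    }
    if (!cand$core3 %in% params$core3) {
      reasons <- c(reasons, sprintf(
        "core must read %s on the 3' side",
        paste(params$core3, collapse = "/")
      ))
    }
    reasons <- c(
      reasons,
      chk_range(cand$upper_stem_len, params$upper_stem, "upper stem"),
      chk_budget(cand$upper_stem_mismatches, params$upper_stem_mismatches, "upper stem"),
      chk_range(nchar(cand$apical_loop), params$apical_loop, "apical loop")
    )
    if (cand$model_class == "eSECIS_II") {
      reasons <- c(
        reasons,
        chk_range(cand$ministem_len, params$ministem, "ministem"),
        chk_budget(cand$ministem_mismatches, params$ministem_mismatches, "ministem"),
        chk_range(cand$bulge_len, params$bulge, "bulge")
      )
    }
  } else {
    if (cand$bulge5 != params$bulge5 || cand$bulge3 != params$bulge3) {
      reasons <- c(reasons, "bulge must read GAA on the 5' side and A on the 3' side")
    }
    reasons <- c(
      reasons,
      chk_range(cand$lower_stem_len, params$lower_stem, "lower stem"),
      chk_range(cand$upper_stem_len, params$upper_stem, "upper stem"),
      chk_range(nchar(cand$apical_loop), params$apical_loop, "apical loop")
    )
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

# ---------------------------------------------------------------------------
# Window scan
# ---------------------------------------------------------------------------

#' Scan a 3'-UTR window for SECIS candidates
#'
#' Runs the structured-motif patterns over the window, builds candidate
#' structures, validates them against the model constraints, evaluates the
#' fixed-structure free energy and keeps candidates below the threshold.
#' Overlapping candidates of one class collapse to the lowest-energy one
#' (ties: leftmost start, then longer upper stem).  Where type I and type II
#' both survive on one locus, both are reported, flagged `coexisting`.
#'
#' @param window a `utr3_window` from [extract_utr3_window()], or a plain
#'   RNA string.
#' @param models list of `secis_model_params` to apply (default all three).
#' @param patterns matching `pattern_spec`s (default [builtin_patterns()]).
#' @return list of accepted `secis_candidate` objects, sorted by start; each
#'   carries `dG`, `dot_bracket` and (when the input was a `utr3_window`)
#'   genomic coordinates.
#' @export
scan_window <- function(window, models = secis_models(),
                        patterns = builtin_patterns()) {
  seq <- if (inherits(window, "utr3_window")) window$sequence else normalize_match_seq(window)
  out <- list()
  for (cls in names(models)) {
    params <- models[[cls]]
    spec <- patterns[[cls]]
    if (is.null(spec)) stop("no pattern for model class ", cls)
    cands <- scan_class_candidates(seq, cls, params, spec)
    out <- c(out, dedup_candidates(cands))
  }
  if (length(out) == 0L) {
    return(list())
  }
  # flag loci where type I and type II co-validate
  out <- flag_coexisting(out)
  if (inherits(window, "utr3_window")) {
    out <- lapply(out, function(cand) {
      g <- window_to_genomic(window, cand$start, cand$end)
      cand$contig_id <- window$contig_id
      cand$genomic_start <- g[1]
      cand$genomic_end <- g[2]
      cand$strand <- window$strand
      cand
    })
  }
  out[order(vapply(out, function(x) x$start, numeric(1)))]
}

# Columnar scan of one model class over a window: run the matcher once,
# validate all matches vectorised, batch-evaluate energies, and build full
# candidate objects only for the survivors.  Semantically identical to
# mapping build_candidate + validate_candidate + energy over match_all
# output (asserted by the acceptance-soundness tests), but fast enough for
# hundreds of 630-nt windows.
scan_class_candidates <- function(seq, cls, params, spec) {
  raw <- .engine_scan(compile_pattern_spec(spec), seq)
  if (raw$n == 0L) {
    return(list())
  }
  ix <- .ELEM_IDX[[cls]]
  iv <- raw$intervals
  len_of <- function(k) iv[, 2L * k] - iv[, 2L * k - 1L]
  stats_of <- function(k) raw$backref_stats[[match(k, raw$backref_elems)]]
  in_range <- function(v, rng) v >= rng[1] & v <= rng[2]
  if (cls == "eSECIS_I") {
    ok <- in_range(len_of(ix$p1), params$upper_stem) &
      stats_of(ix$q1)[, 1] <= params$upper_stem_mismatches &
      in_range(len_of(ix$apical), params$apical_loop)
  } else if (cls == "eSECIS_II") {
    ok <- in_range(len_of(ix$p1) + 1L, params$upper_stem) &
      stats_of(ix$q1)[, 1] <= params$upper_stem_mismatches &
      in_range(len_of(ix$p2), params$ministem) &
      stats_of(ix$q2)[, 1] <= params$ministem_mismatches &
      in_range(len_of(ix$bulge5) + len_of(ix$bulge3), params$bulge) &
      in_range(len_of(ix$apical), params$apical_loop)
  } else {
    ok <- in_range(len_of(ix$p1), params$lower_stem) &
      in_range(len_of(ix$p2), params$upper_stem) &
      in_range(len_of(ix$apical), params$apical_loop)
  }
  dg <- .energy_batch(seq, raw$pairs, raw$n, energy_tables())
  keep <- which(ok & is.finite(dg) & dg < params$energy_threshold)
  if (length(keep) == 0L) {
    return(list())
  }
  # collapse overlapping survivors to the energy-optimal one per locus
  # before building rich candidate objects (ties: leftmost start, then
  # longer upper stem) - same rule as dedup_candidates
  starts <- raw$start[keep]
  ends <- raw$end[keep]
  stems <- len_of(if (cls == "eaSECIS") ix$p2 else ix$p1)[keep] +
    (cls == "eSECIS_II")
  winners <- integer(0)
  ord <- order(starts, ends)
  cur_end <- -1L
  cluster <- integer(length(keep))
  cur <- 0L
  for (z in ord) {
    if (starts[z] >= cur_end) {
      cur <- cur + 1L
      cur_end <- ends[z]
    } else {
      cur_end <- max(cur_end, ends[z])
    }
    cluster[z] <- cur
  }
  for (idx in split(seq_along(keep), cluster)) {
    best <- idx[order(dg[keep[idx]], starts[idx], -stems[idx])][1]
    winners <- c(winners, keep[best])
  }
  winners <- sort(winners)
  # per-match row offsets into the flat pairs matrix
  counts <- tabulate(raw$pairs[, 1], nbins = raw$n)
  offs <- cumsum(c(0L, counts))
  lapply(winners, function(r) {
    rows <- if (counts[r] > 0L) (offs[r] + 1L):(offs[r] + counts[r]) else integer(0)
    m <- reconstruct_match(raw, r, spec, seq, raw$pairs[rows, , drop = FALSE])
    cand <- build_candidate(seq, m, cls)
    cand$dG <- dg[r]
    cand
  })
}

# rebuild a rich pattern_match for one row of an .engine_scan result
reconstruct_match <- function(raw, r, spec, seq, prs = NULL) {
  nelem <- length(spec$elements)
  iv <- matrix(raw$intervals[r, ], nelem, 2, byrow = TRUE)
  backrefs <- vector("list", nelem)
  if (is.null(prs)) prs <- raw$pairs[raw$pairs[, 1] == r, , drop = FALSE]
  # assign pairs to back-references by their partner interval
  for (z in seq_along(raw$backref_elems)) {
    k <- raw$backref_elems[z]
    st <- raw$backref_stats[[z]][r, ]
    sel <- prs[, 3] >= iv[k, 1] & prs[, 3] < iv[k, 2]
    backrefs[[k]] <- list(
      mismatches = st[1], deletions = st[2], insertions = st[3],
      pairs = unname(prs[sel, 2:3, drop = FALSE])
    )
  }
  bindings <- list()
  for (k in seq_len(nelem)) {
    e <- spec$elements[[k]]
    if (e$kind == "segment" && !is.na(e$name)) {
      bindings[[e$name]] <- list(
        start = iv[k, 1], end = iv[k, 2],
        string = substr(seq, iv[k, 1] + 1L, iv[k, 2])
      )
    }
  }
  structure(
    list(
      start = raw$start[r], end = raw$end[r], intervals = iv,
      bindings = bindings, backrefs = backrefs, branch = raw$branch[r, ]
    ),
    class = "pattern_match"
  )
}

# collapse overlapping same-class candidates to the energy-optimal one
dedup_candidates <- function(cands) {
  if (length(cands) <= 1L) {
    return(cands)
  }
  starts <- vapply(cands, function(x) x$start, numeric(1))
  ends <- vapply(cands, function(x) x$end, numeric(1))
  ord <- order(starts, ends)
  cluster <- integer(length(cands))
  cur <- 0L
  cur_end <- -1L
  for (k in ord) {
    if (starts[k] >= cur_end) {
      cur <- cur + 1L
      cur_end <- ends[k]
    } else {
      cur_end <- max(cur_end, ends[k])
    }
    cluster[k] <- cur
  }
  keep <- vapply(split(seq_along(cands), cluster), function(idx) {
    dg <- vapply(cands[idx], function(x) x$dG, numeric(1))
    st <- starts[idx]
    stem <- vapply(cands[idx], function(x) x$upper_stem_len, numeric(1))
    idx[order(dg, st, -stem)][1]
  }, integer(1))
  cands[sort(keep)]
}

flag_coexisting <- function(cands) {
  cls <- vapply(cands, function(x) x$model_class, character(1))
  starts <- vapply(cands, function(x) x$start, numeric(1))
  ends <- vapply(cands, function(x) x$end, numeric(1))
  for (a in seq_along(cands)) {
    cands[[a]]$coexisting <- FALSE
  }
  i1 <- which(cls == "eSECIS_I")
  i2 <- which(cls == "eSECIS_II")
  for (a in i1) {
    for (b in i2) {
      if (starts[a] < ends[b] && starts[b] < ends[a]) {
        cands[[a]]$coexisting <- TRUE
        cands[[b]]$coexisting <- TRUE
      }
    }
  }
  cands
}

# ---------------------------------------------------------------------------
# Canonical euryarchaeal features
# ---------------------------------------------------------------------------

#' Canonical-eaSECIS feature flags
#'
#' Flags whether the candidate's upper stem carries three consecutive
#' S-S pairs (both bases C or G, the hallmark of canonical euryarchaeal
#' SECIS elements) and reports the core-motif variant read from the
#' bulge-flanking context.
#'
#' @param cand a `secis_candidate`.
#' @return list with `has_SS_triplet` (logical) and `core_motif`
#'   (`"AUGA_GA"`, `"GUGA_GA"`, `"AUGA_AA"` or `"other"`).
#' @export
classify_euryarchaeal <- function(cand) {
  prs <- cand$upper_stem_pairs
  seq <- if (!is.null(cand$window_sequence)) cand$window_sequence else NULL
  # pair bases come from the candidate's own sequence slice
  s <- strsplit(cand$sequence, "")[[1]]
  base_at <- function(pos) s[pos - cand$start + 1L]
  has_ss <- FALSE
  if (!is.null(prs) && nrow(prs) >= 3L) {
    prs <- prs[order(prs[, 1]), , drop = FALSE]
    ss <- vapply(seq_len(nrow(prs)), function(k) {
      base_at(prs[k, 1]) %in% c("C", "G") && base_at(prs[k, 2]) %in% c("C", "G")
    }, logical(1))
    runs <- rle(ss)
    has_ss <- any(runs$values & runs$lengths >= 3L)
  }
  motif <- paste0(cand$core5, "_", cand$core3)
  if (!motif %in% c("AUGA_GA", "GUGA_GA", "AUGA_AA")) motif <- "other"
  list(has_SS_triplet = has_ss, core_motif = motif)
}

# ---------------------------------------------------------------------------
# Composition statistics
# ---------------------------------------------------------------------------

#' Position-wise nucleotide composition of key SECIS regions
#'
#' For `region = "core"` the profile is over the aligned core context: the
#' four 5'-side nucleotides (e.g. `AUGA`) followed by the two 3'-side
#' nucleotides (`GA`/`AA`).  For `region = "apical_adenines"` it is over the
#' first five nucleotides of the apical loop (type I, eaSECIS) or of the
#' bulge above the upper stem (type II) - the region whose adenine
#' conservation the models encode.
#'
#' @param candidates list of `secis_candidate` objects.
#' @param region `"core"` or `"apical_adenines"`.
#' @return a `composition_profile`: list with `region`, `counts`
#'   (4 x positions), `freq`, `n`, and `empty` flag.
#' @export
composition_profiles <- function(candidates, region = c("core", "apical_adenines")) {
  region <- match.arg(region)
  strings <- vapply(candidates, function(cand) {
    if (region == "core") paste0(cand$core5, cand$core3) else cand$adenine_run
  }, character(1))
  npos <- if (region == "core") 6L else 5L
  counts <- matrix(0L, 4L, npos, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (s in strings) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq_len(min(length(ch), npos))) {
      if (ch[p] %in% rownames(counts)) {
        counts[ch[p], p] <- counts[ch[p], p] + 1L
      }
    }
  }
  colsums <- colSums(counts)
  freq <- matrix(NA_real_, 4L, npos, dimnames = dimnames(counts))
  for (p in seq_len(npos)) {
    if (colsums[p] > 0) freq[, p] <- unname(counts[, p]) / colsums[p]
  }
  structure(
    list(
      region = region, counts = counts, freq = freq,
      n = length(candidates), empty = length(candidates) == 0L
    ),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile> region=%s n=%d%s\n", x$region, x$n,
    if (x$empty) " (empty)" else ""
  ))
  if (!x$empty) print(round(x$freq, 3))
  invisible(x)
}
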