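# Shared test utilities: random-sequence generators, truncated scan
# patterns for oracle-equivalence checks, and small structure helpers.

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "U"), n,
    replace = TRUE,
    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  ), collapse = "")
}

# the three built-in patterns with segment ranges truncated so the maximum
# total span is <= 40 nt (keeps the exhaustive reference enumerator
# tractable); budgets and literals are unchanged
truncated_patterns <- function() {
  lapply(c(
    eSECIS_I = "r1={au,ua,gc,cg,gu,ug} NNGAN p1=7...9 8...11 r1~p1[2,1,1] (NGANN | NAANN)",
    eSECIS_II = "r1={au,ua,gc,cg,gu,ug} NNGAN p1=6...7 3...4 p2=2...3 2...3 r1~p2[1,1,1] 1...1 r1~p1[2,1,1] (NGANN | NAANN)",
    eaSECIS = "r1={au,ua,gc,cg,gu,ug} p1=3...6 GAA p2=3...6 3...8 r1~p2[0,1,1] A r1~p1[1,1,1]"
  ), parse_pattern)
}

# canonical signature of a match set: start plus all element intervals
match_keys <- function(matches) {
  vapply(matches, function(m) {
    paste(c(m$start, t(m$intervals)), collapse = ",")
  }, character(1))
}

# parse a dot-bracket string into a 0-based pair matrix
db_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- NULL
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out <- rbind(out, c(i - 1L, k - 1L))
    }
  }
  out[order(out[, 1]), , drop = FALSE]
}

# worked type I example: AUGA core, 7-bp perfect stem, 8-nt apical loop
worked_type1_string <- function() "AUGAGGCUCGGUAAAAAAAAACCGAGCCGAAA"

# build a secis_candidate from the single highest-scoring match of a class
candidate_from_seq <- function(seq, cls) {
  cands <- scan_window(seq,
    models = secis_models()[cls],
    patterns = builtin_patterns()[cls]
  )
  expect_gt(length(cands), 0)
  cands[[which.min(vapply(cands, function(x) x$dG, numeric(1)))]]
}

# plant one element of a class inside a random window, return window + locus
plant_in_window <- function(cls, cfg, window_len = 630L, bg_gc = 0.45) {
  el <- secisscan:::make_secis(cls, cfg)
  pos <- sample(30:(window_len - nchar(el$seq) - 30L), 1)
  win <- paste0(
    secisscan:::random_dna(pos, bg_gc), el$seq,
    secisscan:::random_dna(window_len - pos - nchar(el$seq), bg_gc)
  )
  list(window = chartr("T", "U", win), start = pos, end = pos + nchar(el$seq), el = el)
}
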