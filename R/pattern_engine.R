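#' @useDynLib secisscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PATTERN_ALPHABET <- c("A", "C", "G", "U", "T", "N", "R", "Y", "S", "W")

#' Parse a structured-motif pattern
#'
#' Parses a pattern written in a PatScan-style dialect into a `pattern_spec`.
#' The dialect supports, in order of appearance:
#'
#' * pairing-rule declarations, e.g. `r1={au,ua,gc,cg,gu,ug}` (lowercase
#'   ordered base pairs, comma separated);
#' * literal runs over `A C G U N R Y S W` (`T` is accepted and read as `U`);
#' * named length-ranged segments, e.g. `p1=7...15`;
#' * anonymous segments, e.g. `8...20`;
#' * pairing back-references, e.g. `r1~p1[2,1,1]`, which match the reverse of
#'   the named segment under the rule with at most 2 mismatches, 1 deletion
#'   and 1 insertion (budgets in that order);
#' * parenthesised alternations of literals, e.g. `(NGANN | NAANN)`.
#'
#' @param text pattern text, tokens separated by whitespace.
#' @return a `pattern_spec` object.
#' @examples
#' parse_pattern("r1={au,ua,gc,cg,gu,ug} NNGAN p1=7...15 8...20 r1~p1[2,1,1] (NGANN | NAANN)")
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty pattern")

  rules <- list()
  elements <- list()
  segments <- character(0)          # declared segment names, id = index
  n_anon <- 0L

  # re-join parenthesised alternations split across tokens
  joined <- character(0)
  buf <- NULL
  for (tok in tokens) {
    if (is.null(buf) && startsWith(tok, "(") && !endsWith(tok, ")")) {
      buf <- tok
    } else if (!is.null(buf)) {
      buf <- paste(buf, tok)
      if (endsWith(tok, ")")) {
        joined <- c(joined, buf)
        buf <- NULL
      }
    } else {
      joined <- c(joined, tok)
    }
  }
  if (!is.null(buf)) stop("parse error: unclosed '(' in pattern")

  lit_re <- paste0("^[", paste(PATTERN_ALPHABET, collapse = ""), "]+$")
  for (pos in seq_along(joined)) {
    tok <- joined[pos]
    if (grepl("^[a-z][a-z0-9]*=\\{", tok)) {
      # rule declaration: r1={au,ua,...}
      name <- sub("=.*$", "", tok)
      body <- sub("^[a-z][a-z0-9]*=\\{", "", tok)
      if (!endsWith(body, "}")) {
        stop(sprintf("parse error at token %d ('%s'): malformed rule declaration", pos, tok))
      }
      body <- sub("\\}$", "", body)
      prs <- strsplit(body, ",")[[1]]
      mat <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
      for (p in prs) {
        p <- toupper(trimws(p))
        p <- chartr("T", "U", p)
        if (nchar(p) != 2L || !all(strsplit(p, "")[[1]] %in% rownames(mat))) {
          stop(sprintf("parse error at token %d: bad pair '%s' in rule '%s'", pos, p, name))
        }
        mat[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
      }
      rules[[name]] <- mat
    } else if (grepl("^[a-z][a-z0-9]*=[0-9]+\\.\\.\\.[0-9]+$", tok)) {
      # named segment p1=a...b
      name <- sub("=.*$", "", tok)
      rng <- as.integer(strsplit(sub("^[^=]*=", "", tok), "\\.\\.\\.")[[1]])
      if (rng[1] > rng[2]) stop(sprintf("parse error at token %d: min_len > max_len", pos))
      if (name %in% segments) stop(sprintf("parse error at token %d: segment '%s' redeclared", pos, name))
      segments <- c(segments, name)
      elements[[length(elements) + 1L]] <- list(
        kind = "segment", name = name, seg = length(segments),
        min = rng[1], max = rng[2]
      )
    } else if (grepl("^[0-9]+\\.\\.\\.[0-9]+$", tok)) {
      # anonymous segment a...b
      rng <- as.integer(strsplit(tok, "\\.\\.\\.")[[1]])
      if (rng[1] > rng[2]) stop(sprintf("parse error at token %d: min_len > max_len", pos))
      n_anon <- n_anon + 1L
      segments <- c(segments, paste0(".anon", n_anon))
      elements[[length(elements) + 1L]] <- list(
        kind = "segment", name = NA_character_, seg = length(segments),
        min = rng[1], max = rng[2]
      )
    } else if (grepl("^[a-z][a-z0-9]*~[a-z][a-z0-9]*\\[[0-9]+,[0-9]+,[0-9]+\\]$", tok)) {
      # back-reference rule~seg[m,d,i]
      rname <- sub("~.*$", "", tok)
      sname <- sub("\\[.*$", "", sub("^[^~]*~", "", tok))
      budgets <- as.integer(strsplit(gsub("^.*\\[|\\]$", "", tok), ",")[[1]])
      if (is.null(rules[[rname]])) {
        stop(sprintf("parse error at token %d: undeclared rule '%s'", pos, rname))
      }
      if (!sname %in% segments) {
        stop(sprintf("parse error at token %d: back-reference to undeclared segment '%s'", pos, sname))
      }
      elements[[length(elements) + 1L]] <- list(
        kind = "backref", rule = rname, segment = sname,
        seg = match(sname, segments),
        m = budgets[1], d = budgets[2], i = budgets[3]
      )
    } else if (startsWith(tok, "(")) {
      # alternation ( LIT | LIT | ... )
      body <- sub("^\\(", "", sub("\\)$", "", tok))
      branches <- toupper(trimws(strsplit(body, "\\|")[[1]]))
      branches <- chartr("T", "U", branches)
      if (length(branches) < 2L || !all(grepl(lit_re, branches))) {
        stop(sprintf("parse error at token %d ('%s'): alternation branches must be literals", pos, tok))
      }
      elements[[length(elements) + 1L]] <- list(kind = "alternation", branches = branches)
    } else if (grepl(lit_re, toupper(tok))) {
      lit <- chartr("T", "U", toupper(tok))
      elements[[length(elements) + 1L]] <- list(kind = "literal", chars = lit)
    } else {
      stop(sprintf("parse error at token %d: unknown token '%s'", pos, tok))
    }
  }
  if (length(elements) == 0L) stop("pattern declares rules but no elements")
  structure(
    list(text = text, rules = rules, elements = elements, segments = segments),
    class = "pattern_spec"
  )
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat("<pattern_spec> ", length(x$elements), " elements, ",
    length(x$rules), " pairing rule(s)\n",
    sep = ""
  )
  for (k in seq_along(x$elements)) {
    e <- x$elements[[k]]
    desc <- switch(e$kind,
      literal = sprintf("literal  %s", e$chars),
      segment = sprintf(
        "segment  %s %d...%d",
        if (is.na(e$name)) "<anon>" else e$name, e$min, e$max
      ),
      backref = sprintf("backref  %s~%s[%d,%d,%d]", e$rule, e$segment, e$m, e$d, e$i),
      alternation = sprintf("alt      (%s)", paste(e$branches, collapse = " | "))
    )
    cat(sprintf("  [%d] %s\n", k, desc))
  }
  invisible(x)
}

# compile a pattern_spec into the element list the C++ matchers consume
compile_pattern_spec <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  lapply(spec$elements, function(e) {
    switch(e$kind,
      literal = list(type = 0L, chars = e$chars),
      segment = list(type = 1L, seg = e$seg, min = e$min, max = e$max),
      backref = list(
        type = 2L, seg = e$seg, rule = spec$rules[[e$rule]],
        m = e$m, d = e$d, i = e$i
      ),
      alternation = list(type = 3L, branches = e$branches)
    )
  })
}

normalize_match_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("T", "U", toupper(seq))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "U", "N"))
  if (length(bad) > 0L) {
    stop("sequence contains characters outside {A,C,G,U,N}: ", paste(bad, collapse = ","))
  }
  seq
}

wrap_matches <- function(raw, spec, seq) {
  lapply(raw, function(m) {
    iv <- m$intervals
    bindings <- list()
    for (k in seq_along(spec$elements)) {
      e <- spec$elements[[k]]
      if (e$kind == "segment" && !is.na(e$name)) {
        bindings[[e$name]] <- list(
          start = iv[k, 1], end = iv[k, 2],
          string = substr(seq, iv[k, 1] + 1L, iv[k, 2])
        )
      }
    }
    backrefs <- stats::setNames(m$backrefs, NULL)
    structure(
      list(
        start = m$start, end = m$end, intervals = iv,
        bindings = bindings, backrefs = backrefs, branch = m$branch
      ),
      class = "pattern_match"
    )
  })
}

#' Find all matches of a pattern in an RNA sequence
#'
#' Returns every distinct placement (start position plus full segment
#' binding) of `spec` in `seq`, in left-to-right start order.  A
#' back-reference with budgets `[m,d,i]` matches a substring that aligns
#' against the reverse of its segment with at most `d` deletions, `i`
#' insertions and `m` aligned columns falling outside the pairing rule.
#' `N` never satisfies a pairing rule.
#'
#' @param spec a `pattern_spec` from [parse_pattern()].
#' @param seq a single RNA string over `A C G U N` (`T` is read as `U`).
#' @return list of `pattern_match` objects; each carries the matched
#'   interval (0-based half-open), per-element intervals, named segment
#'   bindings, and for each back-reference the realised mismatch/indel
#'   counts and the base-pair list of its canonical alignment.
#' @examples
#' spec <- parse_pattern("r1={au,ua,gc,cg,gu,ug} p1=3...3 r1~p1[0,0,0]")
#' match_all(spec, "GACGUC")
#' @export
match_all <- function(spec, seq) {
  seq <- normalize_match_seq(seq)
  raw <- .engine_match(compile_pattern_spec(spec), seq)
  wrap_matches(raw, spec, seq)
}

#' Exhaustive reference matcher
#'
#' A deliberately naive enumerator with the same contract as [match_all()]:
#' it tries every start position and every combination of segment lengths,
#' and verifies back-references by enumerating all placements of deletions
#' and insertions.  It exists as an independent correctness reference for
#' the production matcher and is only practical on short sequences.
#'
#' @inheritParams match_all
#' @return as [match_all()], without per-back-reference alignment details.
#' @export
match_all_naive <- function(spec, seq) {
  seq <- normalize_match_seq(seq)
  raw <- .naive_match(compile_pattern_spec(spec), seq)
  wrap_matches(raw, spec, seq)
}

#' @export
print.pattern_match <- function(x, ...) {
  cat(sprintf("<pattern_match> [%d,%d)\n", x$start, x$end))
  for (nm in names(x$bindings)) {
    b <- x$bindings[[nm]]
    cat(sprintf("  %s = %s [%d,%d)\n", nm, b$string, b$start, b$end))
  }
  invisible(x)
}

# base-pair list (0-based, columns i < j) of a match, sequence coordinates
match_pairs <- function(match) {
  prs <- lapply(match$backrefs, function(b) if (is.null(b)) NULL else b$pairs)
  prs <- do.call(rbind, prs)
  if (is.null(prs)) prs <- matrix(integer(0), 0, 2)
  colnames(prs) <- c("i", "j")
  prs[order(prs[, 1]), , drop = FALSE]
}

#' Render a match as a dot-bracket string
#'
#' Positions paired by a back-reference alignment are bracketed; positions
#' whose budget was consumed (mismatched or indel positions) are rendered
#' unpaired, as are literals, loops and segment positions without a partner.
#'
#' @param match a `pattern_match`.
#' @param spec the `pattern_spec` it came from (unused fields reserved).
#' @return a dot-bracket string of length `match$end - match$start`.
#' @export
to_dot_bracket <- function(match, spec = NULL) {
  n <- match$end - match$start
  db <- rep(".", n)
  prs <- match_pairs(match)
  if (nrow(prs) > 0L) {
    db[prs[, 1] - match$start + 1L] <- "("
    db[prs[, 2] - match$start + 1L] <- ")"
  }
  paste(db, collapse = "")
}
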