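# Fixed-structure nearest-neighbor free-energy evaluation (Turner 2004
# parameters, 37 C, kcal/mol).  The evaluator scores a *given* pairing map:
# stacking terms for adjacent pairs, hairpin-loop closure by size (with
# terminal mismatches and the tabulated tetra-/hexa-/triloops), bulge and
# internal-loop initiations with Ninio asymmetry, and terminal-AU penalties
# at helix ends.  It does not fold; deterministic by construction.

PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

# stacking energies, row = outer pair (5'->3'), col = inner pair
STACK37 <- matrix(
  c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
  ),
  nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES)
)

# loop-size initiation terms, index = loop size in nt (1..30)
HAIRPIN37 <- c(
  Inf, Inf, 5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40, 6.50,
  6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10, 7.20, 7.20,
  7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50, 7.60, 7.60, 7.70
)
BULGE37 <- c(
  3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80, 4.90,
  5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50, 5.60, 5.70,
  5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00, 6.00, 6.00, 6.10
)
INTERNAL37 <- c(
  Inf, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40, 2.50,
  2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10, 3.20, 3.30,
  3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60, 3.60, 3.70, 3.70
)

TERMINAL_AU37 <- 0.50
NINIO_SLOPE <- 0.60
NINIO_MAX <- 3.00

# hairpin terminal mismatch: MISMATCH_H[[pair]][x, y] for closing pair
# 5'-P x ... y Q-3' (x, y = first/last loop bases); rows/cols A,C,G,U
.mm_mat <- function(v) matrix(v, 4, 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
MISMATCH_H <- list(
  CG = .mm_mat(c(-1.50, -1.50, -1.40, -1.50,
                 -1.00, -1.10, -1.00, -0.80,
                 -2.30, -1.50, -2.40, -1.50,
                 -1.00, -1.40, -1.00, -2.10)),
  GC = .mm_mat(c(-1.10, -1.50, -1.30, -1.50,
                 -1.10, -0.70, -1.10, -0.50,
                 -2.50, -1.50, -2.20, -1.50,
                 -1.10, -1.00, -1.10, -1.60)),
  GU = .mm_mat(c( 0.20, -0.50, -0.30, -0.50,
                 -0.10, -0.20, -0.10, -0.20,
                 -1.00, -0.50, -1.10, -0.50,
                 -0.10, -0.30, -0.10, -1.00)),
  UG = .mm_mat(c(-0.50, -0.30, -0.60, -0.30,
                 -0.20, -0.10, -0.20,  0.00,
                 -0.90, -0.30, -1.10, -0.30,
                 -0.20, -0.10, -0.20, -0.90)),
  AU = .mm_mat(c(-0.30, -0.50, -0.30, -0.50,
                 -0.10, -0.20, -0.10, -0.20,
                 -1.20, -0.50, -1.10, -0.50,
                 -0.10, -0.30, -0.10, -1.20)),
  UA = .mm_mat(c(-0.50, -0.30, -0.50, -0.30,
                 -0.20, -0.10, -0.20,  0.00,
                 -1.50, -0.30, -1.50, -0.30,
                 -0.20, -0.10, -0.20, -0.90))
)

# generic internal-loop terminal mismatch (same indexing)
MISMATCH_I <- list(
  CG = .mm_mat(c( 0.00,  0.00, -0.80,  0.00,
                  0.00,  0.00,  0.00,  0.00,
                 -1.00,  0.00, -1.00,  0.00,
                  0.00,  0.00,  0.00, -0.60)),
  GC = .mm_mat(c( 0.00,  0.00, -0.80,  0.00,
                  0.00,  0.00,  0.00,  0.00,
                 -1.00,  0.00, -1.00,  0.00,
                  0.00,  0.00,  0.00, -0.60))
)
.mm_i_nonCG <- .mm_mat(c( 0.70, 0.70, -0.10, 0.70,
                          0.70, 0.70,  0.70, 0.70,
                         -0.30, 0.70, -0.30, 0.70,
                          0.70, 0.70,  0.70, 0.10))
MISMATCH_I$GU <- .mm_i_nonCG
MISMATCH_I$UG <- .mm_i_nonCG
MISMATCH_I$AU <- .mm_i_nonCG
MISMATCH_I$UA <- .mm_i_nonCG

# 1xn internal loops (n > 2): flat closing-pair term, no base dependence
mismatch_1n <- function(pt) if (pt %in% c("CG", "GC")) 0 else 0.70

# 2x3 / 3x2 internal loops
MISMATCH_I23 <- list(
  CG = .mm_mat(c( 0.00,  0.00, -0.50,  0.00,
                  0.00,  0.00,  0.00,  0.00,
                 -1.10,  0.00, -0.70,  0.00,
                  0.00,  0.00,  0.00, -0.30)),
  GC = .mm_mat(c( 0.00,  0.00,  0.00,  0.00,
                  0.00,  0.00,  0.00,  0.00,
                 -1.20,  0.00, -0.70,  0.00,
                  0.00,  0.00,  0.00, -0.30)),
  GU = .mm_mat(c( 0.70,  0.70,  0.70,  0.70,
                  0.70,  0.70,  0.70,  0.70,
                 -0.40,  0.70,  0.00,  0.70,
                  0.70,  0.70,  0.70,  0.40)),
  UG = .mm_mat(c( 0.70,  0.70,  0.20,  0.70,
                  0.70,  0.70,  0.70,  0.70,
                 -0.40,  0.70,  0.00,  0.70,
                  0.70,  0.70,  0.70,  0.40))
)
MISMATCH_I23$AU <- MISMATCH_I23$GU
MISMATCH_I23$UA <- MISMATCH_I23$UG

# tabulated special hairpin loops (full loop energies, closing pair included
# as first/last characters)
TETRALOOPS <- c(
  CAACGG = 5.50, CCAAGG = 3.30, CCACGG = 3.70, CCCAGG = 3.40, CCGAGG = 3.50,
  CCGCGG = 3.60, CCUAGG = 3.70, CCUCGG = 2.50, CUAAGG = 3.60, CUACGG = 2.80,
  CUCAGG = 3.70, CUCCGG = 2.70, CUGCGG = 2.80, CUUAGG = 3.50, CUUCGG = 3.70,
  CUUUGG = 3.70
)
HEXALOOPS <- c(ACAGUACU = 2.80, ACAGUGAU = 3.60, ACAGUGCU = 2.90, ACAGUGUU = 1.80)
TRILOOPS <- c(CAACG = 6.80, GUUAC = 6.90)

pair_type <- function(x, y) {
  pt <- paste0(x, y)
  if (pt %in% PAIR_TYPES) pt else NA_character_
}

is_au_end <- function(pt) pt %in% c("GU", "UG", "AU", "UA")

loop_init <- function(table, size) {
  if (size < 1L) stop("structural error: loop of size < 1")
  if (size <= length(table)) table[size] else table[30] + 1.079 * log(size / 30)
}

# flatten the mismatch tables into the 6 x 16 layout the C++ core reads
flatten_mm <- function(tabs) {
  out <- matrix(0, 6, 16)
  for (p in seq_along(PAIR_TYPES)) {
    out[p, ] <- as.vector(t(tabs[[PAIR_TYPES[p]]]))
  }
  out
}

energy_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        stack = STACK37,
        hairpin = HAIRPIN37, bulge = BULGE37, internal = INTERNAL37,
        mmh = flatten_mm(MISMATCH_H), mmi = flatten_mm(MISMATCH_I),
        mmi23 = flatten_mm(MISMATCH_I23),
        mm1n = vapply(PAIR_TYPES, mismatch_1n, numeric(1)),
        terminal_au = TERMINAL_AU37,
        ninio_slope = NINIO_SLOPE, ninio_max = NINIO_MAX,
        ml_closing = 9.3, ml_intern = -0.9,
        tetraloops = TETRALOOPS, hexaloops = HEXALOOPS, triloops = TRILOOPS
      )
    }
    cache
  }
})

#' Free energy of a fixed secondary structure
#'
#' Evaluates the Turner 2004 nearest-neighbor free energy (37 C, kcal/mol)
#' of the structure given by `pairs` on `seq`.  The structure is taken as
#' fixed: no folding is performed.  An empty pairing map scores 0.  Hairpin
#' loops shorter than 3 nt are physically impossible and score `+Inf`.
#'
#' @param seq RNA (or DNA) string.
#' @param pairs integer matrix with two columns (i, j), 0-based positions,
#'   i < j, each describing one base pair; pairs must be nested
#'   (non-crossing).
#' @return free energy in kcal/mol.
#' @examples
#' # 3-bp stem closed by a 4-nt loop
#' energy("GGGAAAACCC", cbind(0:2, 9:7))
#' @export
energy <- function(seq, pairs) {
  seq <- chartr("T", "U", toupper(seq))
  n <- nchar(seq)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(0)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 0L) || any(pairs >= n)) {
    stop("structural error: pairing map references positions outside the sequence")
  }
  if (any(pairs[, 1] >= pairs[, 2])) stop("structural error: need i < j in each pair")
  if (anyDuplicated(c(pairs))) stop("structural error: position paired twice")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  # non-crossing check
  if (nrow(pairs) > 1L) {
    for (k in 2:nrow(pairs)) {
      prev <- pairs[k - 1, ]
      cur <- pairs[k, ]
      if (cur[1] < prev[2] && cur[2] > prev[2]) {
        stop("structural error: crossing base pairs (pseudoknots unsupported)")
      }
    }
  }
  s <- strsplit(seq, "")[[1]]
  pt <- vapply(seq_len(nrow(pairs)), function(k) {
    pair_type(s[pairs[k, 1] + 1L], s[pairs[k, 2] + 1L])
  }, character(1))
  if (anyNA(pt)) {
    bad <- which(is.na(pt))[1]
    stop(sprintf(
      "structural error: %s-%s at (%d,%d) is not a canonical or wobble pair",
      s[pairs[bad, 1] + 1L], s[pairs[bad, 2] + 1L], pairs[bad, 1], pairs[bad, 2]
    ))
  }
  .energy_eval(seq, pairs, energy_tables())
}
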