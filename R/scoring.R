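# Per-column scoring. Every method maps a frequency-table column (and,
# where relevant, the reference symbol) to one number: positive/zero for
# conserved columns, increasingly negative for divergent ones.
#
# The closed forms below are this package's definitions, reconstructed
# from the published prose constraints on each method (see the methods
# vignette): weighted and DNAW are normalized by nseq so that DNAW lands
# in [0, 1].

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Built-in scoring weight matrices
#'
#' * `identity`: DNA match/mismatch matrix over A,C,G,T (+5 match, -4
#'   mismatch), for alignments restricted to the four usual nucleotides.
#' * `simple`: the identity scheme extended to IUPAC ambiguity codes; an
#'   ambiguous symbol scores the mean of its expansion against the other
#'   symbol (so e.g. M(A, R) = mean(M(A,A), M(A,G)) = 0.5).
#' * `blosum62`: the standard BLOSUM62 protein matrix.
#'
#' The gap weight attached to each matrix is its minimum off-diagonal
#' entry: a gap is scored as the least-conserving substitution.
#'
#' @param name One of `"identity"`, `"simple"`, `"blosum62"`.
#' @param match,mismatch Scores used to build the DNA matrices.
#' @return A `weight_matrix`: list with `name`, `weights` (symmetric
#'   numeric matrix), `gap_weight`.
#' @examples
#' builtin_matrix("identity")$weights["A", "C"]
#' @export
builtin_matrix <- function(name = c("identity", "simple", "blosum62"),
                           match = 5, mismatch = -4) {
  name <- match.arg(name)
  w <- switch(name,
    identity = {
      b <- c("A", "C", "G", "T")
      m <- matrix(mismatch, 4L, 4L, dimnames = list(b, b))
      diag(m) <- match
      m
    },
    simple = {
      base <- builtin_matrix("identity", match, mismatch)$weights
      syms <- names(IUPAC_EXPANSION)
      m <- matrix(NA_real_, length(syms), length(syms),
                  dimnames = list(syms, syms))
      for (b1 in syms) for (b2 in syms)
        m[b1, b2] <- mean(base[IUPAC_EXPANSION[[b1]], IUPAC_EXPANSION[[b2]]])
      m
    },
    blosum62 = {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    })
  off <- w[row(w) != col(w)]
  structure(list(name = name, weights = w, gap_weight = min(off)),
            class = "weight_matrix")
}

#' Load a custom weight matrix from a whitespace-delimited table
#'
#' @param file Path to a square table with symbol row/column headers.
#' @return A `weight_matrix` with gap weight = minimum off-diagonal entry.
#' @export
read_matrix <- function(file) {
  w <- as.matrix(utils::read.table(file, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  if (nrow(w) != ncol(w) || !identical(rownames(w), colnames(w)))
    stop("weight matrix must be square with matching row/column symbols",
         call. = FALSE)
  off <- w[row(w) != col(w)]
  structure(list(name = "custom", weights = w, gap_weight = min(off)),
            class = "weight_matrix")
}

new_score_track <- function(method, values, ft) {
  structure(list(method = method,
                 values = stats::setNames(as.numeric(values),
                                          colnames(ft$counts)),
                 bounds = ft$bounds),
            class = "score_track")
}

matrix_lookup <- function(w, ref_sym, symbols, gap_weight) {
  # weight of each observed symbol against the reference symbol; gaps (on
  # either side) take the gap weight
  out <- numeric(length(symbols))
  for (k in seq_along(symbols)) {
    b <- symbols[k]
    if (b == GAP || ref_sym == GAP) {
      out[k] <- gap_weight
    } else {
      if (!ref_sym %in% rownames(w) || !b %in% colnames(w))
        stop("symbol not covered by weight matrix: ",
             if (!ref_sym %in% rownames(w)) ref_sym else b, call. = FALSE)
      out[k] <- w[ref_sym, b]
    }
  }
  out
}

#' Weighted column score
#'
#' For column i with reference symbol C(i),
#' `S(i) = (1/nseq) * sum_b gamma(i,b) * M(C(i), b)`, where M is a
#' substitution weight matrix and any pairing involving a gap scores the
#' matrix's gap weight. Identities are promoted over similarities and
#' differences are penalised; higher values mean stronger conservation.
#'
#' @param ft A `freq_table`.
#' @param ref A `ref_track` over the same columns.
#' @param m A `weight_matrix` covering every observed symbol.
#' @return A `score_track` (method `"weighted"`).
#' @export
score_weighted <- function(ft, ref, m = NULL) {
  stopifnot(inherits(ft, "freq_table"), inherits(ref, "ref_track"))
  if (is.null(m))
    m <- builtin_matrix(if (ft$alphabet == "DNA") "identity" else "blosum62")
  stopifnot(inherits(m, "weight_matrix"))
  counts <- ft$counts
  vals <- vapply(seq_len(ncol(counts)), function(j) {
    wts <- matrix_lookup(m$weights, ref$symbols[[j]], rownames(counts),
                         m$gap_weight)
    sum(counts[, j] * wts) / ft$nseq
  }, numeric(1L))
  new_score_track("weighted", vals, ft)
}

#' DNAW column score
#'
#' The DNA-only simplification of the weighted score with weight 1 for
#' identity to the reference and 0 for any difference:
#' `S(i) = gamma(i, C(i)) / nseq`, in `[0, 1]`. Lower values mean more
#' sequences differ from the reference at that column.
#'
#' @inheritParams score_weighted
#' @return A `score_track` (method `"dnaw"`).
#' @export
score_dnaw <- function(ft, ref) {
  stopifnot(inherits(ft, "freq_table"), inherits(ref, "ref_track"))
  if (ft$alphabet != "DNA")
    stop("DNAW applies only to DNA sequences", call. = FALSE)
  counts <- ft$counts
  vals <- vapply(seq_len(ncol(counts)), function(j) {
    r <- ref$symbols[[j]]
    if (r == GAP || !r %in% rownames(counts)) 0
    else counts[r, j] / ft$nseq
  }, numeric(1L))
  new_score_track("dnaw", vals, ft)
}

#' Sign-switched Shannon entropy column score
#'
#' With `f(b) = gamma(i,b)/nseq` over the symbols observed at column i
#' (gap included as a symbol class), the column entropy is
#' `H(i) = -sum f(b) log2 f(b)`. For consistency with the other methods
#' (divergent = negative) the score is `S(i) = -H(i) <= 0`, with equality
#' exactly when the column is uniform.
#'
#' @param ft A `freq_table`.
#' @param base Logarithm base (default 2: bits).
#' @return A `score_track` (method `"entropy"`).
#' @export
score_entropy <- function(ft, base = 2) {
  stopifnot(inherits(ft, "freq_table"))
  counts <- ft$counts
  vals <- vapply(seq_len(ncol(counts)), function(j) {
    f <- counts[counts[, j] > 0L, j] / ft$nseq
    sum(f * log(f, base = base))
  }, numeric(1L))
  new_score_track("entropy", vals, ft)
}

#' Variability column score
#'
#' Counts how many distinct symbols occur, regardless of how conservative
#' each change is: `S(i) = 1 - D(i)`, i.e. 0 for invariant columns and
#' one unit more negative per extra symbol observed (gap included).
#'
#' @param ft A `freq_table`.
#' @return A `score_track` (method `"variability"`).
#' @export
score_variability <- function(ft) {
  stopifnot(inherits(ft, "freq_table"))
  new_score_track("variability", 1 - ft$distinct, ft)
}
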