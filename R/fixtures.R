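# Synthetic alignments with planted structure: outside the planted
# blocks every sequence is identical; inside a block each column
# independently carries a variant base in a random subset of sequences.
# Terminal gap wedges exercise end slicing. Sequence 1 is the reference
# row and never mutates, so ground truth is exact.

#' Generate a synthetic alignment with planted divergent blocks
#'
#' @param nseq Number of sequences (>= 2).
#' @param length Number of alignment columns.
#' @param blocks Data frame (or list coercible to one) with columns
#'   `start`, `end` (1-based inclusive), `variant_fraction` (per-column
#'   probability that the column carries variants), and optionally
#'   `min_variant_copies` (default 2).
#' @param gap_blocks Optional data frame with columns `end` (`"LEFT"` or
#'   `"RIGHT"`) and `depth` (columns): inserts a terminal gap wedge (one
#'   gap per wedge column in sequence 2) so automatic end slicing has
#'   work to do.
#' @param seed Integer seed fixing all randomness.
#' @return A list with `alignment` (an [msa]), and `truth`: `blocks`
#'   (the planted intervals), `snp_columns` (columns where a variant
#'   base was planted in >= 2 sequences), `variant_columns` (all columns
#'   with any planted variant).
#' @examples
#' fx <- generate_msa(nseq = 8, length = 120,
#'                    blocks = data.frame(start = 50, end = 64,
#'                                        variant_fraction = 0.5),
#'                    seed = 1)
#' fx$truth$snp_columns
#' @export
generate_msa <- function(nseq, length, blocks = NULL, gap_blocks = NULL,
                         seed = 1L) {
  stopifnot(nseq >= 2L, length >= 1L)
  if (!is.null(blocks)) {
    blocks <- as.data.frame(blocks)
    if (is.null(blocks$min_variant_copies)) blocks$min_variant_copies <- 2L
    if (any(blocks$start < 1L | blocks$end > length |
            blocks$start > blocks$end))
      stop("planted blocks must lie within [1, length]", call. = FALSE)
    if (any(blocks$variant_fraction < 0 | blocks$variant_fraction > 1))
      stop("variant_fraction must lie in [0, 1]", call. = FALSE)
    if (any(blocks$min_variant_copies > nseq - 2L))
      stop("infeasible spec: min_variant_copies > nseq - 2", call. = FALSE)
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  refrow <- sample(bases, length, replace = TRUE)
  m <- matrix(rep(refrow, each = nseq), nrow = nseq)
  snp_cols <- integer()
  var_cols <- integer()
  if (!is.null(blocks)) {
    # variant subsets are drawn from rows 2..nseq and capped so the
    # reference base keeps the column plurality
    max_copies <- max(2L, (nseq - 1L) %/% 2L)
    for (b in seq_len(nrow(blocks))) {
      lo <- blocks$start[b]; hi <- blocks$end[b]
      minc <- blocks$min_variant_copies[b]
      for (j in lo:hi) {
        if (stats::runif(1L) >= blocks$variant_fraction[b]) next
        alt <- sample(setdiff(bases, refrow[j]), 1L)
        k <- if (max_copies > minc)
          sample(minc:max_copies, 1L) else minc
        rows <- sample(2:nseq, k)
        m[rows, j] <- alt
        var_cols <- c(var_cols, j)
        if (k >= 2L) snp_cols <- c(snp_cols, j)
      }
    }
  }
  if (!is.null(gap_blocks)) {
    gap_blocks <- as.data.frame(gap_blocks)
    for (g in seq_len(nrow(gap_blocks))) {
      d <- gap_blocks$depth[g]
      cols <- if (toupper(gap_blocks$end[g]) == "LEFT") seq_len(d)
              else (length - d + 1L):length
      m[2L, cols] <- "-"
    }
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("seq%02d", seq_len(nseq))
  list(alignment = msa(seqs, alphabet = "DNA"),
       truth = list(blocks = blocks,
                    snp_columns = sort(unique(snp_cols)),
                    variant_columns = sort(unique(var_cols))))
}
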