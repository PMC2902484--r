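# Pre-processing: end slicing, per-column frequency tables, reference track.
# Coordinates are 1-based inclusive columns of the full alignment throughout.

#' Trim gappy alignment ends
#'
#' Alignment ends typically carry a high proportion of gaps (ragged
#' sequence starts), where column frequencies are unreliable. Each end is
#' sliced inward until two contiguous columns are entirely gap-free; the
#' returned bounds span from the first such pair to the last.
#'
#' @param a An [msa] object.
#' @return A list `(start, end)` of 1-based inclusive column bounds, class
#'   `slice_bounds`.
#' @examples
#' a <- msa(c(x = "-CGTAC", y = "ACGTAC", z = "ACGTAC"))
#' slice_ends(a)  # start = 2
#' @export
slice_ends <- function(a) {
  stopifnot(inherits(a, "msa"))
  m <- msa_matrix(a)
  gapfree <- colSums(m == GAP) == 0L
  pair_ok <- gapfree[-length(gapfree)] & gapfree[-1L]
  if (!any(pair_ok))
    stop("alignment too gappy: no two contiguous gap-free columns",
         call. = FALSE)
  start <- which(pair_ok)[1L]
  end <- max(which(pair_ok)) + 1L
  slice_bounds(start, end, a$length)
}

#' @rdname slice_ends
#' @param start,end 1-based inclusive column bounds.
#' @param alignment_length Total number of alignment columns.
#' @export
slice_bounds <- function(start, end, alignment_length) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > alignment_length || start > end)
    stop(sprintf("invalid slice bounds [%d, %d] for %d columns",
                 start, end, alignment_length), call. = FALSE)
  structure(list(start = start, end = end), class = "slice_bounds")
}

#' Per-column residue frequency table
#'
#' Tallies, for each column in `bounds`, how many sequences carry each
#' symbol. The gap is counted as a symbol class of its own (a gap is
#' treated as the lowest-conserving substitution downstream, so its
#' frequency matters). The table is the cache that makes per-column
#' scoring cost independent of the number of sequences.
#'
#' @param a An [msa] object.
#' @param bounds A `slice_bounds` object; defaults to the full alignment.
#' @return A `freq_table`: list with `counts` (symbols x columns integer
#'   matrix, column names = alignment column indices), `distinct`
#'   (distinct-symbol count per column), `symbols`, `nseq`, `bounds`,
#'   `alphabet`.
#' @export
build_frequency_table <- function(a, bounds = NULL) {
  stopifnot(inherits(a, "msa"))
  if (is.null(bounds)) bounds <- slice_bounds(1L, a$length, a$length)
  m <- msa_matrix(a)[, bounds$start:bounds$end, drop = FALSE]
  symbols <- sort(unique(as.vector(m)))
  counts <- vapply(seq_len(ncol(m)), function(j)
    tabulate(factor(m[, j], levels = symbols), nbins = length(symbols)),
    integer(length(symbols)))
  counts <- matrix(counts, nrow = length(symbols),
                   dimnames = list(symbols, bounds$start:bounds$end))
  structure(
    list(counts = counts,
         distinct = colSums(counts > 0L),
         symbols = symbols,
         nseq = a$nseq,
         bounds = bounds,
         alphabet = a$alphabet),
    class = "freq_table")
}

#' Consensus track from a frequency table
#'
#' Per column, the consensus symbol is the most frequent non-gap symbol;
#' ties break to the lexicographically smallest symbol. Gaps are never
#' eligible except for all-gap columns, which yield the gap symbol. A
#' plurality threshold can require the winner to exceed a frequency
#' fraction (default 0: plain plurality).
#'
#' @param ft A `freq_table` from [build_frequency_table()].
#' @param threshold Minimum winner frequency as a fraction of `nseq`;
#'   columns whose winner falls below it get the gap symbol.
#' @return A `ref_track`: list with `symbols` (per-column character,
#'   named by column index), `mode`, `master_id`.
#' @export
call_consensus <- function(ft, threshold = 0) {
  stopifnot(inherits(ft, "freq_table"))
  counts <- ft$counts
  nongap <- rownames(counts) != GAP
  sym <- apply(counts[nongap, , drop = FALSE], 2L, function(cc) {
    if (all(cc == 0L)) return(GAP)
    w <- which(cc == max(cc))[1L]  # rows are sorted, so first max is lexicographic
    if (max(cc) / ft$nseq < threshold) return(GAP)
    rownames(counts)[nongap][w]
  })
  structure(list(symbols = stats::setNames(sym, colnames(counts)),
                 mode = "CONSENSUS", master_id = NULL),
            class = "ref_track")
}

#' Choose the scoring reference: consensus or a master sequence
#'
#' With a master identifier, scoring is referred to that sequence's own
#' residues (including its gaps), which highlights positions where the
#' master differs from the rest; otherwise the consensus is used.
#'
#' @param a An [msa] object.
#' @param ft A `freq_table` over the slice of interest.
#' @param master_id Optional sequence identifier.
#' @return A `ref_track`.
#' @export
select_reference <- function(a, ft, master_id = NULL) {
  stopifnot(inherits(a, "msa"), inherits(ft, "freq_table"))
  if (is.null(master_id)) return(call_consensus(ft))
  if (!master_id %in% names(a$records))
    stop("unknown master sequence: ", master_id, call. = FALSE)
  cols <- ft$bounds$start:ft$bounds$end
  chars <- strsplit(a$records[[master_id]], "", fixed = TRUE)[[1L]][cols]
  structure(list(symbols = stats::setNames(chars, cols),
                 mode = "MASTER", master_id = master_id),
            class = "ref_track")
}
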