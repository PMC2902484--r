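# SNP and region calling. SNP status is decided on the raw score track;
# region membership on the FFT-smoothed track, each against its own
# cutoffs (the two branches of the pipeline).

#' Call putative SNPs from a raw score track
#'
#' A DNA alignment column is reported as a putative SNP when (a) its raw
#' score falls below the low cutoff, (b) at least one non-reference
#' symbol is present, and (c) every non-reference symbol present occurs
#' in at least two sequences — a single-copy variant is indistinguishable
#' from a sequencing error. A consequence of (c) is that alignments of
#' fewer than four sequences cannot support SNP prediction, which is
#' enforced explicitly. Neither synonymy nor structural effect is
#' assessed.
#'
#' @param raw A `score_track` of raw (unsmoothed) scores.
#' @param cut A `cutoff_pair` computed from `raw`.
#' @param ft The `freq_table` the track was scored from.
#' @param ref The `ref_track` used for scoring.
#' @param count_gaps Should a gap class count as a variant symbol
#'   (default `TRUE`)? When `FALSE`, gap-only variation cannot qualify a
#'   column.
#' @return A data frame with columns `column` (1-based alignment
#'   coordinate), `ref`, `variants` (text like `"C:2"`, comma-separated),
#'   `raw_score`.
#' @export
call_snps <- function(raw, cut, ft, ref, count_gaps = TRUE) {
  stopifnot(inherits(raw, "score_track"), inherits(cut, "cutoff_pair"),
            inherits(ft, "freq_table"), inherits(ref, "ref_track"))
  if (ft$alphabet != "DNA")
    stop("SNP calling is DNA-only", call. = FALSE)
  empty <- data.frame(column = integer(), ref = character(),
                      variants = character(), raw_score = numeric(),
                      stringsAsFactors = FALSE)
  if (ft$nseq < 4L) return(empty)
  counts <- ft$counts
  hits <- which(raw$values < cut$low)
  rows <- lapply(hits, function(j) {
    r <- ref$symbols[[j]]
    cc <- counts[, j]
    vars <- cc[cc > 0L & rownames(counts) != r]
    if (!count_gaps) vars <- vars[names(vars) != GAP]
    if (length(vars) == 0L || any(vars < 2L)) return(NULL)
    data.frame(column = as.integer(colnames(counts)[j]), ref = r,
               variants = paste(sprintf("%s:%d", names(vars), vars),
                                collapse = ","),
               raw_score = unname(raw$values[j]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Extract conserved/divergent regions from a smoothed track
#'
#' Divergent candidates are maximal runs of contiguous columns whose
#' smoothed score falls below the low cutoff; conserved candidates are
#' runs above the high cutoff (none when the cutoff pair has no high
#' bound). For DNA, a divergent candidate must contain at least two
#' putative SNP columns to be reported. Each region's characteristic
#' score is the arithmetic mean of the raw scores of its columns.
#'
#' @param smoothed A `smoothed_track`.
#' @param raw The matching raw `score_track`.
#' @param cut A `cutoff_pair` computed from the smoothed track.
#' @param snps SNP data frame from [call_snps()] (ignored for protein).
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param min_snps Minimum SNP columns inside a DNA divergent region
#'   (default 2).
#' @return A data frame with columns `kind`, `start`, `end`, `length`,
#'   `score`, `snp_count`, `bucket` (1-based inclusive alignment
#'   coordinates).
#' @export
extract_regions <- function(smoothed, raw, cut, snps = NULL,
                            alphabet = c("DNA", "PROTEIN"), min_snps = 2L) {
  stopifnot(inherits(smoothed, "smoothed_track"),
            inherits(raw, "score_track"), inherits(cut, "cutoff_pair"))
  alphabet <- match.arg(alphabet)
  stopifnot(length(smoothed$values) == length(raw$values))
  cols <- as.integer(names(raw$values))
  snp_cols <- if (is.null(snps)) integer() else snps$column

  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }

  one_kind <- function(mask, kind) {
    runs <- runs_of(mask)
    if (nrow(runs) == 0L) return(NULL)
    out <- lapply(seq_len(nrow(runs)), function(i) {
      idx <- runs[i, 1L]:runs[i, 2L]
      start <- cols[runs[i, 1L]]; end <- cols[runs[i, 2L]]
      nsnp <- sum(snp_cols >= start & snp_cols <= end)
      if (kind == "DIVERGENT" && alphabet == "DNA" && nsnp < min_snps)
        return(NULL)
      data.frame(kind = kind, start = start, end = end,
                 length = end - start + 1L,
                 score = mean(raw$values[idx]),
                 snp_count = if (alphabet == "DNA") nsnp else NA_integer_,
                 stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1L))]
    if (length(out) == 0L) NULL else do.call(rbind, out)
  }

  div <- one_kind(smoothed$values < cut$low, "DIVERGENT")
  con <- if (!is.na(cut$high))
    one_kind(smoothed$values > cut$high, "CONSERVED") else NULL
  regions <- rbind(div, con)
  if (is.null(regions))
    regions <- data.frame(kind = character(), start = integer(),
                          end = integer(), length = integer(),
                          score = numeric(), snp_count = integer(),
                          stringsAsFactors = FALSE)
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions$bucket <- vapply(regions$length, bucket_length, character(1L))
  regions
}

#' Length class of a region
#'
#' Regions are bucketed as `SHORT` (fewer than 6 positions), `MEDIUM`
#' (6 to 11), or `LONG` (more than 11).
#'
#' @param length Region length in alignment positions.
#' @return `"SHORT"`, `"MEDIUM"` or `"LONG"`.
#' @export
bucket_length <- function(length) {
  if (length < 6) "SHORT" else if (length <= 11) "MEDIUM" else "LONG"
}

#' Summary of called divergent regions
#'
#' @param regions Region data frame from [extract_regions()].
#' @param alignment_length Number of columns the tracks cover (the sliced
#'   length), denominator for the coverage percentage.
#' @return A list: `n_divergent`, `n_conserved`, `divergent_columns`,
#'   `divergent_pct` (100 * divergent columns / `alignment_length`),
#'   `buckets` (named counts over SHORT/MEDIUM/LONG divergent regions).
#' @export
summarize_regions <- function(regions, alignment_length) {
  div <- regions[regions$kind == "DIVERGENT", , drop = FALSE]
  buckets <- table(factor(div$bucket, levels = c("SHORT", "MEDIUM", "LONG")))
  list(n_divergent = nrow(div),
       n_conserved = sum(regions$kind == "CONSERVED"),
       divergent_columns = sum(div$length),
       divergent_pct = 100 * sum(div$length) / alignment_length,
       buckets = stats::setNames(as.integer(buckets), names(buckets)))
}
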