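# End-to-end orchestration: read -> slice -> frequencies -> reference ->
# score -> cutoffs -> smooth -> SNPs -> regions -> summaries. All methods
# share the frequency table, so computing several is cheap.

#' Scan an alignment for divergent regions and putative SNPs
#'
#' Runs the full pipeline for one or more scoring methods. Raw scores
#' are thresholded against cutoffs computed from the raw track to call
#' putative SNPs (DNA only); the FFT-smoothed track is thresholded
#' against its own cutoffs to call conserved/divergent regions (each
#' branch uses its own robust cutoff pair).
#'
#' @param a An [msa] object (or a file path, passed to
#'   [read_alignment()]).
#' @param methods Character vector over `"weighted"`, `"dnaw"`,
#'   `"entropy"`, `"variability"`, or `"all"` (default: all methods
#'   applicable to the alphabet).
#' @param matrix Weight matrix for the weighted score: a name accepted
#'   by [builtin_matrix()] or a `weight_matrix` object; default
#'   `"identity"` for DNA, `"blosum62"` for protein.
#' @param master Optional master-sequence identifier; scoring is then
#'   referred to that sequence rather than the consensus.
#' @param slice Optional manual `c(start, end)` (1-based inclusive
#'   columns) overriding automatic end slicing.
#' @param smooth_window FFT smoothing window in columns (default 10).
#' @param mad_factor Cutoff scale factor (default 1.4826).
#' @param count_gap_snps Should gap-only variation qualify SNP columns?
#' @return A `divscan_result`: list with `alphabet`, `nseq`,
#'   `alignment_length`, `bounds`, `reference` (mode/master), and per
#'   method a list `tracks` holding `raw`, `smoothed`, `cutoffs_raw`,
#'   `cutoffs_smoothed`, `snps`, `regions`, `summary`.
#' @examples
#' fx <- generate_msa(8, 200, data.frame(start = 90, end = 110,
#'                                       variant_fraction = 0.5), seed = 7)
#' res <- scan_msa(fx$alignment, methods = "entropy")
#' res$tracks$entropy$regions
#' @export
scan_msa <- function(a, methods = "all", matrix = NULL, master = NULL,
                     slice = NULL, smooth_window = 10, mad_factor = 1.4826,
                     count_gap_snps = TRUE) {
  if (is.character(a) && length(a) == 1L) a <- read_alignment(a)
  stopifnot(inherits(a, "msa"))
  all_methods <- c("weighted", "dnaw", "entropy", "variability")
  if (identical(methods, "all")) {
    methods <- all_methods
    if (a$alphabet != "DNA") methods <- setdiff(methods, "dnaw")
  } else {
    methods <- match.arg(methods, all_methods, several.ok = TRUE)
    if ("dnaw" %in% methods && a$alphabet != "DNA")
      stop("DNAW applies only to DNA sequences", call. = FALSE)
  }
  bounds <- if (is.null(slice)) slice_ends(a)
            else slice_bounds(slice[1L], slice[2L], a$length)
  ft <- build_frequency_table(a, bounds)
  ref <- select_reference(a, ft, master)
  if (is.character(matrix)) matrix <- builtin_matrix(matrix)

  tracks <- lapply(methods, function(method) {
    raw <- switch(method,
      weighted = score_weighted(ft, ref, matrix),
      dnaw = score_dnaw(ft, ref),
      entropy = score_entropy(ft),
      variability = score_variability(ft))
    cut_raw <- compute_cutoffs(raw, k = mad_factor)
    smoothed <- smooth_fft(raw, window = smooth_window)
    cut_smooth <- compute_cutoffs(smoothed$values, k = mad_factor)
    snps <- if (a$alphabet == "DNA")
      call_snps(raw, cut_raw, ft, ref, count_gaps = count_gap_snps)
    else NULL
    regions <- extract_regions(smoothed, raw, cut_smooth, snps,
                               alphabet = a$alphabet)
    list(raw = raw, smoothed = smoothed,
         cutoffs_raw = cut_raw, cutoffs_smoothed = cut_smooth,
         snps = snps, regions = regions,
         summary = summarize_regions(regions,
                                     bounds$end - bounds$start + 1L))
  })
  names(tracks) <- methods
  structure(list(alphabet = a$alphabet, nseq = a$nseq,
                 alignment_length = a$length,
                 bounds = list(start = bounds$start, end = bounds$end),
                 reference = list(mode = ref$mode,
                                  master_id = ref$master_id),
                 reference_symbols = unname(ref$symbols),
                 tracks = tracks),
            class = "divscan_result")
}

#' @export
print.divscan_result <- function(x, ...) {
  cat(sprintf("divscan result: %s alignment, %d sequences, columns %d-%d\n",
              x$alphabet, x$nseq, x$bounds$start, x$bounds$end))
  for (m in names(x$tracks)) {
    t <- x$tracks[[m]]
    nsnp <- if (is.null(t$snps)) NA_integer_ else nrow(t$snps)
    cat(sprintf("  %-11s %d divergent, %d conserved region(s)%s\n", m,
                t$summary$n_divergent, t$summary$n_conserved,
                if (is.na(nsnp)) "" else sprintf(", %d putative SNP(s)", nsnp)))
  }
  invisible(x)
}

#' Design and grade default primer windows for divergent regions
#'
#' Builds the default window (region plus `flank` nucleotides each side,
#' mapped to the ungapped reference) for every divergent region of a
#' method's track and grades the forward window sequence and its reverse
#' complement.
#'
#' @param result A `divscan_result` from [scan_msa()].
#' @param method Which method's regions to use.
#' @param flank Window flank (default 5).
#' @param ... Passed to [evaluate_primer()].
#' @return A data frame with one row per region and strand: window
#'   coordinates, sequence, measured properties and grades.
#' @export
design_primers <- function(result, method = "entropy", flank = 5L, ...) {
  stopifnot(inherits(result, "divscan_result"))
  if (result$alphabet != "DNA")
    stop("primer design needs a DNA alignment", call. = FALSE)
  t <- result$tracks[[method]]
  if (is.null(t)) stop("method not present in result: ", method,
                       call. = FALSE)
  ref <- structure(
    list(symbols = stats::setNames(
           result$reference_symbols,
           result$bounds$start:result$bounds$end),
         mode = result$reference$mode,
         master_id = result$reference$master_id),
    class = "ref_track")
  div <- t$regions[t$regions$kind == "DIVERGENT", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(div))) {
    win <- default_window(div[i, ], ref, flank = flank)
    for (strand in c("FORWARD", "REVERSE")) {
      s <- if (strand == "FORWARD") win$sequence
           else reverse_complement(win$sequence)
      rep <- evaluate_primer(s, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        region_start = div$start[i], region_end = div$end[i],
        window_start = win$start, window_end = win$end, strand = strand,
        sequence = s, length = rep$length, gc_pct = rep$gc_pct,
        tm_c = rep$tm_c, gc3_count = rep$gc3_count,
        repeat_flag = rep$repeat_flag, dimer_dg = rep$dimer_dg,
        hairpin_dg = rep$hairpin_dg,
        grade_gc = rep$grades[["gc"]], grade_tm = rep$grades[["tm"]],
        grade_clamp = rep$grades[["clamp"]],
        grade_repeats = rep$grades[["repeats"]],
        grade_dimer = rep$grades[["dimer"]],
        grade_hairpin = rep$grades[["hairpin"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame())
  do.call(rbind, rows)
}
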