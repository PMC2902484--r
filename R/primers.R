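# Primer windows over divergent regions, and oligonucleotide quality
# measurement/grading: length, GC%, nearest-neighbor Tm, 3'-end GC clamp,
# repeats, and simplified self-dimer / hairpin free energies.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K), dG37 kcal/mol, keyed by the 5'->3' top
# strand dinucleotide of a Watson-Crick stack.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
NN_DG <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
           CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84,
           TT = -1.00, TG = -1.45, AC = -1.44, AG = -1.28, TC = -1.30,
           CC = -1.84)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA sequence
#'
#' IUPAC ambiguity codes are complemented according to the standard
#' table; the operation is an involution.
#'
#' @param seq A DNA string (IUPAC allowed).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  if (grepl("[^ACGTURYSWKMBDHVN-]", s))
    stop("unrecognized nucleotide character in: ", seq, call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Default primer window around a divergent region
#'
#' Maps a region given in alignment-column coordinates onto the ungapped
#' reference (consensus or master) sequence and extends it by `flank`
#' nucleotides on each side, clamping to the sequence ends. The window
#' plus its ungapped sequence is the default primer candidate.
#'
#' @param region A one-row slice of the region data frame (needs `start`
#'   and `end`, 1-based alignment columns) or a list with those fields.
#' @param ref_track A `ref_track` covering those columns (its gaps define
#'   the column-to-ungapped mapping).
#' @param flank Nucleotides added on each side (default 5).
#' @return A list `(start, end, strand, sequence)` with positions on the
#'   ungapped reference, class `primer_window`.
#' @export
default_window <- function(region, ref_track, flank = 5L) {
  stopifnot(inherits(ref_track, "ref_track"))
  syms <- ref_track$symbols
  cols <- as.integer(names(syms))
  if (!(region$start %in% cols && region$end %in% cols))
    stop("region lies outside the reference track", call. = FALSE)
  nongap <- syms != GAP
  ungapped_pos <- cumsum(nongap)          # column -> ungapped coordinate
  ulen <- sum(nongap)
  sel <- cols >= region$start & cols <= region$end
  if (!any(nongap[sel]))
    stop("region falls entirely within reference gaps", call. = FALSE)
  ustart <- min(ungapped_pos[sel & nongap])
  uend <- max(ungapped_pos[sel & nongap])
  wstart <- max(1L, ustart - as.integer(flank))
  wend <- min(ulen, uend + as.integer(flank))
  refseq <- paste(syms[nongap], collapse = "")
  structure(list(start = wstart, end = wend, strand = "FORWARD",
                 sequence = substr(refseq, wstart, wend)),
            class = "primer_window")
}

melting_temperature <- function(seq, salt_mM = 50, primer_nM = 500,
                                method = c("nn", "wallace")) {
  method <- match.arg(method)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (method == "wallace")
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  pairs <- paste0(chars[-n], chars[-1L])
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  # initiation with terminal G/C: dH 0.1, dS -2.8; terminal A/T: 2.3, 4.1
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)   # monovalent salt
  1000 * dh / (ds + 1.987 * log(primer_nM * 1e-9 / 4)) - 273.15
}

# Minimum stack free energy over all antiparallel self-alignments.
# For each offset, complementary base pairs are found and consecutive
# pairs contribute the nearest-neighbor stack dG; perfect-complement
# stretches sum, loops and bulges are ignored.
dimer_dg <- function(chars) {
  n <- length(chars)
  rev_ <- rev(chars)
  best <- 0
  for (off in (-(n - 1L)):(n - 1L)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    i <- i[ok]; j <- j[ok]
    paired <- COMPLEMENT[chars[i]] == rev_[j]
    if (length(paired) < 2L) next
    stack_ok <- paired[-length(paired)] & paired[-1L]
    if (!any(stack_ok)) next
    total <- sum(NN_DG[paste0(chars[i][-length(i)],
                              chars[i][-1L])][stack_ok])
    if (total < best) best <- total
  }
  best
}

# Minimum stack free energy over hairpin stems with loop >= 3: every
# complementary (i, j) pair with j - i - 1 >= min_loop seeds a stem that
# is extended outward while complementary.
hairpin_dg <- function(chars, min_loop = 3L) {
  n <- length(chars)
  best <- 0
  if (n < min_loop + 4L) return(best)
  for (i in seq_len(n - min_loop - 1L)) {
    for (j in (i + min_loop + 1L):n) {
      if (COMPLEMENT[[chars[i]]] != chars[j]) next
      dg <- 0
      a <- i; b <- j
      while (a - 1L >= 1L && b + 1L <= n &&
             COMPLEMENT[[chars[a - 1L]]] == chars[b + 1L]) {
        dg <- dg + NN_DG[[paste0(chars[a - 1L], chars[a])]]
        a <- a - 1L; b <- b + 1L
      }
      if (dg < best) best <- dg
    }
  }
  best
}

#' Measure primer properties
#'
#' Computes the properties an acceptable PCR primer is screened on:
#' length, GC percentage, melting temperature (nearest-neighbor
#' thermodynamics with the stated salt and primer concentrations, or the
#' Wallace rule), the count of G/C among the five 3'-terminal bases (GC
#' clamp), a repeat flag (mononucleotide run of 4+, or a dinucleotide
#' motif repeated 4+ times), and simplified self-dimer and hairpin free
#' energies (nearest-neighbor stack sums over perfect-complement
#' stretches; no loop or bulge terms).
#'
#' @param seq Primer sequence over A/C/G/T.
#' @param salt_mM Monovalent cation concentration (default 50 mM).
#' @param primer_nM Primer concentration (default 500 nM).
#' @param tm_method `"nn"` (nearest neighbor, default) or `"wallace"`.
#' @return A `primer_report`: list with `sequence`, `length`, `gc_pct`,
#'   `tm_c`, `gc3_count`, `repeat_flag`, `dimer_dg`, `hairpin_dg`, and a
#'   `grades` slot filled by [grade_primer()].
#' @examples
#' evaluate_primer("GGTCTTTAGCAACCCTGA")
#' @export
evaluate_primer <- function(seq, salt_mM = 50, primer_nM = 500,
                            tm_method = c("nn", "wallace")) {
  s <- toupper(seq)
  if (!nzchar(s) || grepl("[^ACGT]", s))
    stop("primer sequences must be non-empty and contain only A, C, G, T",
         call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  gc_pct <- 100 * sum(chars %in% c("G", "C")) / n
  tail5 <- chars[max(1L, n - 4L):n]
  rep_flag <- grepl("(.)\\1{3}", s) || grepl("([ACGT]{2})\\1{3}", s)
  rep <- structure(
    list(sequence = s,
         length = n,
         gc_pct = gc_pct,
         tm_c = melting_temperature(s, salt_mM, primer_nM,
                                    match.arg(tm_method)),
         gc3_count = sum(tail5 %in% c("G", "C")),
         repeat_flag = rep_flag,
         dimer_dg = dimer_dg(chars),
         hairpin_dg = hairpin_dg(chars),
         grades = NULL),
    class = "primer_report")
  grade_primer(rep)
}

#' Grade a primer report against the acceptance thresholds
#'
#' A good primer has GC between 40 and 60 percent (inclusive), melting
#' temperature above 52 degrees C, two to three G/C among the five
#' 3'-terminal bases, no repeats, and self-structure free energies above
#' -4 kcal/mol (dimer) and -3 kcal/mol (hairpin). Values outside a band
#' grade FAIL; values outside but within the `margins` of the boundary
#' grade WARN.
#'
#' @param rep A `primer_report` from [evaluate_primer()].
#' @param margins Named list of WARN margins: `gc` (percentage points),
#'   `tm` (degrees C), `dg` (kcal/mol).
#' @return The report with its `grades` slot filled (named character
#'   vector over gc, tm, clamp, repeats, dimer, hairpin).
#' @export
grade_primer <- function(rep, margins = list(gc = 5, tm = 2, dg = 1)) {
  stopifnot(inherits(rep, "primer_report"))
  band <- function(value, lo, hi, margin) {
    if (value >= lo && value <= hi) "PASS"
    else if (value >= lo - margin && value <= hi + margin) "WARN"
    else "FAIL"
  }
  grades <- c(
    gc = band(rep$gc_pct, 40, 60, margins$gc),
    tm = if (rep$tm_c > 52) "PASS"
         else if (rep$tm_c > 52 - margins$tm) "WARN" else "FAIL",
    clamp = if (rep$gc3_count >= 2 && rep$gc3_count <= 3) "PASS"
            else if (rep$gc3_count %in% c(1L, 4L)) "WARN" else "FAIL",
    repeats = if (rep$repeat_flag) "FAIL" else "PASS",
    dimer = if (rep$dimer_dg > -4) "PASS"
            else if (rep$dimer_dg > -4 - margins$dg) "WARN" else "FAIL",
    hairpin = if (rep$hairpin_dg > -3) "PASS"
              else if (rep$hairpin_dg > -3 - margins$dg) "WARN" else "FAIL")
  rep$grades <- grades
  rep
}

#' @export
print.primer_report <- function(x, ...) {
  cat(sprintf("primer %s\n", x$sequence))
  cat(sprintf("  length  %d nt\n  GC      %.0f%% [%s]\n  Tm      %.1f C [%s]\n",
              x$length, x$gc_pct, x$grades[["gc"]], x$tm_c, x$grades[["tm"]]))
  cat(sprintf("  3' G/C  %d of last 5 [%s]\n  repeats %s [%s]\n",
              x$gc3_count, x$grades[["clamp"]],
              if (x$repeat_flag) "yes" else "no", x$grades[["repeats"]]))
  cat(sprintf("  dimer   %.2f kcal/mol [%s]\n  hairpin %.2f kcal/mol [%s]\n",
              x$dimer_dg, x$grades[["dimer"]],
              x$hairpin_dg, x$grades[["hairpin"]]))
  invisible(x)
}
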