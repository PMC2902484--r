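# Shared helpers: alignment builders and independent brute-force oracles
# (these never call the code paths they are used to check).

aln_from <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("s", seq_along(seqs))
  msa(seqs)
}

# random gapless DNA alignment with some column-level noise
random_dna_aln <- function(nseq, len, p_mut = 0.15) {
  ref <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m <- matrix(rep(ref, each = nseq), nrow = nseq)
  mut <- matrix(stats::runif(nseq * len) < p_mut, nrow = nseq)
  m[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- paste0("s", seq_len(nseq))
  msa(seqs, alphabet = "DNA")
}

# Brute-force per-column scores: loop over sequences, no frequency table.
brute_scores <- function(a, method, ref_symbols, w = NULL, gap_weight = NULL) {
  m <- msa_matrix(a)
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    r <- ref_symbols[j]
    switch(method,
      weighted = {
        tot <- 0
        for (ch in col) {
          tot <- tot + if (ch == "-" || r == "-") gap_weight else w[r, ch]
        }
        tot / n
      },
      dnaw = if (r == "-") 0 else sum(col == r) / n,
      entropy = {
        h <- 0
        for (sym in unique(col)) {
          f <- sum(col == sym) / n
          h <- h - f * log2(f)
        }
        -h
      },
      variability = 1 - length(unique(col)))
  }, numeric(1L))
}

# Quadratic-time direct DFT low-pass oracle mirroring the filter contract.
direct_dft_lowpass <- function(x, window) {
  n <- length(x)
  kc <- ceiling(n / (2 * window))
  ks <- 0:(n - 1)
  co <- vapply(ks, function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1L))
  keep <- pmin(ks, n - ks) <= kc
  co[!keep] <- 0
  out <- vapply(0:(n - 1), function(t)
    sum(co * exp(2i * pi * ks * t / n)) / n, complex(1L))
  Re(out)
}

write_temp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
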