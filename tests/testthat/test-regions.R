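# Build a small scaffold: DNA alignment, entropy scoring, raw/smoothed
# cutoffs, so region/SNP rules can be exercised on known columns.
scan_parts <- function(a, ...) {
  ft <- build_frequency_table(a)
  ref <- call_consensus(ft)
  raw <- score_entropy(ft)
  cut_raw <- compute_cutoffs(raw)
  smoothed <- smooth_fft(raw, ...)
  cut_smooth <- compute_cutoffs(smoothed$values)
  list(ft = ft, ref = ref, raw = raw, cut_raw = cut_raw,
       smoothed = smoothed, cut_smooth = cut_smooth)
}

test_that("a 2/2 split column below cutoff is a putative SNP", {
  seqs <- paste0(strrep("A", 10), c("A", "A", "C", "C"), strrep("G", 10))
  a <- do.call(aln_from, as.list(seqs))
  p <- scan_parts(a)
  snps <- call_snps(p$raw, p$cut_raw, p$ft, p$ref)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$column, 11L)
  expect_equal(snps$ref, "A")          # lexicographic tie-break
  expect_equal(snps$variants, "C:2")
  expect_true(snps$raw_score < p$cut_raw$low)
})

test_that("a single-copy variant vetoes the column", {
  # {A:5, C:2, T:1}: C qualifies but T occurs once
  seqs <- paste0(strrep("A", 10), c("A","A","A","A","A","C","C","T"),
                 strrep("G", 10))
  a <- do.call(aln_from, as.list(seqs))
  p <- scan_parts(a)
  snps <- call_snps(p$raw, p$cut_raw, p$ft, p$ref)
  expect_equal(nrow(snps), 0L)
  # the same column with T upgraded to a second copy is a SNP
  seqs2 <- paste0(strrep("A", 10), c("A","A","A","A","C","C","T","T"),
                  strrep("G", 10))
  p2 <- scan_parts(do.call(aln_from, as.list(seqs2)))
  snps2 <- call_snps(p2$raw, p2$cut_raw, p2$ft, p2$ref)
  expect_equal(snps2$variants, "C:2,T:2")
})

test_that("SNP calling is DNA-only and never fires below four sequences", {
  p <- msa(c(a = "MKLV", b = "MKIV", c = "MKIV", d = "MKLV"),
           alphabet = "PROTEIN")
  ftp <- build_frequency_table(p)
  raw <- score_entropy(ftp)
  expect_error(call_snps(raw, compute_cutoffs(raw), ftp,
                         call_consensus(ftp)), "DNA-only")

  # nseq = 3 with a 1/2 split never qualifies (the variant has 2 copies
  # but the rule set cannot be satisfied at 3 sequences)
  seqs <- paste0(strrep("A", 10), c("A", "C", "C"), strrep("G", 10))
  a <- do.call(aln_from, as.list(seqs))
  pp <- scan_parts(a)
  expect_equal(nrow(call_snps(pp$raw, pp$cut_raw, pp$ft, pp$ref)), 0L)
})

test_that("gap-only variation is a SNP unless disabled", {
  seqs <- paste0(strrep("ACGT", 4), c("A", "A", "-", "-"), strrep("CA", 4))
  a <- do.call(aln_from, as.list(seqs))
  p <- scan_parts(a)
  on_ <- call_snps(p$raw, p$cut_raw, p$ft, p$ref, count_gaps = TRUE)
  off_ <- call_snps(p$raw, p$cut_raw, p$ft, p$ref, count_gaps = FALSE)
  expect_equal(on_$variants, "-:2")
  expect_equal(nrow(off_), 0L)
})

test_that("lowering the low cutoff never increases the SNP count", {
  fx <- generate_msa(8, 200, data.frame(start = 80, end = 110,
                                        variant_fraction = 0.6), seed = 21)
  ft <- build_frequency_table(fx$alignment)
  ref <- call_consensus(ft)
  raw <- score_entropy(ft)
  cut <- compute_cutoffs(raw)
  n_prev <- Inf
  for (drop in c(0, 0.1, 0.3, 0.6, 1)) {
    cut2 <- cut; cut2$low <- cut$low - drop
    n <- nrow(call_snps(raw, cut2, ft, ref))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("divergent regions need >= 2 SNPs on DNA; score is the raw mean", {
  fx <- generate_msa(8, 300, data.frame(start = 140, end = 154,
                                        variant_fraction = 0.6), seed = 5)
  res <- scan_msa(fx$alignment, methods = "entropy")
  t <- res$tracks$entropy
  div <- t$regions[t$regions$kind == "DIVERGENT", ]
  expect_gte(nrow(div), 1L)
  expect_true(all(div$snp_count >= 2L))
  # characteristic score = arithmetic mean of raw scores over the region
  for (i in seq_len(nrow(div))) {
    cols <- as.character(div$start[i]:div$end[i])
    expect_equal(div$score[i], mean(t$raw$values[cols]), tolerance = 1e-12)
  }
  # every SNP column lies below the raw-track low cutoff
  expect_true(all(t$snps$raw_score < t$cutoffs_raw$low))
  # regions are sorted and disjoint
  reg <- t$regions
  if (nrow(reg) > 1L)
    expect_true(all(reg$start[-1L] > reg$end[-nrow(reg)]))
})

test_that("a divergent dip with a single SNP column is discarded", {
  # one isolated 2/2 column: below both cutoffs but only 1 SNP
  seqs <- paste0(strrep("ACGTG", 8), c("A","A","C","C"), strrep("TTCAG", 8))
  a <- do.call(aln_from, as.list(seqs))
  res <- scan_msa(a, methods = "entropy")
  t <- res$tracks$entropy
  expect_equal(nrow(t$snps), 1L)
  expect_equal(sum(t$regions$kind == "DIVERGENT"), 0L)
})

test_that("protein runs above the high cutoff become conserved regions", {
  withr::with_seed(31, {
    aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K")
    core <- sample(aas, 60, replace = TRUE)
    mk <- function() {
      s <- core
      noisy <- c(1:20, 41:60)   # keep 21:40 invariant
      flip <- noisy[runif(length(noisy)) < 0.5]
      s[flip] <- sample(aas, length(flip), replace = TRUE)
      paste(s, collapse = "")
    }
    p <- msa(c(a = mk(), b = mk(), c = mk(), d = mk()),
             alphabet = "PROTEIN")
  })
  res <- scan_msa(p, methods = "entropy")
  reg <- res$tracks$entropy$regions
  con <- reg[reg$kind == "CONSERVED", ]
  expect_gte(nrow(con), 1L)
  expect_true(all(is.na(con$snp_count)))
  expect_true(any(con$start <= 25 & con$end >= 35))
})

test_that("length buckets split at six and eleven positions", {
  expect_equal(bucket_length(4), "SHORT")
  expect_equal(bucket_length(5), "SHORT")
  expect_equal(bucket_length(6), "MEDIUM")
  expect_equal(bucket_length(11), "MEDIUM")
  expect_equal(bucket_length(12), "LONG")
  expect_equal(bucket_length(15), "LONG")
})

test_that("summaries count divergent coverage and buckets", {
  empty <- data.frame(kind = character(), start = integer(),
                      end = integer(), length = integer(),
                      score = numeric(), snp_count = integer(),
                      bucket = character())
  s0 <- summarize_regions(empty, 100)
  expect_equal(s0$n_divergent, 0L)
  expect_equal(s0$divergent_pct, 0)

  one <- data.frame(kind = "DIVERGENT", start = 11L, end = 20L,
                    length = 10L, score = -1, snp_count = 2L,
                    bucket = "MEDIUM")
  expect_equal(summarize_regions(one, 100)$divergent_pct, 10)

  three <- data.frame(kind = "DIVERGENT", start = c(1L, 20L, 50L),
                      end = c(4L, 27L, 64L), length = c(4L, 8L, 15L),
                      score = -1, snp_count = 2L,
                      bucket = c("SHORT", "MEDIUM", "LONG"))
  expect_equal(summarize_regions(three, 100)$buckets,
               c(SHORT = 1L, MEDIUM = 1L, LONG = 1L))
})
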