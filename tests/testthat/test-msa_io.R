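test_that("FASTA alignments load with validation", {
  f <- write_temp(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAC"), ".fa")
  a <- read_alignment(f)
  expect_s3_class(a, "msa")
  expect_equal(a$nseq, 2L)
  expect_equal(a$length, 10L)
  expect_equal(a$alphabet, "DNA")

  ragged <- write_temp(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), ".fa")
  expect_error(read_alignment(ragged), "unequal sequence lengths")

  single <- write_temp(c(">a", "ACGT"), ".fa")
  expect_error(read_alignment(single), "at least two")

  dup <- write_temp(c(">a", "ACGT", ">a", "ACGT"), ".fa")
  expect_error(read_alignment(dup), "duplicate")
})

test_that("format is sniffed from content, overriding a misleading hint", {
  clustal <- c("CLUSTAL format alignment", "", "",
               "a               ACGTACGTACGT",
               "b               ACGTACGAACGT",
               "c               ACGTACGCACGT",
               "                ******* ****")
  # file named .fasta and hinted as fasta: content signature must win
  f <- write_temp(clustal, ".fasta")
  a <- read_alignment(f, format = "fasta")
  expect_equal(a$nseq, 3L)
  expect_equal(unname(a$records[["b"]]), "ACGTACGAACGT")

  # identical content under a different name parses identically
  f2 <- write_temp(clustal, ".weird_extension")
  expect_identical(read_alignment(f2)$records, a$records)

  junk <- write_temp(c("this is not", "any alignment format"))
  expect_error(read_alignment(junk), "unrecognized format")
  expect_error(read_alignment(write_temp(character())), "unrecognized format")
})

test_that("PHYLIP (both layouts), MSF and NEXUS parse", {
  interleaved <- write_temp(c(" 3 20",
                              "sa         ACGTACGTAC",
                              "sb         ACGTACGAAC",
                              "sc         ACGTACGCAC",
                              "",
                              "GTACGTACGT", "GTACGTACGT", "GTACGTACGT"))
  a <- read_alignment(interleaved)
  expect_equal(a$length, 20L)
  expect_equal(unname(a$records[["sb"]]), "ACGTACGAACGTACGTACGT")

  sequential <- write_temp(c(" 3 12",
                             "sa         ACGTACGTACGT",
                             "sb         ACGTACGAACGT",
                             "sc         ACGTACGCACGT"))
  b <- read_alignment(sequential)
  expect_equal(b$nseq, 3L)
  expect_equal(unname(b$records[["sc"]]), "ACGTACGCACGT")

  msf <- write_temp(c("!!NA_MULTIPLE_ALIGNMENT 1.0", "",
                      " x  MSF: 12  Type: N  Check: 1234 ..", "",
                      " Name: sa  Len: 12  Check: 1  Weight: 1.00",
                      " Name: sb  Len: 12  Check: 2  Weight: 1.00",
                      " Name: sc  Len: 12  Check: 3  Weight: 1.00", "",
                      "//", "",
                      "sa  ACGTACGTACGT",
                      "sb  ACGTACGAACGT",
                      "sc  ACGTACGCACGT"))
  d <- read_alignment(msf)
  expect_equal(unname(d$records[["sb"]]), "ACGTACGAACGT")

  nexus <- write_temp(c("#NEXUS", "BEGIN DATA;",
                        "DIMENSIONS NTAX=3 NCHAR=12;",
                        "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
                        "sa ACGTACGTACGT", "sb ACGTACGAACGT",
                        "sc ACGTACGCACGT", ";", "END;"))
  e <- read_alignment(nexus)
  expect_equal(unname(e$records[["sc"]]), "ACGTACGCACGT")
})

test_that("alphabet detection follows the 90% nucleotide rule", {
  expect_equal(detect_alphabet("ACGTACGT"), "DNA")
  expect_equal(detect_alphabet("MKLVWPQRSTED"), "PROTEIN")
  # all eight characters are IUPAC nucleotide symbols -> fraction 1 > 0.9
  expect_equal(detect_alphabet("ACGTRYKM"), "DNA")
  # 10 nucleotide chars out of 12 = 0.833 < 0.9 -> protein
  expect_equal(detect_alphabet("ACGTACGTACEF"), "PROTEIN")
  expect_error(detect_alphabet("----"), "all characters are gaps")
})

test_that("dots normalize to gaps and case folds upward", {
  a <- msa(c(x = "ac.tac", y = "ACGTAC"))
  expect_equal(unname(a$records[["x"]]), "AC-TAC")
})

test_that("written FASTA and Clustal read back identically", {
  a <- random_dna_aln(6, 90)
  ff <- tempfile(fileext = ".fa")
  write_fasta(a, ff)
  expect_identical(read_alignment(ff)$records, a$records)

  fc <- tempfile(fileext = ".aln")
  write_clustal(a, fc)
  expect_identical(read_alignment(fc)$records, a$records)
})

test_that("JSON round-trips alignments and result bundles", {
  a <- random_dna_aln(5, 60)
  b <- from_json(to_json(a))
  expect_identical(b$records, a$records)
  expect_identical(b$alphabet, a$alphabet)

  fx <- generate_msa(8, 200, data.frame(start = 90, end = 104,
                                        variant_fraction = 0.6), seed = 4)
  res <- scan_msa(fx$alignment)
  back <- from_json(to_json(res))
  expect_equal(length(back$tracks), length(res$tracks))
  for (m in names(res$tracks)) {
    expect_equal(unname(unlist(back$tracks[[m]]$raw$values)),
                 unname(res$tracks[[m]]$raw$values), tolerance = 1e-12)
    expect_equal(back$tracks[[m]]$regions$start,
                 res$tracks[[m]]$regions$start)
    expect_equal(back$tracks[[m]]$cutoffs_raw$low,
                 res$tracks[[m]]$cutoffs_raw$low, tolerance = 1e-12)
  }

  expect_error(from_json(substr(to_json(a), 1, 40)))
  expect_error(from_json('{"no_schema": true}'), "malformed")
})

test_that("GFF3 output is well-formed and validates coordinates", {
  regions <- data.frame(kind = "DIVERGENT", start = 10L, end = 18L,
                        length = 9L, score = -1.2, snp_count = 3L,
                        bucket = "MEDIUM", stringsAsFactors = FALSE)
  txt <- write_gff(regions, NULL, landmark = "aln1",
                   alignment_length = 100L)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "##gff-version 3")
  feat <- strsplit(lines[3], "\t")[[1]]
  expect_equal(feat[3], "divergent_region")
  expect_equal(feat[4:5], c("10", "18"))
  expect_equal(feat[6], "-1.200")

  # empty feature set -> header-only document
  empty <- write_gff(regions[0, ], NULL, alignment_length = 50L)
  expect_equal(length(strsplit(empty, "\n")[[1]]), 2L)

  bad <- regions; bad$start <- 20L
  expect_error(write_gff(bad, NULL, alignment_length = 100L), "invalid")
  expect_error(write_gff(regions, NULL, alignment_length = 15L), "beyond")
})

test_that("GFF3 output parses with a conforming reader", {
  skip_if_not_installed("rtracklayer")
  fx <- generate_msa(8, 300, data.frame(start = c(100, 200),
                                        end = c(114, 212),
                                        variant_fraction = 0.6), seed = 11)
  res <- scan_msa(fx$alignment, methods = "entropy")
  t <- res$tracks$entropy
  f <- tempfile(fileext = ".gff3")
  write_gff(t$regions, t$snps, landmark = "aln", file = f,
            alignment_length = res$alignment_length)
  g <- rtracklayer::import(f)
  expect_equal(length(g), nrow(t$regions) + nrow(t$snps))
  expect_true(all(BiocGenerics::start(g) <= BiocGenerics::end(g)))
  div <- g[g$type == "divergent_region"]
  got <- data.frame(start = BiocGenerics::start(div),
                    end = BiocGenerics::end(div))
  want <- t$regions[t$regions$kind == "DIVERGENT", c("start", "end")]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})
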