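# GFF3 export of called regions and putative SNPs.

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write regions and putative SNPs as GFF3
#'
#' Emits one `divergent_region`/`conserved_region` feature per region
#' (score column = characteristic score) and one `sequence_variant`
#' feature per SNP, in 1-based inclusive coordinates on the alignment
#' landmark.
#'
#' @param regions Region data frame from [extract_regions()] (may be
#'   empty).
#' @param snps SNP data frame from [call_snps()] (may be `NULL`/empty).
#' @param landmark Sequence-region name used in column 1 (e.g. the
#'   alignment name).
#' @param source_tag Column-2 source tag.
#' @param file Output path, or `NULL` to return the GFF3 text.
#' @param alignment_length Landmark length for the sequence-region
#'   pragma; defaults to the largest feature end.
#' @return The GFF3 text (invisibly when written to `file`).
#' @export
write_gff <- function(regions, snps = NULL, landmark = "alignment",
                      source_tag = "divscan", file = NULL,
                      alignment_length = NULL) {
  feats <- list()
  if (!is.null(regions) && nrow(regions) > 0L) {
    if (any(regions$start > regions$end) || any(regions$start < 1L))
      stop("invalid region coordinates (start > end or < 1)", call. = FALSE)
    feats <- c(feats, lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      type <- if (r$kind == "DIVERGENT") "divergent_region"
              else "conserved_region"
      attrs <- sprintf("ID=%s_%d;length=%d;bucket=%s",
                       tolower(r$kind), i, r$length, r$bucket)
      if (!is.na(r$snp_count))
        attrs <- paste0(attrs, sprintf(";snp_count=%d", r$snp_count))
      sprintf("%s\t%s\t%s\t%d\t%d\t%.3f\t.\t.\t%s",
              gff3_escape(landmark), gff3_escape(source_tag), type,
              r$start, r$end, r$score, attrs)
    }))
  }
  if (!is.null(snps) && nrow(snps) > 0L) {
    if (any(snps$column < 1L))
      stop("invalid SNP coordinates (< 1)", call. = FALSE)
    feats <- c(feats, lapply(seq_len(nrow(snps)), function(i) {
      s <- snps[i, ]
      sprintf("%s\t%s\tsequence_variant\t%d\t%d\t%.3f\t.\t.\tID=snp_%d;reference=%s;variants=%s",
              gff3_escape(landmark), gff3_escape(source_tag),
              s$column, s$column, s$raw_score, i, s$ref,
              gff3_escape(s$variants))
    }))
  }
  ends <- c(regions$end, snps$column)
  if (is.null(alignment_length))
    alignment_length <- if (length(ends)) max(ends) else 1L
  if (length(ends) && max(ends) > alignment_length)
    stop("feature beyond landmark length", call. = FALSE)
  txt <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", gff3_escape(landmark),
                   as.integer(alignment_length)),
           unlist(feats))
  if (is.null(file)) return(paste(txt, collapse = "\n"))
  writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}

#' Write the region/SNP tables as TSV
#'
#' @param regions Region data frame.
#' @param snps SNP data frame or `NULL`.
#' @param file Output path.
#' @param sort_by `"position"` or `"score"` for the region table.
#' @return `file`, invisibly.
#' @export
write_tsv_report <- function(regions, snps = NULL, file,
                             sort_by = c("position", "score")) {
  sort_by <- match.arg(sort_by)
  ord <- if (sort_by == "position") order(regions$start)
         else order(regions$score)
  con <- file(file, "w")
  on.exit(close(con))
  utils::write.table(regions[ord, , drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(snps) && nrow(snps) > 0L) {
    writeLines("", con)
    utils::write.table(snps, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
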