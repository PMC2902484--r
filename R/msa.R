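#' @keywords internal
"_PACKAGE"

GAP <- "-"

# IUPAC nucleotide symbols accepted when deciding DNA vs protein
DNA_SYMBOLS <- c("A", "C", "G", "T", "U", "N",
                 "R", "Y", "M", "W", "S", "K", "B", "D", "H", "V")

#' Construct a multiple sequence alignment object
#'
#' An `msa` holds an ordered set of equal-length gapped sequences together
#' with the alphabet they were detected (or declared) to use. Residues are
#' normalized to upper case and the alternative gap character `.` is
#' rewritten to `-`.
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   the sequence identifiers). All strings must have equal length.
#' @param alphabet `"DNA"`, `"PROTEIN"`, or `NULL` to auto-detect with
#'   [detect_alphabet()].
#' @return An object of class `msa`: a list with elements `records` (named
#'   character vector), `alphabet`, `length` (columns), `nseq`.
#' @examples
#' aln <- msa(c(s1 = "ACGTACGT", s2 = "ACGTACCT"))
#' aln$alphabet
#' @export
msa <- function(sequences, alphabet = NULL) {
  if (length(sequences) < 2L)
    stop("an alignment needs at least two sequences", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry a non-empty identifier", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(gsub(".", GAP, sequences, fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths: ", paste(lens, collapse = ", "),
         call. = FALSE)
  if (lens[1L] < 1L)
    stop("alignment has zero columns", call. = FALSE)
  if (is.null(alphabet)) alphabet <- detect_alphabet(seqs)
  alphabet <- match.arg(alphabet, c("DNA", "PROTEIN"))
  bad <- grepl("[^A-Z*-]", seqs)
  if (any(bad))
    stop("unrecognized residue characters in: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  structure(
    list(records = stats::setNames(seqs, ids),
         alphabet = alphabet,
         length = unname(lens[1L]),
         nseq = length(seqs)),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("%s multiple sequence alignment: %d sequences x %d columns\n",
              x$alphabet, x$nseq, x$length))
  show <- utils::head(x$records, 6L)
  for (i in seq_along(show)) {
    s <- show[[i]]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-20s %s\n", names(show)[i], s))
  }
  if (x$nseq > 6L) cat(sprintf("  ... and %d more\n", x$nseq - 6L))
  invisible(x)
}

#' Character matrix view of an alignment
#'
#' @param a An [msa] object.
#' @return A `nseq x length` character matrix with sequence identifiers as
#'   row names.
#' @export
msa_matrix <- function(a) {
  stopifnot(inherits(a, "msa"))
  m <- do.call(rbind, strsplit(a$records, "", fixed = TRUE))
  rownames(m) <- names(a$records)
  m
}

#' Decide whether aligned sequences are DNA or protein
#'
#' The alignment is classed as DNA when the fraction of non-gap characters
#' that are IUPAC nucleotide symbols (including ambiguity codes and U/N)
#' exceeds `threshold`; otherwise protein. Case-insensitive.
#'
#' @param sequences Character vector of (possibly gapped) sequences.
#' @param threshold Minimum nucleotide fraction for a DNA call (default
#'   0.9).
#' @return `"DNA"` or `"PROTEIN"`.
#' @examples
#' detect_alphabet("ACGTACGT")
#' detect_alphabet("MKLVWPQRSTED")
#' @export
detect_alphabet <- function(sequences, threshold = 0.9) {
  chars <- unlist(strsplit(toupper(paste(sequences, collapse = "")), "",
                           fixed = TRUE))
  chars <- chars[!chars %in% c(GAP, ".")]
  if (length(chars) == 0L)
    stop("cannot detect alphabet: all characters are gaps", call. = FALSE)
  frac <- mean(chars %in% DNA_SYMBOLS)
  if (frac > threshold) "DNA" else "PROTEIN"
}

# ---- format sniffing and reading -------------------------------------------

sniff_format <- function(lines) {
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) return(NA_character_)
  first <- nonblank[1L]
  if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) return("nexus")
  if (grepl("^\\s*>", first)) return("fasta")
  if (grepl("^\\s*CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  # MSF: a header line "... MSF: <len> ... .." somewhere near the top
  if (any(grepl("MSF:", utils::head(nonblank, 10L)))) return("msf")
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) return("phylip")
  NA_character_
}

#' Read a multiple sequence alignment from file
#'
#' The format is recognised from the file contents, not the file name:
#' FASTA (`>`), Clustal (header word), NEXUS (`#NEXUS`), PHYLIP (numeric
#' header; interleaved or sequential), and MSF (`MSF:` header) are
#' accepted. A `format` hint is consulted only when the content signature
#' is inconclusive, so a misleading hint cannot misparse a recognisable
#' file.
#'
#' @param file Path to the alignment file.
#' @param format Optional hint, one of `"fasta"`, `"clustal"`,
#'   `"phylip"`, `"msf"`, `"nexus"`.
#' @param alphabet Optional `"DNA"`/`"PROTEIN"` override; auto-detected by
#'   default.
#' @return An [msa] object.
#' @export
read_alignment <- function(file, format = NULL, alphabet = NULL) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop("unrecognized format: file is empty", call. = FALSE)
  fmt <- sniff_format(lines)
  if (is.na(fmt)) {
    if (!is.null(format)) {
      fmt <- match.arg(format, c("fasta", "clustal", "phylip", "msf", "nexus"))
    } else {
      stop("unrecognized format: no known content signature found",
           call. = FALSE)
    }
  }
  seqs <- switch(fmt,
    fasta   = read_fasta_records(file),
    clustal = read_clustal_records(file),
    phylip  = read_seqinr_records(file, "phylip"),
    msf     = read_seqinr_records(file, "msf"),
    nexus   = read_nexus_records(file))
  msa(seqs, alphabet = alphabet)
}

read_fasta_records <- function(file) {
  set <- tryCatch(Biostrings::readBStringSet(file),
                  error = function(e)
                    stop("unrecognized format: corrupt FASTA (",
                         conditionMessage(e), ")", call. = FALSE))
  seqs <- as.character(set)
  # FASTA headers: identifier is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

read_clustal_records <- function(file) {
  set <- tryCatch(
    Biostrings::readAAMultipleAlignment(file, format = "clustal"),
    error = function(e)
      stop("unrecognized format: corrupt Clustal (",
           conditionMessage(e), ")", call. = FALSE))
  as.character(Biostrings::unmasked(set))
}

read_seqinr_records <- function(file, fmt) {
  r <- tryCatch(seqinr::read.alignment(file, format = fmt),
                error = function(e)
                  stop("unrecognized format: corrupt ", toupper(fmt), " (",
                       conditionMessage(e), ")", call. = FALSE))
  stats::setNames(unlist(r$seq), trimws(r$nam))
}

read_nexus_records <- function(file) {
  r <- tryCatch(ape::read.nexus.data(file),
                error = function(e)
                  stop("unrecognized format: corrupt NEXUS (",
                       conditionMessage(e), ")", call. = FALSE))
  vapply(r, paste, character(1L), collapse = "")
}

# ---- writers ----------------------------------------------------------------

#' Write an alignment to FASTA or Clustal
#'
#' @param a An [msa] object.
#' @param file Output path.
#' @param width Line width for sequence blocks.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(a, file, width = 60L) {
  stopifnot(inherits(a, "msa"))
  set <- Biostrings::BStringSet(a$records)
  Biostrings::writeXStringSet(set, file, width = as.integer(width))
  invisible(file)
}

#' @rdname write_fasta
#' @export
write_clustal <- function(a, file, width = 60L) {
  stopifnot(inherits(a, "msa"))
  ids <- names(a$records)
  pad <- max(nchar(ids)) + 3L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL format alignment", "", ""), con)
  starts <- seq(1L, a$length, by = width)
  for (s in starts) {
    e <- min(s + width - 1L, a$length)
    chunk <- substr(a$records, s, e)
    block <- vapply(seq_along(ids), function(i)
      sprintf("%-*s%s", pad, ids[i], chunk[i]), character(1L))
    # conservation line: '*' where the column is invariant
    cols <- do.call(rbind, strsplit(chunk, "", fixed = TRUE))
    stars <- apply(cols, 2L, function(cc)
      if (length(unique(cc)) == 1L && cc[1L] != GAP) "*" else " ")
    writeLines(c(block, sprintf("%-*s%s", pad, "", paste(stars, collapse = ""))),
               con)
    writeLines("", con)
  }
  invisible(file)
}

# ---- JSON round trip --------------------------------------------------------

# drop S3 classes from nested track/cutoff objects so the bundle
# serializes as plain JSON structures (data frames keep their class)
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Serialize an alignment (or result bundle) to JSON
#'
#' Alignments and analysis bundles share a versioned-schema JSON envelope
#' so that intermediate results can be cached on disk and reloaded without
#' reparsing the source alignment.
#'
#' @param x An [msa] object or a `divscan_result` bundle from [scan_msa()].
#' @return A JSON string (class `json`).
#' @export
to_json <- function(x) {
  if (inherits(x, "msa")) {
    payload <- list(schema = "divscan-msa/1",
                    alphabet = x$alphabet,
                    ids = names(x$records),
                    sequences = unname(x$records))
  } else if (inherits(x, "divscan_result")) {
    payload <- c(list(schema = "divscan-result/1"), strip_classes(unclass(x)))
  } else {
    stop("no JSON schema for objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname to_json
#' @param txt JSON text produced by [to_json()].
#' @export
from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (is.null(obj$schema))
    stop("malformed document: missing schema tag", call. = FALSE)
  if (identical(obj$schema, "divscan-msa/1")) {
    return(msa(stats::setNames(obj$sequences, obj$ids),
               alphabet = obj$alphabet))
  }
  if (identical(obj$schema, "divscan-result/1")) {
    obj$schema <- NULL
    return(structure(obj, class = "divscan_result"))
  }
  stop("malformed document: unknown schema ", obj$schema, call. = FALSE)
}
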