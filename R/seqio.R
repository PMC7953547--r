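#' @importFrom Biostrings DNAStringSet BStringSet readBStringSet
#'   writeXStringSet reverseComplement PhredQuality QualityScaledDNAStringSet
#'   quality width
#' @importFrom S4Vectors mcols
NULL

# Uppercase and map everything outside {A,C,G,T,N} to N.
.normalizeSeq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# First lines of a possibly gzipped text file, for format pre-checks.
.headLines <- function(path, n = 1L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, n = n, warn = FALSE)
}

#' Read a FASTA file into a normalized DNAStringSet
#'
#' Sequences are uppercased and any character outside `A`,`C`,`G`,`T`,`N`
#' (ambiguity codes, stray symbols) is mapped to `N`. Plain and gzipped files
#' are both accepted.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a [Biostrings::DNAStringSet] with record ids as names, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "ACRT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- .headLines(path)
  if (length(first) == 0L)
    stop("FASTA format error at line 1: file is empty: ", path)
  if (!startsWith(first[[1L]], ">"))
    stop("FASTA format error at line 1: expected '>' header, got: ",
         substr(first[[1L]], 1L, 40L))
  x <- readBStringSet(path)
  if (length(x) == 0L)
    stop("FASTA format error at line 1: no records in ", path)
  DNAStringSet(stats::setNames(.normalizeSeq(as.character(x)), names(x)))
}

#' Read a FASTQ file into a quality-carrying DNAStringSet
#'
#' Four-line FASTQ records, optionally gzipped. Sequence normalization is the
#' same as [readFasta()]. Phred qualities are carried along (so they can be
#' round-tripped) but are never used in extension scoring: overlap quality is
#' defined purely as the count of agreeing bases.
#'
#' @param path path to a FASTQ file (optionally gzip-compressed).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- .headLines(path)
  if (length(first) == 0L)
    stop("FASTQ format error at line 1: file is empty: ", path)
  if (!startsWith(first[[1L]], "@"))
    stop("FASTQ format error at line 1: expected '@' header, got: ",
         substr(first[[1L]], 1L, 40L))
  con <- gzfile(path, open = "rt")
  nlines <- 0L
  repeat {
    chunk <- readLines(con, n = 65536L, warn = FALSE)
    if (length(chunk) == 0L) break
    nlines <- nlines + length(chunk)
  }
  close(con)
  if (nlines %% 4L != 0L)
    stop("FASTQ format error at line ", nlines,
         ": truncated record (line count not a multiple of 4)")
  x <- tryCatch(
    readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("FASTQ format error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  quals <- S4Vectors::mcols(x)$qualities
  bad <- which(Biostrings::width(quals) != Biostrings::width(x))
  if (length(bad))
    stop("FASTQ format error: quality length differs from sequence length ",
         "for record(s): ", paste(head(names(x)[bad], 5L), collapse = ", "))
  seqs <- DNAStringSet(stats::setNames(.normalizeSeq(as.character(x)), names(x)))
  QualityScaledDNAStringSet(seqs, PhredQuality(quals))
}

#' Write sequences as wrapped FASTA
#'
#' @param records a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @param wrap line width for sequence wrapping (default 60).
#' @return invisibly, `path`.
#' @export
writeFasta <- function(records, path, wrap = 60L) {
  if (is.character(records))
    records <- DNAStringSet(records)
  if (length(records) && (is.null(names(records)) || any(!nzchar(names(records)))))
    stop("all records must have non-empty ids")
  stopifnot(wrap >= 1L)
  writeXStringSet(records, path, width = as.integer(wrap))
  invisible(path)
}

#' Write reads as 4-line FASTQ
#'
#' Qualities are taken from the object when it is quality-scaled; otherwise a
#' uniform dummy Phred quality (`I`) is written, as the simulator does not
#' model base qualities.
#'
#' @param records a [Biostrings::QualityScaledDNAStringSet] or
#'   [Biostrings::DNAStringSet].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastq <- function(records, path) {
  if (is.character(records))
    records <- DNAStringSet(records)
  if (length(records) && (is.null(names(records)) || any(!nzchar(names(records)))))
    stop("all records must have non-empty ids")
  if (!methods::is(records, "QualityScaledDNAStringSet")) {
    q <- BStringSet(vapply(
      Biostrings::width(records),
      function(w) strrep("I", w), character(1)
    ))
    records <- QualityScaledDNAStringSet(records, PhredQuality(q))
  }
  writeXStringSet(records, path, format = "fastq", qualities = quality(records))
  invisible(path)
}

# Reverse-complement of plain character sequences.
.rc <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
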