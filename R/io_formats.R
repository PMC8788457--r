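#' @useDynLib clashr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# -- small sequence helpers ---------------------------------------------------

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and replaces T with U.  N is preserved (ambiguous base).
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
as_rna <- function(x) chartr("acgutT", "ACGUUU", x)

#' Reverse complement of RNA sequences
#'
#' @param x character vector over \{A,C,G,U,N\}.
#' @return reverse complements (N maps to N).
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

.is_gz <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# -- FASTQ --------------------------------------------------------------------

#' Read a FASTQ file into a read table
#'
#' Accepts plain or gzip-compressed 4-line FASTQ with Sanger+33 quality
#' encoding (no +64 auto-detection).  Each record is validated individually:
#' a malformed record (missing '@' or '+' line, sequence/quality length
#' mismatch, quality character out of the Sanger range) raises an error
#' naming the 1-based record index.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return a `data.frame` with columns `read_id` (header up to first
#'   whitespace, without '@'), `sequence`, `qualities` (list column of
#'   integer Phred scores), `umi` (empty until extracted) and `count`
#'   (1 until collapsing).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(empty_reads())
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("FASTQ record ", bad[1], ": missing '+' separator line")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("FASTQ record ", bad[1], ": sequence and quality lengths differ (",
         nchar(seqs[bad[1]]), " vs ", nchar(qual[bad[1]]), ")")
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) stop("FASTQ record ", bad[1], ": empty sequence")
  quals <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  rng <- vapply(quals, function(q) min(q) >= 0L && max(q) <= 93L, logical(1))
  if (any(!rng))
    stop("FASTQ record ", which(!rng)[1], ": quality character outside Sanger+33 range")
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  reads <- data.frame(read_id = ids, sequence = seqs, umi = "",
                      count = 1L, stringsAsFactors = FALSE)
  reads$qualities <- quals
  reads[c("read_id", "sequence", "qualities", "umi", "count")]
}

#' An empty read table with the canonical columns
#' @return zero-row read `data.frame`.
#' @export
empty_reads <- function() {
  out <- data.frame(read_id = character(), sequence = character(),
                    umi = character(), count = integer(),
                    stringsAsFactors = FALSE)
  out$qualities <- list()
  out[c("read_id", "sequence", "qualities", "umi", "count")]
}

#' Write a read table as FASTQ (Sanger+33)
#'
#' @param reads read table as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) ==
                vapply(reads$qualities, length, integer(1))))
  qs <- vapply(reads$qualities,
               function(q) intToUtf8(q + 33L), character(1))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$read_id)
    out[seq(2L, length(out), 4L)] <- reads$sequence
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qs
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# -- FASTA --------------------------------------------------------------------

#' Read a reference FASTA into a sequence set
#'
#' Sequences are normalized to the RNA alphabet (T becomes U) and validated:
#' reference sequences must be non-empty, strictly over \{A,C,G,U\} (no N),
#' and names (headers up to the first whitespace) must be unique.
#'
#' @param path FASTA or FASTA.gz file.
#' @param role `"regulatory"` or `"target"`.
#' @return an object of class `seq_set`: a list with `role`, `seq` (named
#'   character vector) and `description` (full headers).
#' @export
read_fasta <- function(path, role = c("regulatory", "target")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  desc <- names(set)
  nm <- sub("\\s.*$", "", desc)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate FASTA name(s): ", paste(unique(dup), collapse = ", "))
  seqs <- as_rna(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for FASTA entry: ", nm[nchar(seqs) == 0L][1])
  badch <- grepl("[^ACGU]", seqs)
  if (any(badch))
    stop("reference sequence contains non-ACGU characters: ", nm[badch][1])
  names(seqs) <- nm
  names(desc) <- nm
  seq_set(seqs, role, description = desc)
}

#' Construct a sequence set from named sequences
#'
#' @param seqs named character vector of RNA sequences.
#' @param role `"regulatory"` or `"target"`.
#' @param description optional full headers (defaults to the names).
#' @return a `seq_set` object.
#' @export
seq_set <- function(seqs, role = c("regulatory", "target"),
                    description = NULL) {
  role <- match.arg(role)
  if (is.null(names(seqs)) && length(seqs))
    stop("sequence set requires named sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  seqs <- as_rna(seqs)
  if (length(seqs) && any(grepl("[^ACGU]", seqs)))
    stop("reference sequences must be over {A,C,G,U}")
  if (is.null(description)) description <- stats::setNames(names(seqs), names(seqs))
  structure(list(role = role, seq = seqs, description = description),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> role=", x$role, ", ", length(x$seq), " sequences, ",
      "lengths ", if (length(x$seq)) paste0(min(nchar(x$seq)), "-",
                                            max(nchar(x$seq))) else "-",
      " nt\n", sep = "")
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$seq)

#' Write a sequence set (or named character vector) as FASTA
#'
#' @param seqs a `seq_set` or named character vector.
#' @param path output path; `.gz` selects compression.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "seq_set")) seqs <- seqs$seq
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

# -- CSV ----------------------------------------------------------------------

#' Write a report table as RFC-4180 CSV
#'
#' Writes a header row plus one row per record; character fields are quoted,
#' so embedded commas and newlines survive a round trip through standard CSV
#' readers.  Row order is taken as given: report builders sort their tables
#' by a documented key before calling this.
#'
#' @param rows a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
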