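# Read preprocessing: 5' barcode/UMI and 3' adaptor trimming, length and
# mean-quality filtering, and collapsing to unique sequences with counts.

#' Preprocessing configuration
#'
#' @param adapter5 5' adaptor sequence removed (with mismatch tolerance)
#'   before barcode/UMI extraction; empty disables.
#' @param barcode5_pattern 5' barcode pattern over \{A,C,G,U,N\}; `N` marks a
#'   UMI position (e.g. `"NNNNNN"` for a 6-nt UMI).  Fixed bases must match
#'   exactly; a mismatch discards the read.  Empty disables.
#' @param adapter3 3' adaptor sequence; empty disables 3' trimming.
#' @param min_len,max_len retained insert length range after trimming
#'   (defaults 17 and 70 nt, the usual CLASH size selection window).
#' @param min_phred minimum mean Phred score of the trimmed read (default 30).
#' @param min_adapter_overlap minimum adaptor prefix length matched at the
#'   read 3' end (default 3).
#' @param max_trim_mismatch_rate tolerated mismatch fraction within an
#'   adaptor match (default 0.1).
#' @return a `trim_config` list.
#' @export
trim_config <- function(adapter5 = "", barcode5_pattern = "", adapter3 = "",
                        min_len = 17L, max_len = 70L, min_phred = 30,
                        min_adapter_overlap = 3L,
                        max_trim_mismatch_rate = 0.1) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len > 0L && min_len <= max_len))
    stop("invalid length range: need 0 < min_len <= max_len")
  if (min_phred < 0 || min_phred > 93)
    stop("min_phred must lie in [0, 93]")
  if (min_adapter_overlap < 1L) stop("min_adapter_overlap must be >= 1")
  barcode5_pattern <- as_rna(barcode5_pattern)
  if (nchar(barcode5_pattern) &&
      grepl("[^ACGUN]", barcode5_pattern))
    stop("barcode5_pattern must be over {A,C,G,U,N}")
  structure(list(adapter5 = as_rna(adapter5),
                 barcode5_pattern = barcode5_pattern,
                 adapter3 = as_rna(adapter3),
                 min_len = min_len, max_len = max_len,
                 min_phred = min_phred,
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_trim_mismatch_rate = max_trim_mismatch_rate),
            class = "trim_config")
}

#' Probability that a base call with Phred score q is correct
#'
#' `1 - 10^(-q/10)`: Q30 corresponds to 99.9% accuracy, Q50 to 99.999%.
#'
#' @param q non-negative Phred score(s).
#' @return probability the call is correct, in \[0, 1).
#' @export
phred_to_accuracy <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  1 - 10^(-q / 10)
}

# leftmost adaptor match position (1-based start) or NA; the match runs from
# `i` through the read 3' end (or covers the full adaptor internally)
.find_adapter3 <- function(seq_chars, ad_chars, min_overlap, max_rate) {
  L <- length(seq_chars); al <- length(ad_chars)
  if (L == 0L || al == 0L) return(NA_integer_)
  for (i in seq_len(L)) {
    w <- min(al, L - i + 1L)
    if (w < min_overlap) break
    mm <- sum(seq_chars[i:(i + w - 1L)] != ad_chars[seq_len(w)])
    if (mm <= w * max_rate + 1e-9) return(i)
  }
  NA_integer_
}

#' Trim the 3' adaptor from one read
#'
#' Removes everything from the leftmost occurrence of an adaptor prefix
#' (length at least `min_adapter_overlap`, mismatch rate at most
#' `max_trim_mismatch_rate`) that extends through the read's 3' end (or is a
#' complete internal adaptor copy).  Qualities are trimmed in lockstep.  A
#' read with no match is returned unchanged.
#'
#' @param read one-row read table (or equivalent list).
#' @param cfg a [trim_config()].
#' @return the (possibly trimmed) read.
#' @export
trim_adapter3 <- function(read, cfg) {
  if (nchar(cfg$adapter3) == 0L) return(read)
  s <- as_rna(read$sequence[[1]])
  i <- .find_adapter3(strsplit(s, "", fixed = TRUE)[[1]],
                      strsplit(cfg$adapter3, "", fixed = TRUE)[[1]],
                      cfg$min_adapter_overlap, cfg$max_trim_mismatch_rate)
  if (is.na(i)) return(read)
  read$sequence[[1]] <- substr(read$sequence[[1]], 1L, i - 1L)
  read$qualities[[1]] <- read$qualities[[1]][seq_len(i - 1L)]
  read
}

#' Trim the 5' adaptor and barcode/UMI from one read
#'
#' If `adapter5` is set and matches the read prefix (within the mismatch
#' tolerance) it is removed first.  Then `barcode5_pattern` is applied to the
#' read 5' end: bases under `N` positions are extracted as the UMI, fixed
#' bases must match exactly, and the whole pattern length is removed.  A
#' fixed-base mismatch, or a read shorter than the pattern, discards the read.
#'
#' @param read one-row read table.
#' @param cfg a [trim_config()].
#' @return a list with `read` (trimmed, `umi` populated), `keep` (logical)
#'   and `reason` (discard reason or `""`).
#' @export
trim_5prime <- function(read, cfg) {
  s <- as_rna(read$sequence[[1]])
  q <- read$qualities[[1]]
  # optional fixed 5' adaptor ahead of the barcode
  a5 <- cfg$adapter5
  if (nchar(a5) > 0L && nchar(s) >= nchar(a5)) {
    mm <- sum(strsplit(substr(s, 1L, nchar(a5)), "", fixed = TRUE)[[1]] !=
              strsplit(a5, "", fixed = TRUE)[[1]])
    if (mm <= nchar(a5) * cfg$max_trim_mismatch_rate + 1e-9) {
      s <- substring(s, nchar(a5) + 1L)
      q <- q[-seq_len(nchar(a5))]
    }
  }
  pat <- cfg$barcode5_pattern
  umi <- ""
  if (nchar(pat) > 0L) {
    pl <- nchar(pat)
    if (nchar(s) < pl) {
      return(list(read = read, keep = FALSE, reason = "shorter_than_barcode"))
    }
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    sc <- strsplit(substr(s, 1L, pl), "", fixed = TRUE)[[1]]
    fixed <- pc != "N"
    if (any(fixed & (sc != pc))) {
      return(list(read = read, keep = FALSE, reason = "barcode_mismatch"))
    }
    umi <- paste(sc[!fixed], collapse = "")
    s <- substring(s, pl + 1L)
    q <- q[-seq_len(pl)]
  }
  read$sequence[[1]] <- s
  read$qualities[[1]] <- q
  read$umi[[1]] <- umi
  list(read = read, keep = TRUE, reason = "")
}

#' Keep/drop decision for a trimmed read
#'
#' Keeps the read iff its length is within `[min_len, max_len]` and its mean
#' Phred score is at least `min_phred` (inclusive bounds).
#'
#' @param read one-row read table.
#' @param cfg a [trim_config()].
#' @return logical.
#' @export
filter_read <- function(read, cfg) {
  L <- nchar(read$sequence[[1]])
  if (L < cfg$min_len || L > cfg$max_len) return(FALSE)
  mean(read$qualities[[1]]) >= cfg$min_phred
}

#' Collapse reads to unique sequences with counts
#'
#' Reads with identical sequence (and identical UMI when `umi_aware`) are
#' merged; the representative keeps the first read's id and qualities and
#' `count` sums the merged read counts.  Output is sorted by descending
#' count, then sequence (then UMI), so collapsing is deterministic.
#'
#' @param reads read table.
#' @param umi_aware if `TRUE`, reads with the same sequence but different
#'   UMIs are kept apart (distinct molecules).
#' @return collapsed read table.
#' @export
collapse_reads <- function(reads, umi_aware = TRUE) {
  if (nrow(reads) == 0L) return(reads)
  key <- if (umi_aware) paste(reads$sequence, reads$umi, sep = "\r")
         else reads$sequence
  first <- !duplicated(key)
  counts <- tapply(reads$count, key, sum)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(counts[key[first]])
  ord <- order(-out$count, out$sequence, out$umi)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing stage
#'
#' Applies, in order: 5' adaptor/barcode/UMI trimming, 3' adaptor trimming,
#' length and mean-quality filtering, and collapsing to unique reads.  Read
#' sequences are normalized to the RNA alphabet.
#'
#' @param reads raw read table from [read_fastq()].
#' @param cfg a [trim_config()].
#' @param umi_aware collapse behaviour; default: UMI-aware iff the barcode
#'   pattern contains `N`.
#' @return list with `reads` (collapsed), `stats` (`n_input`, `n_after_trim`,
#'   `n_unique_after_trim`) and `discards` (table of per-read drop reasons).
#' @export
preprocess_run <- function(reads, cfg,
                           umi_aware = grepl("N", cfg$barcode5_pattern,
                                             fixed = TRUE)) {
  n_input <- nrow(reads)
  reasons <- character(0)
  kept <- vector("list", n_input)
  n_kept <- 0L
  for (i in seq_len(n_input)) {
    r <- reads[i, , drop = FALSE]
    r$sequence[[1]] <- as_rna(r$sequence[[1]])
    t5 <- trim_5prime(r, cfg)
    if (!t5$keep) { reasons <- c(reasons, t5$reason); next }
    r <- trim_adapter3(t5$read, cfg)
    if (!filter_read(r, cfg)) {
      L <- nchar(r$sequence[[1]])
      reasons <- c(reasons,
                   if (L < cfg$min_len) "too_short"
                   else if (L > cfg$max_len) "too_long" else "low_quality")
      next
    }
    n_kept <- n_kept + 1L
    kept[[n_kept]] <- r
  }
  trimmed <- if (n_kept) do.call(rbind, kept[seq_len(n_kept)]) else empty_reads()
  rownames(trimmed) <- NULL
  collapsed <- collapse_reads(trimmed, umi_aware = umi_aware)
  list(reads = collapsed,
       stats = list(n_input = n_input,
                    n_after_trim = sum(trimmed$count),
                    n_unique_after_trim = nrow(collapsed)),
       discards = table(factor(reasons)))
}
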