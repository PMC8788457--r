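# Chimeric-read identification under three stringencies:
#   strict     - intact regulatory RNA + perfect-match target remainder
#   scored     - alignment-based fragments, single best interpretation
#   exhaustive - alignment-based fragments, all interpretations reported
#
# All spans are 0-based half-open internally; CSV reports convert to
# 1-based inclusive.

#' Chimera-search parameters
#'
#' @param mode `"strict"`, `"scored"` or `"exhaustive"` (default; the most
#'   sensitive search, reporting every interpretation of every read).
#' @param min_fragment_len minimum length of each fragment of a chimera
#'   (default 16 nt; short enough for small-RNA fragments, long enough that
#'   chance exact matches are rare).
#' @param max_overlap maximum number of junction bases allowed to map to
#'   both fragments simultaneously (default 4).
#' @param max_gap_between maximum unassigned bases between the two fragments
#'   (default 0 in strict mode, 4 otherwise).
#' @param max_hits_per_fragment cap on reference hits kept per fragment
#'   (default 10).
#' @param seed_k k-mer seed length for the exact-match index (default 12;
#'   must not exceed `min_fragment_len`).
#' @param align_match,align_mismatch local-alignment scores (+1 / -2).
#' @param align_gap_open,align_gap_extend gap penalties (5 and 2, applied as
#'   positive costs: a gap of length L costs `open + L * extend`).
#' @return a `search_params` list.
#' @export
search_params <- function(mode = c("exhaustive", "strict", "scored"),
                          min_fragment_len = 16L, max_overlap = 4L,
                          max_gap_between = NULL,
                          max_hits_per_fragment = 10L, seed_k = 12L,
                          align_match = 1, align_mismatch = -2,
                          align_gap_open = 5, align_gap_extend = 2) {
  mode <- match.arg(mode)
  min_fragment_len <- as.integer(min_fragment_len)
  if (min_fragment_len < 8L) stop("min_fragment_len must be >= 8")
  if (max_overlap < 0L) stop("max_overlap must be >= 0")
  if (max_hits_per_fragment < 1L) stop("max_hits_per_fragment must be >= 1")
  if (is.null(max_gap_between))
    max_gap_between <- if (mode == "strict") 0L else 4L
  seed_k <- as.integer(seed_k)
  if (seed_k > min_fragment_len)
    stop("seed_k must not exceed min_fragment_len")
  structure(list(mode = mode, min_fragment_len = min_fragment_len,
                 max_overlap = as.integer(max_overlap),
                 max_gap_between = as.integer(max_gap_between),
                 max_hits_per_fragment = as.integer(max_hits_per_fragment),
                 seed_k = seed_k,
                 align_match = align_match, align_mismatch = align_mismatch,
                 align_gap_open = align_gap_open,
                 align_gap_extend = align_gap_extend),
            class = "search_params")
}

.empty_hits <- function() {
  data.frame(ref_name = character(), read_start = integer(),
             read_end = integer(), ref_start = integer(),
             ref_end = integer(), n_mismatch = integer(),
             n_indel = integer(), align_score = numeric(),
             stringsAsFactors = FALSE)
}

.empty_candidates <- function() {
  data.frame(reg_name = character(), reg_read_start = integer(),
             reg_read_end = integer(), reg_ref_start = integer(),
             reg_ref_end = integer(), reg_score = numeric(),
             tgt_name = character(), tgt_read_start = integer(),
             tgt_read_end = integer(), tgt_ref_start = integer(),
             tgt_ref_end = integer(), tgt_score = numeric(),
             n_mismatch = integer(), n_indel = integer(),
             orientation = character(), overlap_nt = integer(),
             gap_nt = integer(), combined_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Build a k-mer seed index over a reference set
#'
#' Every k-mer of every reference is recorded, so exact seed lookup is
#' complete: any exact match of length >= k contains at least one indexed
#' seed.
#'
#' @param refs a `seq_set`.
#' @param k seed length (default 12).
#' @return a `seq_index` with the seed map, the reference sequences and the
#'   role tag.
#' @export
build_index <- function(refs, k = 12L) {
  stopifnot(inherits(refs, "seq_set"))
  k <- as.integer(k)
  seqs <- refs$seq
  short <- names(seqs)[nchar(seqs) < k]
  if (length(short))
    stop("reference shorter than seed length ", k, ": ",
         paste(short, collapse = ", "))
  parts <- lapply(names(seqs), function(nm) {
    n <- nchar(seqs[[nm]])
    data.frame(kmer = substring(seqs[[nm]], 1:(n - k + 1L), k:n),
               ref = nm, pos = 0:(n - k), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  structure(list(role = refs$role, k = k,
                 map = split(all[c("ref", "pos")], all$kmer),
                 refs = seqs,
                 refchars = lapply(seqs, function(s)
                   strsplit(s, "", fixed = TRUE)[[1]])),
            class = "seq_index")
}

#' Look up a k-mer in a seed index
#'
#' @param index a `seq_index`.
#' @param kmer k-mer string.
#' @return data.frame of (`ref`, `pos`) occurrences (0-based), possibly empty.
#' @export
index_lookup <- function(index, kmer) {
  hit <- index$map[[kmer]]
  if (is.null(hit))
    return(data.frame(ref = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  hit
}

#' All maximal exact matches between a read and a reference set
#'
#' Seed-and-extend: each indexed k-mer hit is extended to its maximal exact
#' run on the read/reference diagonal; runs of length at least
#' `min_fragment_len` are reported with zero mismatches and indels.  `N`
#' never matches any base.
#'
#' @param read_seq read sequence (RNA alphabet).
#' @param index a [build_index()] result.
#' @param min_fragment_len minimum match length.
#' @return a fragment-hit `data.frame` (0-based half-open `read_start`,
#'   `read_end`, `ref_start`, `ref_end`).
#' @export
find_fragments_exact <- function(read_seq, index, min_fragment_len = 16L) {
  s <- as_rna(read_seq)
  L <- nchar(s); k <- index$k
  if (L < k) return(.empty_hits())
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  seen <- new.env(parent = emptyenv())
  rows <- list()
  kmers <- substring(s, 1:(L - k + 1L), k:L)
  for (i in seq_along(kmers)) {
    if (grepl("N", kmers[i], fixed = TRUE)) next
    occ <- index$map[[kmers[i]]]
    if (is.null(occ)) next
    for (h in seq_len(nrow(occ))) {
      ref <- occ$ref[h]
      rc <- index$refchars[[ref]]
      a <- i; b <- occ$pos[h] + 1L            # 1-based starts
      while (a > 1L && b > 1L && sc[a - 1L] != "N" &&
             sc[a - 1L] == rc[b - 1L]) { a <- a - 1L; b <- b - 1L }
      a2 <- i + k - 1L; b2 <- occ$pos[h] + k  # 1-based ends
      while (a2 < L && b2 < length(rc) && sc[a2 + 1L] != "N" &&
             sc[a2 + 1L] == rc[b2 + 1L]) { a2 <- a2 + 1L; b2 <- b2 + 1L }
      len <- a2 - a + 1L
      if (len < min_fragment_len) next
      key <- paste(ref, a, b, len, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <-
        data.frame(ref_name = ref, read_start = a - 1L, read_end = a2,
                   ref_start = b - 1L, ref_end = b2, n_mismatch = 0L,
                   n_indel = 0L, align_score = as.numeric(len),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(-out$align_score, out$ref_name, out$read_start,
                   out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# local alignment of many reads against every reference; returns a list of
# fragment-hit data.frames, one per read (already thresholded and capped)
.aligned_hits_batch <- function(read_seqs, index, params) {
  n <- length(read_seqs)
  out <- rep(list(.empty_hits()), n)
  if (n == 0L || length(index$refs) == 0L) return(out)
  letters5 <- c("A", "C", "G", "T", "N")
  submat <- matrix(params$align_mismatch, 5L, 5L,
                   dimnames = list(letters5, letters5))
  diag(submat) <- params$align_match
  submat["N", ] <- params$align_mismatch   # N never matches, even N vs N
  submat[, "N"] <- params$align_mismatch
  pat <- Biostrings::DNAStringSet(chartr("U", "T", read_seqs))
  min_score <- params$min_fragment_len * params$align_match * 0.8
  per_ref <- list()
  for (nm in names(index$refs)) {
    subj <- Biostrings::DNAString(chartr("U", "T", index$refs[[nm]]))
    al <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = params$align_gap_open,
                                        gapExtension = params$align_gap_extend)
    sc <- Biostrings::score(al)
    p <- Biostrings::pattern(al); su <- Biostrings::subject(al)
    ind <- Biostrings::nindel(al)
    hits <- data.frame(read = seq_len(n), ref_name = nm,
                       read_start = Biostrings::start(p) - 1L,
                       read_end = Biostrings::end(p),
                       ref_start = Biostrings::start(su) - 1L,
                       ref_end = Biostrings::end(su),
                       n_mismatch = Biostrings::nmismatch(al),
                       n_indel = ind@insertion[, "WidthSum"] +
                                 ind@deletion[, "WidthSum"],
                       align_score = sc, stringsAsFactors = FALSE)
    keep <- sc > min_score &
      (hits$read_end - hits$read_start) >= params$min_fragment_len
    per_ref[[nm]] <- hits[keep, , drop = FALSE]
  }
  all <- do.call(rbind, per_ref)
  if (is.null(all) || nrow(all) == 0L) return(out)
  rownames(all) <- NULL
  for (i in unique(all$read)) {
    h <- all[all$read == i, , drop = FALSE]
    h <- h[order(-h$align_score, h$ref_name, h$read_start), , drop = FALSE]
    h <- utils::head(h, params$max_hits_per_fragment)
    h$read <- NULL
    rownames(h) <- NULL
    out[[i]] <- h
  }
  out
}

#' Local-alignment fragment hits for one read
#'
#' Each reference is aligned locally to the read (match +1, mismatch -2,
#' affine gaps), tolerating short insertions and deletions.  Hits scoring
#' above `0.8 * min_fragment_len * align_match` and spanning at least
#' `min_fragment_len` read bases are kept, at most `max_hits_per_fragment`
#' of them, by descending score.
#'
#' @param read_seq read sequence.
#' @param index a [build_index()] result.
#' @param params a [search_params()].
#' @return a fragment-hit `data.frame`.
#' @export
find_fragments_aligned <- function(read_seq, index, params = search_params()) {
  .aligned_hits_batch(as_rna(read_seq), index, params)[[1]]
}

#' Pair regulatory and target fragment hits of one read into chimera
#' candidates
#'
#' Every (regulatory, target) hit combination, in either order along the
#' read, is kept when the two read spans overlap by at most `max_overlap`
#' bases and are separated by at most `max_gap_between` bases.
#' `combined_score` is the sum of the two alignment scores minus the overlap.
#'
#' @param reg_hits,tgt_hits fragment hits of one read.
#' @param params a [search_params()].
#' @return a candidate `data.frame`.
#' @export
pair_fragments <- function(reg_hits, tgt_hits, params = search_params()) {
  if (nrow(reg_hits) == 0L || nrow(tgt_hits) == 0L)
    return(.empty_candidates())
  g <- expand.grid(r = seq_len(nrow(reg_hits)), t = seq_len(nrow(tgt_hits)))
  rs <- reg_hits$read_start[g$r]; re <- reg_hits$read_end[g$r]
  ts <- tgt_hits$read_start[g$t]; te <- tgt_hits$read_end[g$t]
  ov <- pmax(0L, pmin(re, te) - pmax(rs, ts))
  gap <- pmax(0L, pmax(rs, ts) - pmin(re, te))
  ok <- ov <= params$max_overlap & gap <= params$max_gap_between
  if (!any(ok)) return(.empty_candidates())
  g <- g[ok, , drop = FALSE]
  rs <- rs[ok]; re <- re[ok]; ts <- ts[ok]; te <- te[ok]
  data.frame(
    reg_name = reg_hits$ref_name[g$r],
    reg_read_start = rs, reg_read_end = re,
    reg_ref_start = reg_hits$ref_start[g$r],
    reg_ref_end = reg_hits$ref_end[g$r],
    reg_score = reg_hits$align_score[g$r],
    tgt_name = tgt_hits$ref_name[g$t],
    tgt_read_start = ts, tgt_read_end = te,
    tgt_ref_start = tgt_hits$ref_start[g$t],
    tgt_ref_end = tgt_hits$ref_end[g$t],
    tgt_score = tgt_hits$align_score[g$t],
    n_mismatch = reg_hits$n_mismatch[g$r] + tgt_hits$n_mismatch[g$t],
    n_indel = reg_hits$n_indel[g$r] + tgt_hits$n_indel[g$t],
    orientation = ifelse(rs < ts | (rs == ts & re <= te),
                         "reg_first", "target_first"),
    overlap_nt = ov[ok], gap_nt = gap[ok],
    combined_score = reg_hits$align_score[g$r] +
      tgt_hits$align_score[g$t] - ov[ok],
    stringsAsFactors = FALSE)
}

.sort_candidates <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  ord <- order(-cands$combined_score, cands$reg_name, cands$tgt_name,
               cands$orientation, cands$reg_read_start, cands$tgt_read_start,
               cands$tgt_ref_start)
  out <- cands[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.dedup_candidates <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  key <- paste(cands$reg_name, cands$reg_read_start, cands$reg_read_end,
               cands$reg_ref_start, cands$reg_ref_end,
               cands$tgt_name, cands$tgt_read_start, cands$tgt_read_end,
               cands$tgt_ref_start, cands$tgt_ref_end,
               cands$orientation, sep = ":")
  out <- cands[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strict chimera search (intact regulatory RNA, perfect target match)
#'
#' Requires a full-length, mismatch-free copy of a regulatory reference at
#' the read's 5' or 3' end; the entire remaining sequence must match a
#' target reference exactly.  No insertions between the fragments and no
#' junction overlap are tolerated.  All qualifying interpretations are
#' returned (capped per fragment at `max_hits_per_fragment`).
#'
#' @param read_seq read sequence.
#' @param reg_index,tgt_index [build_index()] results for the regulatory and
#'   target sets.
#' @param params a [search_params()].
#' @return a candidate `data.frame`.
#' @export
search_strict <- function(read_seq, reg_index, tgt_index,
                          params = search_params(mode = "strict")) {
  s <- as_rna(read_seq); L <- nchar(s)
  rows <- list()
  for (rn in sort(names(reg_index$refs))) {
    rseq <- reg_index$refs[[rn]]; rl <- nchar(rseq)
    if (rl >= L) next
    occ <- gregexpr(rseq, s, fixed = TRUE)[[1]]
    if (occ[1] == -1L) next
    for (p in as.integer(occ)) {
      ends <- list()
      if (p == 1L)            # regulatory at 5' end, target is the rest
        ends[[length(ends) + 1L]] <-
          list(start = rl, end = L, orient = "reg_first")
      if (p + rl - 1L == L)   # regulatory at 3' end
        ends[[length(ends) + 1L]] <-
          list(start = 0L, end = p - 1L, orient = "target_first")
      for (e in ends) {
        rem <- substr(s, e$start + 1L, e$end)
        tl <- nchar(rem)
        if (tl < params$min_fragment_len) next
        if (grepl("N", rem, fixed = TRUE)) next
        n_hit <- 0L
        for (tn in sort(names(tgt_index$refs))) {
          tocc <- gregexpr(rem, tgt_index$refs[[tn]], fixed = TRUE)[[1]]
          if (tocc[1] == -1L) next
          for (tp in as.integer(tocc)) {
            if (n_hit >= params$max_hits_per_fragment) break
            n_hit <- n_hit + 1L
            rows[[length(rows) + 1L]] <- data.frame(
              reg_name = rn, reg_read_start = p - 1L,
              reg_read_end = p - 1L + rl,
              reg_ref_start = 0L, reg_ref_end = rl,
              reg_score = as.numeric(rl),
              tgt_name = tn, tgt_read_start = e$start,
              tgt_read_end = e$end,
              tgt_ref_start = tp - 1L, tgt_ref_end = tp - 1L + tl,
              tgt_score = as.numeric(tl),
              n_mismatch = 0L, n_indel = 0L,
              orientation = e$orient, overlap_nt = 0L, gap_nt = 0L,
              combined_score = as.numeric(rl + tl),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) return(.empty_candidates())
  .sort_candidates(.dedup_candidates(do.call(rbind, rows)))
}

# full exhaustive candidate pool for one read: alignment-derived pairs,
# exact maximal-match pairs, and the strict interpretations (so the
# stricter modes' results are contained by construction)
.exhaustive_pool <- function(read_seq, reg_index, tgt_index, params,
                             reg_aligned = NULL, tgt_aligned = NULL) {
  s <- as_rna(read_seq)
  reg_ex <- find_fragments_exact(s, reg_index, params$min_fragment_len)
  tgt_ex <- find_fragments_exact(s, tgt_index, params$min_fragment_len)
  if (is.null(reg_aligned))
    reg_aligned <- find_fragments_aligned(s, reg_index, params)
  if (is.null(tgt_aligned))
    tgt_aligned <- find_fragments_aligned(s, tgt_index, params)
  dedup_hits <- function(a, b) {
    h <- rbind(a, b)
    key <- paste(h$ref_name, h$read_start, h$read_end,
                 h$ref_start, h$ref_end, sep = ":")
    h[!duplicated(key), , drop = FALSE]
  }
  reg_hits <- utils::head(dedup_hits(reg_aligned, reg_ex),
                          2L * params$max_hits_per_fragment)
  tgt_hits <- utils::head(dedup_hits(tgt_aligned, tgt_ex),
                          2L * params$max_hits_per_fragment)
  pool <- rbind(pair_fragments(reg_hits, tgt_hits, params),
                search_strict(s, reg_index, tgt_index, params))
  .sort_candidates(.dedup_candidates(pool))
}

#' Exhaustive chimera search (all interpretations)
#'
#' The most sensitive mode: candidates are built from alignment-derived and
#' exact fragment hits on both sides, plus every strict-mode interpretation,
#' and all of them are reported, sorted by descending combined score.  A
#' single read may therefore support several RNA-RNA interactions.
#'
#' @inheritParams search_strict
#' @return a candidate `data.frame`.
#' @export
search_exhaustive <- function(read_seq, reg_index, tgt_index,
                              params = search_params(mode = "exhaustive")) {
  .exhaustive_pool(read_seq, reg_index, tgt_index, params)
}

#' Scored chimera search (single best interpretation)
#'
#' Builds the same candidate pool as the exhaustive mode but keeps only the
#' interpretation with the highest combined score; ties are broken by
#' lexicographic (regulatory name, target name), then orientation and spans,
#' so the result is deterministic.
#'
#' @inheritParams search_strict
#' @return a candidate `data.frame` with at most one row.
#' @export
search_scored <- function(read_seq, reg_index, tgt_index,
                          params = search_params(mode = "scored")) {
  pool <- .exhaustive_pool(read_seq, reg_index, tgt_index, params)
  utils::head(pool, 1L)   # pool is sorted by score with deterministic ties
}

#' Run the chimera search over a collapsed read table
#'
#' Builds the two seed indexes and dispatches each read to the configured
#' search mode, returning one table of all candidates with read ids and
#' collapsed read counts attached.
#'
#' @param reads collapsed read table (from [preprocess_run()]).
#' @param reg_set,tgt_set regulatory and target `seq_set`s.
#' @param params a [search_params()].
#' @return list with `candidates` (data.frame; one row per interpretation)
#'   and `n_chimeric` (total read count of reads with >= 1 interpretation).
#' @export
search_reads <- function(reads, reg_set, tgt_set,
                         params = search_params()) {
  reg_index <- build_index(reg_set, params$seed_k)
  tgt_index <- build_index(tgt_set, params$seed_k)
  n <- nrow(reads)
  if (n == 0L) {
    empty <- cbind(data.frame(read_id = character(), count = integer(),
                              stringsAsFactors = FALSE), .empty_candidates())
    return(list(candidates = empty, n_chimeric = 0L))
  }
  seqs <- as_rna(reads$sequence)
  if (params$mode %in% c("scored", "exhaustive")) {
    reg_al <- .aligned_hits_batch(seqs, reg_index, params)
    tgt_al <- .aligned_hits_batch(seqs, tgt_index, params)
  }
  out <- vector("list", n)
  chimeric_count <- 0L
  for (i in seq_len(n)) {
    cand <- switch(params$mode,
      strict = search_strict(seqs[i], reg_index, tgt_index, params),
      scored = utils::head(.exhaustive_pool(seqs[i], reg_index, tgt_index,
                                            params, reg_al[[i]],
                                            tgt_al[[i]]), 1L),
      exhaustive = .exhaustive_pool(seqs[i], reg_index, tgt_index, params,
                                    reg_al[[i]], tgt_al[[i]]))
    if (nrow(cand)) {
      chimeric_count <- chimeric_count + reads$count[i]
      out[[i]] <- cbind(data.frame(read_id = reads$read_id[i],
                                   count = reads$count[i],
                                   stringsAsFactors = FALSE), cand)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  cands <- if (length(out)) do.call(rbind, out)
           else cbind(data.frame(read_id = character(), count = integer(),
                                 stringsAsFactors = FALSE),
                      .empty_candidates())
  rownames(cands) <- NULL
  list(candidates = cands, n_chimeric = chimeric_count)
}
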