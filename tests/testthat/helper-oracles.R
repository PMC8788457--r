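# Independent oracles and small fixture builders used across the suite.

# one-row read table
make_read <- function(seq, qual = rep(40L, nchar(seq)), id = "r1",
                      umi = "") {
  r <- data.frame(read_id = id, sequence = seq, umi = umi, count = 1L,
                  stringsAsFactors = FALSE)
  r$qualities <- list(as.integer(qual))
  r[c("read_id", "sequence", "qualities", "umi", "count")]
}

bind_reads <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

rand_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                       replace = TRUE), collapse = "")

# brute-force maximal exact matches by diagonal scanning: for every
# (reference, diagonal), maximal runs of equal non-N characters of length
# >= min_len.  Independent of the seed-and-extend implementation.
oracle_exact_matches <- function(read, refs, min_len) {
  rc <- strsplit(as_rna(read), "")[[1]]
  L <- length(rc)
  rows <- list()
  for (nm in names(refs$seq)) {
    fc <- strsplit(refs$seq[[nm]], "")[[1]]
    M <- length(fc)
    for (d in (-(M - 1L)):(L - 1L)) {     # read_pos = ref_pos + d
      lo <- max(1L, 1L - d); hi <- min(M, L - d)
      if (hi - lo + 1L < min_len) next
      run <- 0L
      for (p in lo:hi) {
        ok <- fc[p] != "N" && rc[p + d] != "N" && fc[p] == rc[p + d]
        if (ok) run <- run + 1L
        if ((!ok || p == hi) && run >= min_len) {
          ep <- if (ok) p else p - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            ref_name = nm,
            read_start = ep + d - run,       # 0-based half-open
            read_end = ep + d,
            ref_start = ep - run, ref_end = ep,
            stringsAsFactors = FALSE)
        }
        if (!ok) run <- 0L
      }
    }
  }
  if (!length(rows))
    return(data.frame(ref_name = character(), read_start = integer(),
                      read_end = integer(), ref_start = integer(),
                      ref_end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$ref_name, out$read_start, out$ref_start), , drop = FALSE]
}

# canonical form of a fragment-hit table for comparison with the oracle
canon_hits <- function(h) {
  h <- h[c("ref_name", "read_start", "read_end", "ref_start", "ref_end")]
  h <- h[order(h$ref_name, h$read_start, h$ref_start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# exhaustive enumeration oracle for the intermolecular duplex DP: every
# antiparallel pairing of short sequences, scored by its own arithmetic
# from the same parameter table.
.ORACLE_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

oracle_set_energy <- function(ac, bc, ps, model) {
  pt <- function(t) match(paste0(ac[ps[t, 1]], bc[ps[t, 2]]), .ORACLE_PAIRS)
  weak <- function(p) p %in% c(1L, 2L, 5L, 6L)
  k <- nrow(ps)
  e <- model$init + model$terminal_au * (weak(pt(1)) + weak(pt(k)))
  if (k >= 2L) for (t in 2:k) {
    da <- ps[t, 1] - ps[t - 1, 1] - 1L
    db <- ps[t - 1, 2] - ps[t, 2] - 1L
    e <- e + if (da == 0L && db == 0L)
      model$stack[pt(t - 1), pt(t)]
    else if (da == 0L || db == 0L)
      model$bulge_open + model$bulge_ext * (da + db)
    else model$internal_open + model$internal_ext * (da + db)
  }
  e
}

oracle_duplex_min <- function(a, b, model = energy_model()) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  can <- function(i, j) paste0(ac[i], bc[j]) %in% .ORACLE_PAIRS
  best <- Inf
  recurse <- function(i_min, j_max, cur) {
    if (nrow(cur) > 0L) {
      e <- oracle_set_energy(ac, bc, cur, model)
      if (e < best) best <<- e
    }
    if (i_min > n || j_max < 1L) return(invisible())
    for (i in i_min:n) for (j in seq_len(j_max))
      if (can(i, j))
        recurse(i + 1L, j - 1L, rbind(cur, c(i, j)))
    invisible()
  }
  recurse(1L, m, matrix(integer(), 0L, 2L))
  best
}

# a tiny deterministic synthetic run shared by several tests
small_library <- function(seed = 1L, n_chimeric = 30L, n_background = 10L,
                          ...) {
  cfg <- synth_config(seed = seed, n_chimeric_reads = n_chimeric,
                      n_background_reads = n_background, error_rate = 0,
                      ...)
  refs <- generate_references(cfg)
  lib <- generate_library(refs, cfg)
  list(cfg = cfg, refs = refs, lib = lib)
}

preprocess_library <- function(x) {
  tc <- trim_config(barcode5_pattern = x$cfg$barcode5_pattern,
                    adapter3 = x$cfg$adapter3)
  preprocess_run(x$lib$reads, tc)
}
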