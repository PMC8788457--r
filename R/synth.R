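# Synthetic CLASH library generation with a ground-truth manifest.
# The generator emulates the library structure of a CLASH experiment:
# a chimeric insert (regulatory fragment ligated to a target fragment, in
# either order) flanked by a 5' barcode/UMI and a 3' adaptor, mixed with
# non-chimeric background reads, with optional substitution errors.

.BASES <- c("A", "C", "G", "U")

.rand_seq <- function(len) paste(sample(.BASES, len, replace = TRUE),
                                 collapse = "")

.set_seed <- function(seed) {
  # fixed RNG algorithm so libraries are reproducible across R versions
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Synthetic library configuration
#'
#' Defaults describe a small but realistic single-guide CLASH experiment:
#' miRNA-sized regulatory RNAs (19-31 nt), mRNA-sized targets
#' (200-1500 nt), each target carrying one perfectly complementary planted
#' site, a 6-nt UMI barcode, a standard 3' sequencing adaptor, and a low
#' Illumina-like substitution error rate.
#'
#' @param seed RNG seed; the same seed reproduces the library byte for byte.
#' @param n_regulatory,n_target reference set sizes.  With the defaults
#'   (20 and 20) each target is paired with a distinct regulatory RNA, so
#'   every planted site is a unique fragment; setting `n_target` above
#'   `n_regulatory` recycles partners and deliberately creates
#'   multi-mapping sites.
#' @param reg_len,tgt_len length ranges (2-vectors, inclusive).
#' @param n_chimeric_reads chimeric reads planted at complementary sites.
#' @param n_decoy_reads random-ligation chimeras: a regulatory RNA joined to
#'   a target fragment taken at a random (non-complementary) position.
#' @param n_background_reads non-chimeric reads, half single-reference
#'   fragments and half uniform random sequence.
#' @param frac_target_first fraction of chimeras with the target fragment 5'
#'   of the regulatory fragment (default 0.3).
#' @param complementary_site plant each target with the reverse complement
#'   of its partner regulatory RNA (default `TRUE`).
#' @param mismatches_in_site substitutions introduced into each planted site
#'   (default 0).
#' @param adapter5,adapter3,barcode5_pattern read flanks, as in
#'   [trim_config()].
#' @param error_rate per-base substitution probability (default 0.005).
#' @param decoy_multimap copy a shared 20-mer into two targets, creating
#'   multi-mapping fragments (default `FALSE`).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_regulatory = 20L, n_target = 20L,
                         reg_len = c(19L, 31L), tgt_len = c(200L, 1500L),
                         n_chimeric_reads = 200L, n_decoy_reads = 0L,
                         n_background_reads = 100L,
                         frac_target_first = 0.3,
                         complementary_site = TRUE,
                         mismatches_in_site = 0L,
                         adapter5 = "", adapter3 = "AGAUCGGAAGAGC",
                         barcode5_pattern = "NNNNNN",
                         error_rate = 0.005, decoy_multimap = FALSE) {
  stopifnot(frac_target_first >= 0, frac_target_first <= 1,
            error_rate >= 0, error_rate <= 1,
            n_regulatory >= 0, n_target >= 0, n_chimeric_reads >= 0,
            n_decoy_reads >= 0, n_background_reads >= 0,
            length(reg_len) == 2L, length(tgt_len) == 2L,
            reg_len[1] <= reg_len[2], tgt_len[1] <= tgt_len[2])
  structure(list(seed = as.integer(seed),
                 n_regulatory = as.integer(n_regulatory),
                 n_target = as.integer(n_target),
                 reg_len = as.integer(reg_len), tgt_len = as.integer(tgt_len),
                 n_chimeric_reads = as.integer(n_chimeric_reads),
                 n_decoy_reads = as.integer(n_decoy_reads),
                 n_background_reads = as.integer(n_background_reads),
                 frac_target_first = frac_target_first,
                 complementary_site = complementary_site,
                 mismatches_in_site = as.integer(mismatches_in_site),
                 adapter5 = as_rna(adapter5), adapter3 = as_rna(adapter3),
                 barcode5_pattern = as_rna(barcode5_pattern),
                 error_rate = error_rate, decoy_multimap = decoy_multimap),
            class = "synth_config")
}

#' Generate synthetic regulatory and target reference sets
#'
#' Random sequences in the configured length ranges.  When
#' `complementary_site` is on, each target carries one embedded reverse
#' complement of its partner regulatory RNA (partners cycle through the
#' regulatory set), with `mismatches_in_site` substitutions; the planted
#' site coordinates are recorded.  When `decoy_multimap` is on, one random
#' 20-mer is copied into two targets (outside any planted site).
#'
#' @param cfg a [synth_config()].
#' @return list: `reg` and `tgt` (`seq_set`s) and `sites` (data.frame of
#'   planted complementary sites, 1-based inclusive target coordinates).
#' @export
generate_references <- function(cfg) {
  .set_seed(cfg$seed)
  reg_names <- sprintf("reg_%03d", seq_len(cfg$n_regulatory))
  regs <- vapply(seq_len(cfg$n_regulatory), function(i)
    .rand_seq(sample(cfg$reg_len[1]:cfg$reg_len[2], 1L)), character(1))
  names(regs) <- reg_names
  tgt_names <- sprintf("tgt_%03d", seq_len(cfg$n_target))
  tgts <- vapply(seq_len(cfg$n_target), function(i)
    .rand_seq(sample(cfg$tgt_len[1]:cfg$tgt_len[2], 1L)), character(1))
  names(tgts) <- tgt_names
  sites <- data.frame(tgt_name = character(), reg_name = character(),
                      start_1based = integer(), end_1based = integer(),
                      stringsAsFactors = FALSE)
  if (cfg$complementary_site && cfg$n_target > 0L && cfg$n_regulatory > 0L) {
    rows <- vector("list", cfg$n_target)
    for (i in seq_len(cfg$n_target)) {
      rn <- reg_names[((i - 1L) %% cfg$n_regulatory) + 1L]
      site <- revcomp_rna(regs[[rn]])
      if (cfg$mismatches_in_site > 0L) {
        sc <- strsplit(site, "")[[1]]
        at <- sample(length(sc), min(cfg$mismatches_in_site, length(sc)))
        for (p in at) sc[p] <- sample(setdiff(.BASES, sc[p]), 1L)
        site <- paste(sc, collapse = "")
      }
      sl <- nchar(site); tl <- nchar(tgts[[i]])
      pos <- sample(tl - sl + 1L, 1L)
      substr(tgts[[i]], pos, pos + sl - 1L) <- site
      rows[[i]] <- data.frame(tgt_name = tgt_names[i], reg_name = rn,
                              start_1based = pos, end_1based = pos + sl - 1L,
                              stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
  }
  if (cfg$decoy_multimap && cfg$n_target >= 2L) {
    shared <- .rand_seq(20L)
    picks <- sample(cfg$n_target, 2L)
    for (i in picks) {
      tl <- nchar(tgts[[i]])
      forbid <- sites[sites$tgt_name == tgt_names[i], , drop = FALSE]
      repeat {
        pos <- sample(tl - 19L, 1L)
        clear <- !nrow(forbid) ||
          all(pos + 19L < forbid$start_1based | pos > forbid$end_1based)
        if (clear) break
      }
      substr(tgts[[i]], pos, pos + 19L) <- shared
    }
  }
  list(reg = seq_set(regs, "regulatory"),
       tgt = seq_set(tgts, "target"),
       sites = sites)
}

# realize a barcode pattern with given UMI bases; returns the emitted prefix
.realize_barcode <- function(pattern, umi) {
  if (nchar(pattern) == 0L) return("")
  pc <- strsplit(pattern, "")[[1]]
  pc[pc == "N"] <- strsplit(umi, "")[[1]]
  paste(pc, collapse = "")
}

#' Generate a synthetic CLASH read library with ground truth
#'
#' Each chimeric read is `adapter5 + barcode/UMI + insert + adapter3`, where
#' the insert joins the full regulatory sequence to a target fragment (at
#' the planted complementary site for true chimeras; at a random position
#' for decoys), in either order per `frac_target_first`.  Background reads
#' carry single-reference fragments or uniform random inserts.  Per-base
#' substitution errors are applied at `error_rate`; qualities are Q40 with
#' errored bases at Q20.  UMIs are drawn without replacement, so every
#' sequenced molecule is distinguishable.  Reads are emitted as DNA (U
#' written as T), as a sequencer would.
#'
#' @param refs a [generate_references()] result.
#' @param cfg the same [synth_config()].
#' @return list: `reads` (read table, writable with [write_fastq()]) and
#'   `manifest` (one row per planted chimeric read: names, 1-based fragment
#'   spans on the references, orientation, RNA insert sequence, UMI, and
#'   `site_type` `"complementary"` or `"decoy"`).
#' @export
generate_library <- function(refs, cfg) {
  .set_seed(bitwXor(cfg$seed, 7919L))
  n_umi <- sum(strsplit(cfg$barcode5_pattern, "")[[1]] == "N")
  n_total <- cfg$n_chimeric_reads + cfg$n_decoy_reads +
    cfg$n_background_reads
  umis <- if (n_umi > 0L) {
    space <- do.call(paste0, expand.grid(rep(list(.BASES), n_umi),
                                         stringsAsFactors = FALSE))
    if (n_total > length(space))
      stop("more reads than distinct UMIs; lengthen the barcode pattern")
    sample(space, n_total)
  } else rep("", n_total)
  regs <- refs$reg$seq; tgts <- refs$tgt$seq
  manifest <- vector("list", cfg$n_chimeric_reads + cfg$n_decoy_reads)
  inserts <- character(n_total)
  ids <- character(n_total)
  idx <- 0L
  make_chimera <- function(id, reg_name, tgt_name, t_start, t_end, type) {
    reg_frag <- regs[[reg_name]]
    tgt_frag <- substr(tgts[[tgt_name]], t_start, t_end)
    target_first <- stats::runif(1) < cfg$frac_target_first
    ins <- if (target_first) paste0(tgt_frag, reg_frag)
           else paste0(reg_frag, tgt_frag)
    list(manifest = data.frame(
           read_id = id, reg_name = reg_name,
           reg_start_1based = 1L, reg_end_1based = nchar(reg_frag),
           tgt_name = tgt_name, tgt_start_1based = t_start,
           tgt_end_1based = t_end,
           orientation = if (target_first) "target_first" else "reg_first",
           insert_seq = ins, umi = "", site_type = type,
           stringsAsFactors = FALSE),
         insert = ins)
  }
  for (i in seq_len(cfg$n_chimeric_reads)) {
    idx <- idx + 1L
    if (nrow(refs$sites) == 0L)
      stop("chimeric reads require planted sites (complementary_site = TRUE)")
    s <- refs$sites[sample(nrow(refs$sites), 1L), ]
    ch <- make_chimera(sprintf("chim_%05d", i), s$reg_name, s$tgt_name,
                       s$start_1based, s$end_1based, "complementary")
    manifest[[idx]] <- ch$manifest
    inserts[idx] <- ch$insert
    ids[idx] <- ch$manifest$read_id
  }
  for (i in seq_len(cfg$n_decoy_reads)) {
    idx <- idx + 1L
    rn <- names(regs)[sample(length(regs), 1L)]
    tn <- names(tgts)[sample(length(tgts), 1L)]
    flen <- sample(cfg$reg_len[1]:cfg$reg_len[2], 1L)
    pos <- sample(nchar(tgts[[tn]]) - flen + 1L, 1L)
    ch <- make_chimera(sprintf("decoy_%05d", i), rn, tn,
                       pos, pos + flen - 1L, "decoy")
    manifest[[idx]] <- ch$manifest
    inserts[idx] <- ch$insert
    ids[idx] <- ch$manifest$read_id
  }
  all_refs <- c(regs, tgts)
  for (i in seq_len(cfg$n_background_reads)) {
    idx <- idx + 1L
    ids[idx] <- sprintf("bg_%05d", i)
    len <- sample(20L:40L, 1L)
    if (i %% 2L == 0L && length(all_refs)) {   # single-reference fragment
      rn <- names(all_refs)[sample(length(all_refs), 1L)]
      rs <- all_refs[[rn]]
      len <- min(len, nchar(rs))
      pos <- sample(nchar(rs) - len + 1L, 1L)
      inserts[idx] <- substr(rs, pos, pos + len - 1L)
    } else {                                   # uniform random insert
      inserts[idx] <- .rand_seq(len)
    }
  }
  manifest <- if (cfg$n_chimeric_reads + cfg$n_decoy_reads > 0L)
    do.call(rbind, manifest)
  else data.frame(read_id = character(), reg_name = character(),
                  reg_start_1based = integer(), reg_end_1based = integer(),
                  tgt_name = character(), tgt_start_1based = integer(),
                  tgt_end_1based = integer(), orientation = character(),
                  insert_seq = character(), umi = character(),
                  site_type = character(), stringsAsFactors = FALSE)
  if (nrow(manifest)) manifest$umi <- umis[seq_len(nrow(manifest))]
  # assemble reads: adapter5 + realized barcode + insert + adapter3
  seqs <- character(n_total); quals <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    pre <- paste0(cfg$adapter5, .realize_barcode(cfg$barcode5_pattern,
                                                 umis[i]))
    full <- paste0(pre, inserts[i], cfg$adapter3)
    q <- rep(40L, nchar(full))
    if (cfg$error_rate > 0) {
      fc <- strsplit(full, "")[[1]]
      err <- which(stats::runif(length(fc)) < cfg$error_rate)
      for (p in err) fc[p] <- sample(setdiff(.BASES, fc[p]), 1L)
      q[err] <- 20L
      full <- paste(fc, collapse = "")
    }
    seqs[i] <- chartr("U", "T", full)   # emit DNA as a sequencer would
    quals[[i]] <- q
  }
  reads <- data.frame(read_id = ids, sequence = seqs, umi = "",
                      count = 1L, stringsAsFactors = FALSE)
  reads$qualities <- quals
  reads <- reads[c("read_id", "sequence", "qualities", "umi", "count")]
  # shuffle so read types are interleaved, deterministically under the seed
  perm <- sample(n_total)
  reads <- reads[perm, , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, manifest = manifest)
}

#' Write a synthetic library to disk
#'
#' @param refs a [generate_references()] result.
#' @param lib a [generate_library()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.  Writes `reads.fastq`, `regulatory.fa`,
#'   `targets.fa` and `truth.tsv`.
#' @export
write_library <- function(refs, lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(lib$reads, file.path(dir, "reads.fastq"))
  write_fasta(refs$reg, file.path(dir, "regulatory.fa"))
  write_fasta(refs$tgt, file.path(dir, "targets.fa"))
  utils::write.table(lib$manifest, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Score pipeline output against the ground-truth manifest
#'
#' A candidate interpretation is a true positive iff its (regulatory name,
#' target name, orientation) matches the manifest row for that read id;
#' span-exact recovery additionally requires both reference fragment spans
#' to match the planted spans.
#'
#' @param candidates candidate table from [search_reads()].
#' @param manifest manifest from [generate_library()].
#' @return list: `precision` (fraction of candidate interpretations that
#'   are true positives), `recall` (fraction of planted chimeras recovered),
#'   `span_exact` (fraction recovered with exact fragment spans), and the
#'   underlying counts.
#' @export
evaluate_recovery <- function(candidates, manifest) {
  n_cand <- nrow(candidates)
  n_truth <- nrow(manifest)
  if (n_truth == 0L)
    return(list(precision = NA_real_, recall = NA_real_,
                span_exact = NA_real_, n_candidates = n_cand,
                n_truth = 0L, n_true_positive = 0L))
  mkey <- paste(manifest$read_id, manifest$reg_name, manifest$tgt_name,
                manifest$orientation, sep = "\r")
  skey <- paste(mkey, manifest$reg_start_1based, manifest$reg_end_1based,
                manifest$tgt_start_1based, manifest$tgt_end_1based,
                sep = "\r")
  ckey <- paste(candidates$read_id, candidates$reg_name,
                candidates$tgt_name, candidates$orientation, sep = "\r")
  cskey <- paste(ckey, candidates$reg_ref_start + 1L,
                 candidates$reg_ref_end, candidates$tgt_ref_start + 1L,
                 candidates$tgt_ref_end, sep = "\r")
  tp <- ckey %in% mkey
  list(precision = if (n_cand) mean(tp) else NA_real_,
       recall = mean(mkey %in% ckey),
       span_exact = mean(skey %in% cskey),
       n_candidates = n_cand, n_truth = n_truth,
       n_true_positive = sum(tp))
}
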