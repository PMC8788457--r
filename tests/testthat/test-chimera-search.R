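refs_small <- function() {
  seq_set(c(r1 = "ACGUACGU"), "regulatory")
}

test_that("the k-mer index is complete and lookups are exact", {
  idx <- build_index(refs_small(), k = 4)
  hit <- index_lookup(idx, "ACGU")
  expect_equal(sort(hit$pos), c(0L, 4L))
  expect_equal(nrow(index_lookup(idx, "AAAA")), 0L)
  two <- seq_set(c(a = "AAACGUACGUAA", b = "GGACGUACGUGG"), "target")
  idx2 <- build_index(two, k = 10)
  expect_setequal(index_lookup(idx2, "ACGUACGUAA")$ref, c("a"))
  expect_setequal(index_lookup(idx2, "AACGUACGUA")$ref, c("a"))
  expect_setequal(index_lookup(idx2, "GGACGUACGU")$ref, c("b"))
  expect_error(build_index(seq_set(c(s = "ACG"), "target"), k = 4),
               "shorter than seed")
})

test_that("exact fragment search finds maximal matches and misses short ones", {
  set.seed(5)
  ref <- rand_rna(21)
  refs <- seq_set(c(m = ref), "regulatory")
  idx <- build_index(refs, 12)
  h <- find_fragments_exact(ref, idx, 16)
  expect_equal(nrow(h), 1L)
  expect_equal(h$read_start, 0L)
  expect_equal(h$read_end, 21L)
  expect_equal(h$ref_start, 0L)
  expect_equal(h$n_mismatch, 0L)
  expect_equal(h$align_score, 21)

  # a 10-nt shared substring is below min_fragment_len
  h <- find_fragments_exact(paste0(substr(ref, 1, 10), rand_rna(30)),
                            idx, 16)
  expect_equal(nrow(h), 0L)

  # two disjoint planted copies give two hits
  read <- paste0(ref, "AAAAAAA", ref)
  h <- find_fragments_exact(read, idx, 16)
  expect_equal(nrow(h), 2L)
})

test_that("exact search agrees with the brute-force diagonal oracle", {
  set.seed(42)
  for (trial in 1:120) {
    n_ref <- sample(1:6, 1)
    refs <- seq_set(stats::setNames(
      vapply(seq_len(n_ref), function(i) rand_rna(sample(14:40, 1)),
             character(1)),
      paste0("ref", seq_len(n_ref))), "target")
    read <- rand_rna(sample(12:60, 1))
    # half the trials plant a real fragment so matches actually occur
    if (trial %% 2 == 0) {
      src <- refs$seq[[sample(n_ref, 1)]]
      fl <- sample(12:min(20, nchar(src)), 1)
      fs <- sample(nchar(src) - fl + 1, 1)
      pos <- sample(nchar(read) - fl + 1, 1)
      substr(read, pos, pos + fl - 1) <- substr(src, fs, fs + fl - 1)
    }
    idx <- build_index(refs, 12)
    got <- canon_hits(find_fragments_exact(read, idx, 12))
    want <- oracle_exact_matches(read, refs, 12)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("trial", trial))
  }
})

test_that("aligned search tolerates substitutions and short indels", {
  set.seed(9)
  ref <- rand_rna(24)
  refs <- seq_set(c(m = ref), "target")
  idx <- build_index(refs, 12)
  params <- search_params()

  h <- find_fragments_aligned(ref, idx, params)
  expect_equal(nrow(h), 1L)
  expect_equal(h$align_score, 24)          # perfect copy: length * match
  expect_equal(h$n_mismatch, 0L)

  mut <- ref
  substr(mut, 12, 12) <- if (substr(ref, 12, 12) == "A") "C" else "A"
  h <- find_fragments_aligned(mut, idx, params)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_mismatch, 1L)
  expect_equal(h$read_start, 0L)
  expect_equal(h$read_end, 24L)

  del <- paste0(substr(ref, 1, 11), substr(ref, 13, 24))
  h <- find_fragments_aligned(del, idx, params)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_indel, 1L)
})

test_that("fragment pairing enforces the overlap and gap limits", {
  params <- search_params(max_overlap = 4, max_gap_between = 4)
  hit <- function(s, e, ref = "x", score = e - s)
    data.frame(ref_name = ref, read_start = s, read_end = e,
               ref_start = 0L, ref_end = e - s, n_mismatch = 0L,
               n_indel = 0L, align_score = score, stringsAsFactors = FALSE)
  # adjacent fragments: overlap 0, gap 0, regulatory first
  c1 <- pair_fragments(hit(0, 21), hit(21, 46), params)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$overlap_nt, 0L)
  expect_equal(c1$gap_nt, 0L)
  expect_equal(c1$orientation, "reg_first")
  expect_equal(c1$combined_score, 21 + 25)

  # 3-nt overlap is within the default allowance of 4
  c2 <- pair_fragments(hit(0, 21), hit(18, 40), params)
  expect_equal(c2$overlap_nt, 3L)
  expect_equal(c2$combined_score, 21 + 22 - 3)

  # 6-nt overlap is rejected
  expect_equal(nrow(pair_fragments(hit(0, 21), hit(15, 40), params)), 0L)

  # 4-nt gap accepted, 5-nt gap rejected
  expect_equal(pair_fragments(hit(0, 21), hit(25, 45), params)$gap_nt, 4L)
  expect_equal(nrow(pair_fragments(hit(0, 21), hit(26, 46), params)), 0L)

  # target-first orientation
  c3 <- pair_fragments(hit(20, 40), hit(0, 20), params)
  expect_equal(c3$orientation, "target_first")
})

test_that("strict mode demands an intact regulatory RNA and perfect target", {
  set.seed(21)
  reg <- rand_rna(21)
  tgt <- rand_rna(300)
  regs <- seq_set(c(mir = reg), "regulatory")
  tgts <- seq_set(c(t1 = tgt), "target")
  ri <- build_index(regs, 12); ti <- build_index(tgts, 12)
  params <- search_params(mode = "strict")
  frag <- substr(tgt, 100, 124)

  cand <- search_strict(paste0(reg, frag), ri, ti, params)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$orientation, "reg_first")
  expect_equal(cand$tgt_ref_start, 99L)
  expect_equal(cand$tgt_ref_end, 124L)
  expect_equal(cand$overlap_nt, 0L)

  # target-first order is also found
  cand <- search_strict(paste0(frag, reg), ri, ti, params)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$orientation, "target_first")

  # one mismatch in the regulatory fragment: no candidate
  reg_mut <- reg
  substr(reg_mut, 10, 10) <- if (substr(reg, 10, 10) == "G") "C" else "G"
  expect_equal(nrow(search_strict(paste0(reg_mut, frag), ri, ti, params)), 0L)

  # a 4-nt insertion between the fragments: no candidate
  expect_equal(nrow(search_strict(paste0(reg, "ACGU", frag), ri, ti, params)),
               0L)

  # remaining sequence below min_fragment_len: no candidate
  expect_equal(nrow(search_strict(paste0(reg, substr(tgt, 100, 110)),
                                  ri, ti, params)), 0L)
})

test_that("scored mode returns the single best-scoring interpretation", {
  set.seed(33)
  reg <- rand_rna(21)
  t1 <- rand_rna(200)
  frag_long <- substr(t1, 50, 74)    # 25 nt, unique to t1
  # t2 shares only the first 18 nt of that fragment, a weaker interpretation
  t2 <- paste0(rand_rna(100), substr(frag_long, 1, 18), rand_rna(80))
  regs <- seq_set(c(mir = reg), "regulatory")
  tgts <- seq_set(c(t1 = t1, t2 = t2), "target")
  ri <- build_index(regs, 12); ti <- build_index(tgts, 12)
  params <- search_params(mode = "scored")

  read <- paste0(reg, frag_long)
  exh <- search_exhaustive(read, ri, ti,
                           search_params(mode = "exhaustive"))
  expect_setequal(unique(exh$tgt_name), c("t1", "t2"))
  cand <- search_scored(read, ri, ti, params)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$tgt_name, "t1")

  # identical-score interpretations tie-break to the smaller target name
  tgts2 <- seq_set(c(b = t1, a = t1), "target")
  ti2 <- build_index(tgts2, 12)
  cand <- search_scored(read, ri, ti2, params)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$tgt_name, "a")

  # nothing pairable: empty result
  expect_equal(nrow(search_scored(rand_rna(40), ri, ti, params)), 0L)
})

test_that("exhaustive mode reports all interpretations of a multimapping fragment", {
  set.seed(55)
  reg <- rand_rna(21)
  shared <- rand_rna(25)
  t1 <- paste0(rand_rna(80), shared, rand_rna(80))
  t2 <- paste0(rand_rna(40), shared, rand_rna(120))
  regs <- seq_set(c(mir = reg), "regulatory")
  tgts <- seq_set(c(t1 = t1, t2 = t2), "target")
  ri <- build_index(regs, 12); ti <- build_index(tgts, 12)
  cand <- search_exhaustive(paste0(reg, shared), ri, ti,
                            search_params(mode = "exhaustive"))
  expect_setequal(unique(cand$tgt_name), c("t1", "t2"))
  expect_gte(nrow(cand), 2L)
  # sorted by descending combined score
  expect_true(all(diff(cand$combined_score) <= 0))
})

candidate_keys <- function(cand) {
  paste(cand$read_id, cand$reg_name, cand$reg_read_start, cand$reg_read_end,
        cand$reg_ref_start, cand$reg_ref_end, cand$tgt_name,
        cand$tgt_read_start, cand$tgt_read_end, cand$tgt_ref_start,
        cand$tgt_ref_end, cand$orientation, sep = ":")
}

test_that("stringency containment holds on synthetic libraries", {
  for (seed in 1:3) {
    x <- small_library(seed = seed, n_chimeric = 20, n_background = 8)
    pre <- preprocess_library(x)
    strict <- search_reads(pre$reads, x$refs$reg, x$refs$tgt,
                           search_params(mode = "strict"))$candidates
    scored <- search_reads(pre$reads, x$refs$reg, x$refs$tgt,
                           search_params(mode = "scored"))$candidates
    exh <- search_reads(pre$reads, x$refs$reg, x$refs$tgt,
                        search_params(mode = "exhaustive"))$candidates
    expect_true(all(candidate_keys(strict) %in% candidate_keys(exh)))
    expect_true(all(candidate_keys(scored) %in% candidate_keys(exh)))
    expect_gte(nrow(exh), nrow(strict))
  }
})

test_that("the search is deterministic for identical inputs", {
  x <- small_library(seed = 8, n_chimeric = 15, n_background = 5)
  pre <- preprocess_library(x)
  a <- search_reads(pre$reads, x$refs$reg, x$refs$tgt, search_params())
  b <- search_reads(pre$reads, x$refs$reg, x$refs$tgt, search_params())
  expect_identical(a, b)
})
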