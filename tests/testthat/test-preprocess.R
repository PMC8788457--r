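test_that("Phred scores convert to base-call accuracies", {
  expect_equal(phred_to_accuracy(30), 0.999)
  expect_equal(phred_to_accuracy(50), 0.99999)
  expect_equal(phred_to_accuracy(0), 0)
  expect_error(phred_to_accuracy(-1), "non-negative")
  # strictly increasing; accuracy + error probability = 1
  q <- 0:60
  acc <- phred_to_accuracy(q)
  expect_true(all(diff(acc) > 0))
  expect_equal(acc + 10^(-q / 10), rep(1, length(q)))
})

test_that("3' adaptor trimming removes full and partial matches", {
  cfg <- trim_config(adapter3 = "AGAUCGGAAGAG")
  insert <- "ACGUACGUACGUACGUA"
  r <- trim_adapter3(make_read(paste0(insert, "AGAUCGGAAGAG")), cfg)
  expect_equal(r$sequence, insert)
  expect_equal(length(r$qualities[[1]]), nchar(insert))

  # no adaptor: unchanged
  r <- trim_adapter3(make_read(insert), cfg)
  expect_equal(r$sequence, insert)

  # 3-nt adaptor prefix at the 3' end, at the minimum overlap
  r <- trim_adapter3(make_read(paste0(insert, "AGA")), cfg)
  expect_equal(r$sequence, insert)

  # 2-nt prefix is below the minimum overlap
  r <- trim_adapter3(make_read(paste0(insert, "AG")), cfg)
  expect_equal(r$sequence, paste0(insert, "AG"))

  # one mismatch in a 12-nt match is within the 10% tolerance
  r <- trim_adapter3(make_read(paste0(insert, "AGAUCGGAACAG")), cfg)
  expect_equal(r$sequence, insert)

  # leftmost occurrence wins even with trailing bases after the adaptor
  r <- trim_adapter3(make_read(paste0(insert, "AGAUCGGAAGAG", "CCCC")), cfg)
  expect_equal(r$sequence, insert)
})

test_that("5' barcode/UMI extraction populates umi and discards mismatches", {
  cfg <- trim_config(barcode5_pattern = "NNNNNN")
  out <- trim_5prime(make_read(paste0("ACGUAC", "GGGGCCCCAAAA")), cfg)
  expect_true(out$keep)
  expect_equal(out$read$umi, "ACGUAC")
  expect_equal(out$read$sequence, "GGGGCCCCAAAA")
  expect_equal(length(out$read$qualities[[1]]), 12L)

  # empty pattern: no-op
  out <- trim_5prime(make_read("ACGU"), trim_config())
  expect_true(out$keep)
  expect_equal(out$read$sequence, "ACGU")
  expect_equal(out$read$umi, "")

  # fixed-base mismatch discards
  cfg2 <- trim_config(barcode5_pattern = "GGNNNN")
  out <- trim_5prime(make_read("CCAAAAUUUUGGGG"), cfg2)
  expect_false(out$keep)
  expect_equal(out$reason, "barcode_mismatch")
  out <- trim_5prime(make_read("GGACGUCCCUUUAAA"), cfg2)
  expect_true(out$keep)
  expect_equal(out$read$umi, "ACGU")

  # read shorter than the pattern discards
  out <- trim_5prime(make_read("ACG"), cfg)
  expect_false(out$keep)

  # 5' adaptor ahead of the barcode is removed first
  cfg3 <- trim_config(adapter5 = "GUUCAG", barcode5_pattern = "NNNNNN")
  out <- trim_5prime(make_read(paste0("GUUCAG", "AAAACC", "GCGCGCGC")), cfg3)
  expect_true(out$keep)
  expect_equal(out$read$umi, "AAAACC")
  expect_equal(out$read$sequence, "GCGCGCGC")
})

test_that("length and mean-quality filtering uses inclusive bounds", {
  cfg <- trim_config()
  expect_false(filter_read(make_read(rand_rna(16)), cfg))
  expect_true(filter_read(make_read(rand_rna(17), rep(30L, 17)), cfg))
  expect_true(filter_read(make_read(rand_rna(70), rep(40L, 70)), cfg))
  expect_false(filter_read(make_read(rand_rna(71)), cfg))
  # mean Phred exactly at the threshold is kept; just below is dropped
  q <- c(rep(20L, 10), rep(40L, 10))
  expect_true(filter_read(make_read(rand_rna(20), q), cfg))
  q[1] <- 19L
  expect_false(filter_read(make_read(rand_rna(20), q), cfg))
})

test_that("collapsing merges identical sequences and respects UMIs", {
  reads <- bind_reads(make_read("ACGU", id = "a"),
                      make_read("ACGU", id = "b"),
                      make_read("ACGG", id = "c"))
  col <- collapse_reads(reads, umi_aware = FALSE)
  expect_equal(nrow(col), 2L)
  expect_equal(col$count, c(2L, 1L))          # sorted by descending count
  expect_equal(col$sequence, c("ACGU", "ACGG"))
  expect_equal(col$read_id[1], "a")           # first occurrence represents

  # same sequence, different UMIs: distinct molecules when umi_aware
  reads <- bind_reads(make_read("ACGU", id = "a", umi = "AAAAAA"),
                      make_read("ACGU", id = "b", umi = "CCCCCC"))
  expect_equal(nrow(collapse_reads(reads, umi_aware = TRUE)), 2L)
  expect_equal(collapse_reads(reads, umi_aware = FALSE)$count, 2L)
})

test_that("preprocessing recovers every planted insert from an error-free library", {
  x <- small_library(seed = 3, n_chimeric = 25, n_background = 10)
  pre <- preprocess_library(x)
  expect_equal(pre$stats$n_input, 35L)
  expect_true(pre$stats$n_after_trim <= pre$stats$n_input)
  expect_true(pre$stats$n_unique_after_trim <= pre$stats$n_after_trim)
  m <- x$lib$manifest
  got <- pre$reads$sequence[match(m$read_id, pre$reads$read_id)]
  expect_equal(got, m$insert_seq)
  umis <- pre$reads$umi[match(m$read_id, pre$reads$read_id)]
  expect_equal(umis, m$umi)
})

test_that("trimming never grows a read and keeps qualities in lockstep", {
  cfg <- trim_config(barcode5_pattern = "NNNNNN", adapter3 = "AGAUCGGAAGAG")
  set.seed(11)
  for (i in 1:40) {
    L <- sample(10:80, 1)
    r <- make_read(rand_rna(L), sample(0:93, L, replace = TRUE))
    out <- trim_5prime(r, cfg)
    if (out$keep) r2 <- trim_adapter3(out$read, cfg) else r2 <- r
    expect_lte(nchar(r2$sequence), L)
    expect_equal(nchar(r2$sequence), length(r2$qualities[[1]]))
  }
})

test_that("preprocessing of empty or all-short input gives zero counts", {
  cfg <- trim_config()
  out <- preprocess_run(empty_reads(), cfg)
  expect_equal(out$stats$n_input, 0L)
  expect_equal(out$stats$n_after_trim, 0L)
  short <- bind_reads(make_read("ACGU"), make_read("GGGG"))
  out <- preprocess_run(short, cfg)
  expect_equal(out$stats$n_after_trim, 0L)
  expect_equal(nrow(out$reads), 0L)
})
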