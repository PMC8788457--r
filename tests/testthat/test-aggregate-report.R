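# minimal scored-candidate row builder
cand_row <- function(read_id, reg = "mir", tgt = "t1", tstart0 = 100L,
                     tend0 = 125L, count = 1L, dG = -15,
                     orientation = "reg_first") {
  data.frame(read_id = read_id, count = count, reg_name = reg,
             reg_read_start = 0L, reg_read_end = 21L,
             reg_ref_start = 0L, reg_ref_end = 21L, reg_score = 21,
             tgt_name = tgt, tgt_read_start = 21L, tgt_read_end = 46L,
             tgt_ref_start = tstart0, tgt_ref_end = tend0, tgt_score = 25,
             n_mismatch = 0L, n_indel = 0L, orientation = orientation,
             overlap_nt = 0L, gap_nt = 0L, combined_score = 46,
             hybrid_dG = dG, duplex_stable = TRUE, duplex_pairs = 18L,
             diagram = "x", stringsAsFactors = FALSE)
}

test_that("grouping sums counts over distinct reads at one site", {
  cands <- rbind(cand_row("r1", count = 2L), cand_row("r2"), cand_row("r3"))
  ix <- group_interactions(cands)
  expect_equal(nrow(ix$interactions), 1L)
  expect_equal(ix$interactions$total_read_count, 4L)
  expect_equal(ix$interactions$n_unique_chimeras, 3L)
  expect_equal(ix$interactions$n_sites, 1L)
  expect_equal(nrow(ix$sites), 1L)
  expect_equal(ix$sites$tgt_start_1based, 101L)
  expect_equal(ix$sites$tgt_end_1based, 125L)
})

test_that("grouping is empty for no candidates and splits distant sites", {
  ix <- group_interactions(cand_row("x")[0, ])
  expect_equal(nrow(ix$interactions), 0L)
  expect_equal(nrow(ix$sites), 0L)

  # two sites 100 nt apart on one target: one interaction, two sites
  cands <- rbind(cand_row("r1", tstart0 = 100L, tend0 = 125L),
                 cand_row("r2", tstart0 = 225L, tend0 = 250L, dG = -8))
  ix <- group_interactions(cands)
  expect_equal(nrow(ix$interactions), 1L)
  expect_equal(ix$interactions$n_sites, 2L)
  expect_equal(ix$interactions$best_dG, -15)
  expect_equal(nrow(ix$sites), 2L)

  # spans overlapping by 1 nt merge into a single site
  cands <- rbind(cand_row("r1", tstart0 = 100L, tend0 = 125L),
                 cand_row("r2", tstart0 = 124L, tend0 = 150L))
  ix <- group_interactions(cands)
  expect_equal(ix$interactions$n_sites, 1L)
  expect_equal(ix$sites$tgt_start_1based, 101L)
  expect_equal(ix$sites$tgt_end_1based, 150L)

  # abutting (zero-overlap) spans stay separate
  cands <- rbind(cand_row("r1", tstart0 = 100L, tend0 = 125L),
                 cand_row("r2", tstart0 = 125L, tend0 = 150L))
  expect_equal(group_interactions(cands)$interactions$n_sites, 2L)
})

test_that("browse views aggregate and sort as documented", {
  cands <- rbind(
    cand_row("r1", reg = "mirA", tgt = "t1"),
    cand_row("r2", reg = "mirA", tgt = "t2", dG = -5),
    cand_row("r3", reg = "mirB", tgt = "t1", count = 3L),
    cand_row("r4", reg = "mirB", tgt = "t1"))
  ix <- group_interactions(cands)

  byreg <- view_by_regulatory(ix)
  expect_equal(byreg$reg_name, c("mirA", "mirB"))   # 2 targets beats 1
  expect_equal(byreg$n_targets, c(2L, 1L))

  bytgt <- view_by_target(ix)
  expect_equal(bytgt$tgt_name[1], "t1")
  expect_equal(bytgt$n_unique_chimeras, c(3L, 1L))
  expect_equal(bytgt$n_regulatory, c(2L, 1L))

  bypair <- view_by_pair(ix, "read_count")
  expect_equal(bypair$read_count[1], 4L)            # mirB/t1: 3 + 1
  bypair_e <- view_by_pair(ix, "energy")
  expect_equal(bypair_e$hybrid_dG, sort(bypair_e$hybrid_dG))
  expect_error(view_by_pair(ix, "banana"), "sort_key")

  # equal read counts rank by lower (more favorable) energy
  cands2 <- rbind(cand_row("r1", tgt = "t1", dG = -20.1),
                  cand_row("r2", tgt = "t2", dG = -5.2))
  bp <- view_by_pair(group_interactions(cands2), "read_count")
  expect_equal(bp$hybrid_dG, c(-20.1, -5.2))
})

test_that("region annotation labels sites by majority overlap", {
  regions <- data.frame(
    tgt_name = "t1", region = c("5UTR", "CDS", "3UTR"),
    start_1based = c(1L, 51L, 100L), end_1based = c(50L, 99L, 300L),
    stringsAsFactors = FALSE)

  # site fully inside the 3'UTR
  ix <- group_interactions(cand_row("r1", tstart0 = 119L, tend0 = 145L))
  ann <- annotate_regions(ix, regions)
  expect_equal(ann$sites$region, "3UTR")
  expect_equal(ann$summary$n_sites[ann$summary$region == "3UTR"], 1L)

  # site straddling the CDS/3UTR boundary with 60% in the 3'UTR
  ix <- group_interactions(cand_row("r1", tstart0 = 91L, tend0 = 111L))
  # span 92..111: 8 nt in CDS (92-99), 12 nt in 3UTR (100-111)
  expect_equal(annotate_regions(ix, regions)$sites$region, "3UTR")

  # exact tie goes to the downstream-most region
  ix2 <- group_interactions(cand_row("r1", tstart0 = 91L, tend0 = 107L))
  # span 92..107: CDS 92-99 = 8 nt, 3UTR 100-107 = 8 nt -> tie -> 3UTR
  expect_equal(annotate_regions(ix2, regions)$sites$region, "3UTR")

  # transcript absent from the table
  ix <- group_interactions(cand_row("r1", tgt = "t9"))
  expect_equal(annotate_regions(ix, regions)$sites$region, "unannotated")
})

test_that("region tables load from TSV and BED with coordinate conversion", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("tgt_name\tregion\tstart\tend", "t1\t5UTR\t1\t50",
               "t1\tCDS\t51\t99"), f)
  tsv <- read_region_table(f, "tsv")
  expect_equal(tsv$start_1based, c(1L, 51L))

  b <- tempfile(fileext = ".bed")
  writeLines(c("t1\t0\t50\t5UTR", "t1\t50\t99\tCDS"), b)
  bed <- read_region_table(b, "bed")
  expect_equal(bed$start_1based, c(1L, 51L))
  expect_equal(bed$end_1based, c(50L, 99L))

  writeLines(c("tgt_name\tregion\tstart\tend", "t1\tA\t1\t50",
               "t1\tB\t40\t99"), f)
  expect_error(read_region_table(f, "tsv"), "overlapping")
})

test_that("run summaries capture parameters and the four read counts", {
  s <- summarize_run(list(n_input = 100, n_after_trim = 80,
                          n_unique_after_trim = 60, n_chimeric = 30,
                          n_interactions = 12),
                     list(min_len = 17, algorithm = "exhaustive"))
  expect_equal(s$counts$value,
               c(100L, 80L, 60L, 30L, 12L))
  expect_setequal(s$parameters$setting, c("min_len", "algorithm"))
  # empty run: counts all zero, parameters still complete
  s0 <- summarize_run(list(), list(min_len = 17))
  expect_equal(s0$counts$value, rep(0L, 5))
  expect_equal(nrow(s0$parameters), 1L)
})

test_that("read counts are conserved through grouping in strict and scored modes", {
  for (mode in c("strict", "scored")) {
    x <- small_library(seed = 4, n_chimeric = 25, n_background = 10)
    pre <- preprocess_library(x)
    sr <- search_reads(pre$reads, x$refs$reg, x$refs$tgt,
                       search_params(mode = mode))
    cands <- score_chimeras(sr$candidates, x$refs$reg, x$refs$tgt)
    ix <- group_interactions(cands)
    expect_equal(sum(ix$interactions$total_read_count), sr$n_chimeric,
                 info = mode)
  }
})
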