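# Pipeline orchestration: preprocess -> chimera search -> duplex energy ->
# aggregation -> CSV reports, with run-parameter capture and logging.

#' Full run configuration
#'
#' Bundles input paths, trimming, search, energy and report options with the
#' standard defaults (length range 17-70 nt, mean Phred 30, junction overlap
#' 4 nt, exhaustive search).  Every field is serialized verbatim into the
#' run's parameters table.
#'
#' @param reads FASTQ(.gz) of raw reads.
#' @param regulatory,targets FASTA(.gz) reference sets.
#' @param out_dir output directory (created).
#' @param adapter5,adapter3,barcode5 trimming inputs (see [trim_config()]).
#' @param min_len,max_len,min_phred filtering thresholds.
#' @param algorithm `"exhaustive"` (default), `"scored"` or `"strict"`.
#' @param min_fragment,max_overlap,max_hits search knobs
#'   (see [search_params()]).
#' @param energy_params optional custom energy table path.
#' @param regions optional region-annotation table path.
#' @param regions_format `"tsv"` or `"bed"`.
#' @param sort_key ranking for the pair view (`"read_count"` or `"energy"`).
#' @param skip_preprocess treat the input as already trimmed and filtered.
#' @return a `run_config` list.
#' @export
run_config <- function(reads, regulatory, targets, out_dir,
                       adapter5 = "", adapter3 = "", barcode5 = "",
                       min_len = 17L, max_len = 70L, min_phred = 30,
                       algorithm = c("exhaustive", "scored", "strict"),
                       min_fragment = 16L, max_overlap = 4L, max_hits = 10L,
                       energy_params = NULL, regions = NULL,
                       regions_format = c("tsv", "bed"),
                       sort_key = c("read_count", "energy"),
                       skip_preprocess = FALSE) {
  structure(list(reads = reads, regulatory = regulatory, targets = targets,
                 out_dir = out_dir, adapter5 = adapter5, adapter3 = adapter3,
                 barcode5 = barcode5, min_len = min_len, max_len = max_len,
                 min_phred = min_phred, algorithm = match.arg(algorithm),
                 min_fragment = min_fragment, max_overlap = max_overlap,
                 max_hits = max_hits, energy_params = energy_params,
                 regions = regions,
                 regions_format = match.arg(regions_format),
                 sort_key = match.arg(sort_key),
                 skip_preprocess = skip_preprocess),
            class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Cross-field checks; every violation is reported, naming the offending
#' option(s).
#'
#' @param cfg a [run_config()].
#' @return the normalized config, or an error listing every violation.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  if (cfg$min_len > cfg$max_len)
    errs <- c(errs, sprintf("min_len (%d) exceeds max_len (%d)",
                            cfg$min_len, cfg$max_len))
  if (cfg$min_len < 1L) errs <- c(errs, "min_len must be >= 1")
  if (cfg$min_phred < 0 || cfg$min_phred > 93)
    errs <- c(errs, "min_phred must lie in [0, 93]")
  if (cfg$min_fragment < 8L) errs <- c(errs, "min_fragment must be >= 8")
  if (cfg$max_overlap < 0L) errs <- c(errs, "max_overlap must be >= 0")
  if (cfg$max_hits < 1L) errs <- c(errs, "max_hits must be >= 1")
  bc <- as_rna(cfg$barcode5)
  if (nchar(bc) && grepl("[^ACGUN]", bc))
    errs <- c(errs, "barcode5 must be over {A,C,G,U,N}")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$barcode5 <- bc
  cfg
}

#' Run the full analysis pipeline
#'
#' Preprocess -> search -> duplex energy -> aggregate -> report.  Writes,
#' under `out_dir`: `collapsed.fasta` (unique trimmed reads, `name_count`
#' headers), `per_read.csv` (every chimera interpretation, 1-based
#' coordinates), `by_regulatory.csv`, `by_target.csv`, `by_pair.csv`,
#' `parameters.csv`, `counts.csv`, optionally `region_summary.csv`, and
#' `run.log`.  All CSVs are byte-deterministic for identical inputs.
#'
#' @param cfg a [run_config()], validated with [validate_config()].
#' @return (invisibly) a list with the collapsed reads, candidate table,
#'   interaction set, views and stats.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  for (f in c("reads", "regulatory", "targets"))
    if (!file.exists(cfg[[f]]))
      stop("input file for --", f, " not found: ", cfg[[f]])
  if (!is.null(cfg$regions) && !file.exists(cfg$regions))
    stop("region annotation file not found: ", cfg$regions)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  cat("", file = logf)
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  log("reading references")
  reg_set <- read_fasta(cfg$regulatory, "regulatory")
  tgt_set <- read_fasta(cfg$targets, "target")
  log("reading reads: ", cfg$reads)
  raw <- read_fastq(cfg$reads)
  tcfg <- trim_config(adapter5 = cfg$adapter5,
                      barcode5_pattern = cfg$barcode5,
                      adapter3 = cfg$adapter3, min_len = cfg$min_len,
                      max_len = cfg$max_len, min_phred = cfg$min_phred)
  if (cfg$skip_preprocess) {
    log("preprocessing skipped (input declared pre-trimmed)")
    raw$sequence <- as_rna(raw$sequence)
    pre <- list(reads = collapse_reads(raw, umi_aware = FALSE),
                stats = list(n_input = nrow(raw), n_after_trim = nrow(raw),
                             n_unique_after_trim = NA_integer_))
    pre$stats$n_unique_after_trim <- nrow(pre$reads)
  } else {
    log("preprocessing ", nrow(raw), " reads")
    pre <- preprocess_run(raw, tcfg)
  }
  log("kept ", pre$stats$n_after_trim, " reads (",
      pre$stats$n_unique_after_trim, " unique)")
  collapsed <- pre$reads
  if (nrow(collapsed)) {
    fa <- stats::setNames(collapsed$sequence,
                          paste0(collapsed$read_id, "_", collapsed$count))
    write_fasta(fa, file.path(cfg$out_dir, "collapsed.fasta"))
  }
  params <- search_params(mode = cfg$algorithm,
                          min_fragment_len = cfg$min_fragment,
                          max_overlap = cfg$max_overlap,
                          max_hits_per_fragment = cfg$max_hits)
  log("searching chimeras (", cfg$algorithm, " mode)")
  sr <- search_reads(collapsed, reg_set, tgt_set, params)
  log(nrow(sr$candidates), " candidate interpretations; chimeric read count ",
      sr$n_chimeric)
  model <- if (is.null(cfg$energy_params)) energy_model()
           else energy_model(cfg$energy_params)
  log("scoring duplex energies")
  cands <- score_chimeras(sr$candidates, reg_set, tgt_set, model)
  ix <- group_interactions(cands)
  log(nrow(ix$interactions), " RNA-RNA interactions")
  stats <- c(pre$stats, list(n_chimeric = sr$n_chimeric,
                             n_interactions = nrow(ix$interactions)))
  summ <- summarize_run(stats, unclass(cfg))
  # per-read table, 1-based inclusive coordinates
  per_read <- cands
  for (col in c("reg_read_start", "reg_ref_start", "tgt_read_start",
                "tgt_ref_start"))
    per_read[[col]] <- per_read[[col]] + 1L
  names(per_read) <- sub("_start$", "_start_1based", names(per_read))
  names(per_read) <- sub("_end$", "_end_1based", names(per_read))
  per_read <- per_read[order(per_read$read_id, -per_read$combined_score,
                             per_read$reg_name, per_read$tgt_name), ,
                       drop = FALSE]
  write_csv_table(per_read, file.path(cfg$out_dir, "per_read.csv"))
  write_csv_table(view_by_regulatory(ix),
                  file.path(cfg$out_dir, "by_regulatory.csv"))
  write_csv_table(view_by_target(ix),
                  file.path(cfg$out_dir, "by_target.csv"))
  pair_view <- view_by_pair(ix, cfg$sort_key)
  annotated <- NULL
  if (!is.null(cfg$regions)) {
    regions <- read_region_table(cfg$regions, cfg$regions_format)
    annotated <- annotate_regions(ix, regions)
    pair_view <- merge(pair_view, annotated$sites[
      c("reg_name", "tgt_name", "site", "region")],
      by = c("reg_name", "tgt_name", "site"), sort = FALSE)
    write_csv_table(annotated$summary,
                    file.path(cfg$out_dir, "region_summary.csv"))
  }
  write_csv_table(pair_view, file.path(cfg$out_dir, "by_pair.csv"))
  write_csv_table(summ$parameters, file.path(cfg$out_dir, "parameters.csv"))
  write_csv_table(summ$counts, file.path(cfg$out_dir, "counts.csv"))
  log("done")
  invisible(list(reads = collapsed, candidates = cands, interactions = ix,
                 pair_view = pair_view, annotated = annotated,
                 stats = stats, summary = summ))
}
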