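# Grouping per-read chimeras into RNA-RNA interactions, the three browse
# views, optional region annotation, and the run summary tables.
# All coordinates in these tables are 1-based inclusive (column names say so).

#' Group scored chimera candidates into RNA-RNA interactions
#'
#' Candidates are keyed by (regulatory RNA, target RNA); within a pair,
#' candidate target spans overlapping by at least 1 nt are merged into one
#' interaction site.  Each site's read count sums the collapsed counts of
#' its distinct supporting reads; the site's reported span, energy and
#' diagram come from its lowest-energy member.
#'
#' @param candidates candidate table annotated by [score_chimeras()].
#' @return list of class `interaction_set`: `interactions` (one row per
#'   RNA-RNA pair: `reg_name`, `tgt_name`, `n_sites`, `total_read_count`,
#'   `n_unique_chimeras`, `best_dG`) and `sites` (one row per site, 1-based
#'   inclusive spans).
#' @export
group_interactions <- function(candidates) {
  empty_sites <- data.frame(
    reg_name = character(), tgt_name = character(), site = integer(),
    tgt_start_1based = integer(), tgt_end_1based = integer(),
    reg_start_1based = integer(), reg_end_1based = integer(),
    read_count = integer(), n_unique_reads = integer(),
    hybrid_dG = numeric(), diagram = character(), stringsAsFactors = FALSE)
  empty_ix <- data.frame(
    reg_name = character(), tgt_name = character(), n_sites = integer(),
    total_read_count = integer(), n_unique_chimeras = integer(),
    best_dG = numeric(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L)
    return(structure(list(interactions = empty_ix, sites = empty_sites),
                     class = "interaction_set"))
  stopifnot("hybrid_dG" %in% names(candidates))
  key <- paste(candidates$reg_name, candidates$tgt_name, sep = "\r")
  site_rows <- list(); ix_rows <- list()
  for (k in sort(unique(key))) {
    grp <- candidates[key == k, , drop = FALSE]
    grp <- grp[order(grp$tgt_ref_start, grp$tgt_ref_end), , drop = FALSE]
    # merge target spans overlapping by >= 1 nt into sites
    site_id <- integer(nrow(grp)); cur <- 1L
    cur_end <- grp$tgt_ref_end[1]
    site_id[1] <- 1L
    for (i in seq_len(nrow(grp))[-1]) {
      if (grp$tgt_ref_start[i] < cur_end) {
        site_id[i] <- cur
        cur_end <- max(cur_end, grp$tgt_ref_end[i])
      } else {
        cur <- cur + 1L
        site_id[i] <- cur
        cur_end <- grp$tgt_ref_end[i]
      }
    }
    n_unique_ix <- length(unique(grp$read_id))
    total <- 0L
    for (sid in seq_len(cur)) {
      sg <- grp[site_id == sid, , drop = FALSE]
      firsts <- !duplicated(sg$read_id)
      rc <- sum(sg$count[firsts])
      total <- total + rc
      best <- sg[order(sg$hybrid_dG, sg$tgt_ref_start,
                       sg$reg_ref_start), , drop = FALSE][1, ]
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        reg_name = best$reg_name, tgt_name = best$tgt_name, site = sid,
        tgt_start_1based = min(sg$tgt_ref_start) + 1L,
        tgt_end_1based = max(sg$tgt_ref_end),
        reg_start_1based = best$reg_ref_start + 1L,
        reg_end_1based = best$reg_ref_end,
        read_count = rc, n_unique_reads = sum(firsts),
        hybrid_dG = best$hybrid_dG, diagram = best$diagram,
        stringsAsFactors = FALSE)
    }
    ix_rows[[length(ix_rows) + 1L]] <- data.frame(
      reg_name = grp$reg_name[1], tgt_name = grp$tgt_name[1],
      n_sites = cur, total_read_count = total,
      n_unique_chimeras = n_unique_ix,
      best_dG = min(grp$hybrid_dG), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  ix <- do.call(rbind, ix_rows)
  ord <- order(ix$reg_name, ix$tgt_name)
  ix <- ix[ord, , drop = FALSE]
  rownames(ix) <- NULL; rownames(sites) <- NULL
  structure(list(interactions = ix, sites = sites),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set> ", nrow(x$interactions), " RNA-RNA pairs, ",
      nrow(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Browse interactions by regulatory RNA
#'
#' One row per regulatory RNA with the number of distinct targets it was
#' found in chimeras with, sorted by descending target count then name.
#'
#' @param ix an [group_interactions()] result.
#' @return a `data.frame` (`reg_name`, `n_targets`, `n_unique_chimeras`,
#'   `total_read_count`).
#' @export
view_by_regulatory <- function(ix) {
  d <- ix$interactions
  if (nrow(d) == 0L)
    return(data.frame(reg_name = character(), n_targets = integer(),
                      n_unique_chimeras = integer(),
                      total_read_count = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(d, d$reg_name), function(g)
    data.frame(reg_name = g$reg_name[1], n_targets = nrow(g),
               n_unique_chimeras = sum(g$n_unique_chimeras),
               total_read_count = sum(g$total_read_count),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$n_targets, out$reg_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Browse interactions by target RNA
#'
#' One row per target RNA with the number of unique chimeras containing it
#' and the number of distinct regulatory RNAs pairing with it, sorted by
#' descending chimera count then name.
#'
#' @param ix an [group_interactions()] result.
#' @return a `data.frame` (`tgt_name`, `n_unique_chimeras`, `n_regulatory`,
#'   `total_read_count`).
#' @export
view_by_target <- function(ix) {
  d <- ix$interactions
  if (nrow(d) == 0L)
    return(data.frame(tgt_name = character(), n_unique_chimeras = integer(),
                      n_regulatory = integer(), total_read_count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(d, d$tgt_name), function(g)
    data.frame(tgt_name = g$tgt_name[1],
               n_unique_chimeras = sum(g$n_unique_chimeras),
               n_regulatory = nrow(g),
               total_read_count = sum(g$total_read_count),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$n_unique_chimeras, out$tgt_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Browse interactions by RNA-RNA pair (site level)
#'
#' One row per interaction site with read count, hybrid free energy, mapped
#' spans (1-based inclusive) and the pairing diagram, ranked by descending
#' read count (`sort_key = "read_count"`; ties by lower dG) or ascending
#' free energy (`sort_key = "energy"`; ties by higher count).
#'
#' @param ix an [group_interactions()] result.
#' @param sort_key `"read_count"` or `"energy"`.
#' @param max_rows optional preview cap applied after sorting (CSV exports
#'   pass `Inf`).
#' @return a site-level `data.frame`.
#' @export
view_by_pair <- function(ix, sort_key = c("read_count", "energy"),
                         max_rows = Inf) {
  if (!is.character(sort_key) || !all(sort_key %in% c("read_count", "energy")))
    stop("unknown sort_key: ", paste(sort_key, collapse = ","),
         " (expected 'read_count' or 'energy')")
  sort_key <- match.arg(sort_key)
  s <- ix$sites
  if (nrow(s) == 0L) return(s)
  ord <- if (sort_key == "read_count")
    order(-s$read_count, s$hybrid_dG, s$reg_name, s$tgt_name,
          s$tgt_start_1based)
  else
    order(s$hybrid_dG, -s$read_count, s$reg_name, s$tgt_name,
          s$tgt_start_1based)
  out <- s[ord, , drop = FALSE]
  if (is.finite(max_rows)) out <- utils::head(out, max_rows)
  rownames(out) <- NULL
  out
}

#' Read a target region-annotation table
#'
#' TSV format: columns `tgt_name`, `region`, `start`, `end` with 1-based
#' inclusive coordinates.  BED format: 4 columns (transcript, 0-based
#' half-open start/end, region label), converted internally.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"bed"`.
#' @return a `data.frame` (`tgt_name`, `region`, `start_1based`,
#'   `end_1based`).
#' @export
read_region_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("tgt_name", "region", "start", "end")
    if (!all(need %in% names(d)))
      stop("region TSV must have columns: ", paste(need, collapse = ", "))
    out <- data.frame(tgt_name = d$tgt_name, region = d$region,
                      start_1based = as.integer(d$start),
                      end_1based = as.integer(d$end),
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(d) < 4L) stop("region BED must have at least 4 columns")
    out <- data.frame(tgt_name = d[[1]], region = d[[4]],
                      start_1based = as.integer(d[[2]]) + 1L,
                      end_1based = as.integer(d[[3]]),
                      stringsAsFactors = FALSE)
  }
  # intervals must not overlap within a transcript
  for (tn in unique(out$tgt_name)) {
    g <- out[out$tgt_name == tn, , drop = FALSE]
    g <- g[order(g$start_1based), , drop = FALSE]
    if (nrow(g) > 1L &&
        any(g$start_1based[-1] <= g$end_1based[-nrow(g)]))
      stop("overlapping region intervals for transcript ", tn)
  }
  out
}

#' Annotate interaction sites with target regions
#'
#' Each site is labeled by the region (e.g. 5UTR/CDS/3UTR) containing the
#' majority of its target span; an exact tie goes to the downstream-most
#' region.  Sites on transcripts absent from the table (or outside all its
#' intervals) are labeled `"unannotated"`.
#'
#' @param ix an [group_interactions()] result.
#' @param regions a [read_region_table()] result.
#' @return list: `sites` (the site table with a `region` column) and
#'   `summary` (site count per region label, sorted by descending count).
#' @export
annotate_regions <- function(ix, regions) {
  s <- ix$sites
  lab <- rep("unannotated", nrow(s))
  for (i in seq_len(nrow(s))) {
    r <- regions[regions$tgt_name == s$tgt_name[i], , drop = FALSE]
    if (nrow(r) == 0L) next
    ov <- pmax(0L, pmin(r$end_1based, s$tgt_end_1based[i]) -
                   pmax(r$start_1based, s$tgt_start_1based[i]) + 1L)
    if (all(ov == 0L)) next
    best <- which(ov == max(ov))
    if (length(best) > 1L)   # boundary tie: downstream-most region
      best <- best[which.max(r$start_1based[best])]
    lab[i] <- r$region[best]
  }
  s$region <- lab
  tab <- table(lab)
  summary <- data.frame(region = names(tab), n_sites = as.integer(tab),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n_sites, summary$region), , drop = FALSE]
  rownames(summary) <- NULL
  list(sites = s, summary = summary)
}

#' Build the run summary tables
#'
#' @param stats named list of read-accounting counts (`n_input`,
#'   `n_after_trim`, `n_unique_after_trim`, `n_chimeric`, `n_interactions`).
#' @param params named list of every setting used for the run.
#' @return list of two `data.frame`s: `parameters` (setting, value) and
#'   `counts` (metric, value).
#' @export
summarize_run <- function(stats, params) {
  flat <- function(x) vapply(x, function(v) paste(format(v), collapse = ","),
                             character(1))
  parameters <- data.frame(setting = names(params), value = flat(params),
                           stringsAsFactors = FALSE)
  metrics <- c("n_input", "n_after_trim", "n_unique_after_trim",
               "n_chimeric", "n_interactions")
  vals <- vapply(metrics, function(m)
    if (is.null(stats[[m]])) 0L else as.integer(stats[[m]]), integer(1))
  counts <- data.frame(metric = metrics, value = vals,
                       stringsAsFactors = FALSE)
  list(parameters = parameters, counts = counts)
}
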