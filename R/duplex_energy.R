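# Intermolecular RNA duplex free energy: nearest-neighbor stacking with
# GU wobble, duplex initiation, terminal AU/GU penalties and affine
# bulge/internal-loop costs.  Hybridization-only: neither monomer's
# intramolecular structure is considered.

.PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")

.pkg_env <- new.env(parent = emptyenv())

#' Load a nearest-neighbor duplex energy model
#'
#' Parses the packaged (or a user-supplied) parameter table: 36 dinucleotide
#' stack free energies covering all Watson-Crick and GU-wobble steps, the
#' duplex initiation penalty, the terminal AU/GU penalty, and affine bulge
#' and internal-loop costs.  The stack table must satisfy the rotational
#' symmetry `value(XY/WZ) == value(ZW/YX)` (checked), which guarantees
#' `duplex_fold(a, b)` and `duplex_fold(b, a)` agree.
#'
#' @param path parameter file; default: the table shipped with the package.
#' @return an `energy_model` list with `stack` (6x6 matrix indexed by pair
#'   type), `init`, `terminal_au`, `bulge_open`, `bulge_ext`,
#'   `internal_open`, `internal_ext`, `max_loop`.
#' @export
energy_model <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_env$default_model)) return(.pkg_env$default_model)
    path <- system.file("extdata", "rna_duplex_params.tsv",
                        package = "clashr")
    cache <- TRUE
  } else cache <- FALSE
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stack <- matrix(NA_real_, 6L, 6L,
                  dimnames = list(.PAIR_CODES, .PAIR_CODES))
  scalars <- list()
  for (f in fields) {
    if (f[1] == "param") {
      scalars[[f[2]]] <- as.numeric(f[3])
    } else if (f[1] == "stack") {
      top <- strsplit(sub("/.*", "", f[2]), "")[[1]]
      bot <- strsplit(sub(".*/", "", f[2]), "")[[1]]
      left <- paste0(top[1], bot[1]); right <- paste0(top[2], bot[2])
      if (!(left %in% .PAIR_CODES && right %in% .PAIR_CODES))
        stop("invalid stack step in energy table: ", f[2])
      stack[left, right] <- as.numeric(f[3])
    } else stop("unrecognized energy-table row type: ", f[1])
  }
  if (anyNA(stack)) stop("energy table is missing stack entries")
  if (any(!is.finite(stack))) stop("non-finite stack energy")
  # rotational symmetry: value(L, R) == value(flip(R), flip(L))
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (l in .PAIR_CODES) for (r in .PAIR_CODES)
    if (abs(stack[l, r] - stack[flip(r), flip(l)]) > 1e-9)
      stop("stack table breaks rotational symmetry at ", l, "/", r)
  if (stack["GC", "CG"] != min(stack))
    stop("expected the GC/CG stack to be the most stabilizing entry")
  need <- c("init", "terminal_au", "bulge_open", "bulge_ext",
            "internal_open", "internal_ext", "max_loop")
  miss <- setdiff(need, names(scalars))
  if (length(miss)) stop("energy table missing: ", paste(miss, collapse = ", "))
  if (any(unlist(scalars[need[-7]]) < 0)) stop("penalties must be >= 0")
  model <- structure(c(list(stack = stack), scalars[need]),
                     class = "energy_model")
  if (cache) .pkg_env$default_model <- model
  model
}

.encode_rna <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  v[is.na(v)] <- 0L
  as.integer(v)
}

#' Minimum free energy intermolecular duplex between two RNA sequences
#'
#' Dynamic program over intermolecular pairings only: pairs increase along
#' `seq_a` and decrease along `seq_b` (antiparallel, no pseudoknots, no
#' intramolecular structure).  Total energy is initiation + stacking +
#' affine loop penalties + terminal AU/GU penalties; the minimum-energy
#' structure is returned with a deterministic tie-break (more pairs
#' preferred, then leftmost).  If no structure reaches dG <= 0, the result
#' is flagged as having no stable duplex (`stable = FALSE`, `dG = 0`, no
#' pairs).
#'
#' @param seq_a,seq_b RNA sequences over \{A,C,G,U\}, at most 200 nt.
#' @param model an [energy_model()]; default: the packaged table.
#' @return a `duplex_result`: `dG` (kcal/mol), `stable`, `pairs`
#'   (data.frame of 1-based `a_pos`, `b_pos`), `n_wc`, `n_gu`,
#'   `n_unpaired_a`, `n_unpaired_b`, plus the input sequences.
#' @export
duplex_fold <- function(seq_a, seq_b, model = energy_model()) {
  seq_a <- as_rna(seq_a); seq_b <- as_rna(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("duplex_fold requires non-empty sequences")
  if (grepl("[^ACGU]", seq_a) || grepl("[^ACGU]", seq_b))
    stop("duplex_fold sequences must be over {A,C,G,U}")
  if (nchar(seq_a) > 200L || nchar(seq_b) > 200L)
    stop("duplex_fold sequences must be at most 200 nt")
  res <- .duplex_dp(.encode_rna(seq_a), .encode_rna(seq_b), model$stack,
                    model$init, model$terminal_au, model$bulge_open,
                    model$bulge_ext, model$internal_open,
                    model$internal_ext, as.integer(model$max_loop))
  stable <- is.finite(res$dg) && res$dg <= 0
  pairs <- if (stable)
    data.frame(a_pos = res$a_pos, b_pos = res$b_pos)
  else data.frame(a_pos = integer(), b_pos = integer())
  ac <- strsplit(seq_a, "")[[1]]; bc <- strsplit(seq_b, "")[[1]]
  ptypes <- paste0(ac[pairs$a_pos], bc[pairs$b_pos])
  structure(list(
    dG = if (stable) res$dg else 0,
    stable = stable,
    pairs = pairs,
    n_wc = sum(ptypes %in% c("AU", "UA", "CG", "GC")),
    n_gu = sum(ptypes %in% c("GU", "UG")),
    n_unpaired_a = nchar(seq_a) - nrow(pairs),
    n_unpaired_b = nchar(seq_b) - nrow(pairs),
    seq_a = seq_a, seq_b = seq_b), class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  if (!x$stable) {
    cat("<duplex_result> no stable duplex\n")
  } else {
    cat("<duplex_result> dG =", format(x$dG, digits = 4), "kcal/mol,",
        nrow(x$pairs), "pairs\n")
    cat(render_diagram(x), "\n")
  }
  invisible(x)
}

#' Render a duplex as a three-line text diagram
#'
#' Top line: `seq_a` 5'->3'; middle line: `|` for Watson-Crick pairs, `:`
#' for GU wobbles; bottom line: `seq_b` 3'->5'.  Columns are aligned, with
#' `-` filling the opposite strand across a bulge and spaces padding
#' dangling ends.
#'
#' @param result a [duplex_fold()] result.
#' @param seq_a,seq_b the sequences folded (defaults: those stored in
#'   `result`; supplying different ones is an error).
#' @return a single string with embedded newlines.
#' @export
render_diagram <- function(result, seq_a = result$seq_a,
                           seq_b = result$seq_b) {
  if (!identical(as_rna(seq_a), result$seq_a) ||
      !identical(as_rna(seq_b), result$seq_b))
    stop("diagram sequences do not match the folded sequences")
  ac <- strsplit(result$seq_a, "")[[1]]
  bc <- strsplit(result$seq_b, "")[[1]]
  n <- length(ac); m <- length(bc)
  P <- result$pairs
  if (nrow(P) == 0L) return("(no stable duplex)")
  top <- character(0); mid <- character(0); bot <- character(0)
  pad <- function(x, w, fill) c(rep(fill, w - length(x)), x)
  padr <- function(x, w, fill) c(x, rep(fill, w - length(x)))
  # dangling 5' end of a / 3' end of b
  a_pre <- if (P$a_pos[1] > 1L) ac[seq_len(P$a_pos[1] - 1L)] else character(0)
  b_pre <- if (P$b_pos[1] < m) bc[m:(P$b_pos[1] + 1L)] else character(0)
  w <- max(length(a_pre), length(b_pre))
  top <- pad(a_pre, w, " "); bot <- pad(b_pre, w, " ")
  mid <- rep(" ", w)
  for (t in seq_len(nrow(P))) {
    if (t > 1L) {   # interior loop / bulge between pair t-1 and t
      aseg <- if (P$a_pos[t] - P$a_pos[t - 1L] > 1L)
        ac[(P$a_pos[t - 1L] + 1L):(P$a_pos[t] - 1L)] else character(0)
      bseg <- if (P$b_pos[t - 1L] - P$b_pos[t] > 1L)
        bc[(P$b_pos[t - 1L] - 1L):(P$b_pos[t] + 1L)] else character(0)
      w <- max(length(aseg), length(bseg))
      top <- c(top, padr(aseg, w, "-"))
      bot <- c(bot, padr(bseg, w, "-"))
      mid <- c(mid, rep(" ", w))
    }
    pt <- paste0(ac[P$a_pos[t]], bc[P$b_pos[t]])
    top <- c(top, ac[P$a_pos[t]])
    bot <- c(bot, bc[P$b_pos[t]])
    mid <- c(mid, if (pt %in% c("GU", "UG")) ":" else "|")
  }
  k <- nrow(P)
  a_post <- if (P$a_pos[k] < n) ac[(P$a_pos[k] + 1L):n] else character(0)
  b_post <- if (P$b_pos[k] > 1L) bc[(P$b_pos[k] - 1L):1L] else character(0)
  w <- max(length(a_post), length(b_post))
  top <- c(top, padr(a_post, w, " "))
  bot <- c(bot, padr(b_post, w, " "))
  mid <- c(mid, rep(" ", w))
  paste(paste(top, collapse = ""), paste(mid, collapse = ""),
        paste(bot, collapse = ""), sep = "\n")
}

#' Annotate chimera candidates with duplex free energies
#'
#' Extracts each candidate's regulatory and target fragment sequences from
#' the references, folds the fragment pair with [duplex_fold()], and
#' attaches `hybrid_dG` (kcal/mol; 0 when no stable duplex), `duplex_stable`,
#' `duplex_pairs` and the text `diagram`.  Identical fragment pairs are
#' folded once (memoized), so energies are deterministic across duplicates.
#'
#' @param candidates candidate table from [search_reads()].
#' @param reg_set,tgt_set the reference `seq_set`s.
#' @param model an [energy_model()].
#' @return the candidate table with energy columns appended.
#' @export
score_chimeras <- function(candidates, reg_set, tgt_set,
                           model = energy_model()) {
  n <- nrow(candidates)
  dG <- numeric(n); stable <- logical(n)
  npairs <- integer(n); diagram <- character(n)
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    aseq <- substr(reg_set$seq[[candidates$reg_name[i]]],
                   candidates$reg_ref_start[i] + 1L,
                   candidates$reg_ref_end[i])
    bseq <- substr(tgt_set$seq[[candidates$tgt_name[i]]],
                   candidates$tgt_ref_start[i] + 1L,
                   candidates$tgt_ref_end[i])
    key <- paste(aseq, bseq, sep = "|")
    res <- memo[[key]]
    if (is.null(res)) {
      res <- duplex_fold(aseq, bseq, model)
      memo[[key]] <- res
    }
    dG[i] <- res$dG
    stable[i] <- res$stable
    npairs[i] <- nrow(res$pairs)
    diagram[i] <- if (res$stable) render_diagram(res) else "(no stable duplex)"
  }
  candidates$hybrid_dG <- dG
  candidates$duplex_stable <- stable
  candidates$duplex_pairs <- npairs
  candidates$diagram <- diagram
  candidates
}
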