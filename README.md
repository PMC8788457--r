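# clashr

Analysis of CLASH sequencing data in R: from raw FASTQ reads to ranked,
energy-scored RNA–RNA interactions.

CLASH (crosslinking, ligation and sequencing of hybrids) captures in vivo
RNA–RNA interactions — a miRNA or piRNA bound to its target while engaged
by an Argonaute-family protein — as *chimeric* cDNA reads: a fragment of
the regulatory RNA ligated to a fragment of its target within one
sequencing read. Each chimeric read is direct physical evidence for one
interaction. `clashr` is for small-RNA biologists who have a CLASH
library (or any chimera-generating ligation protocol) plus two reference
FASTA sets — regulatory RNAs and candidate targets — and want a table of
supported interactions with binding-site coordinates, read support and
hybridization energies.

## What it does

1. **Preprocess** (`preprocess_run`): 5′ barcode/UMI extraction
   (`NNNNNN`-style patterns), 3′ adaptor trimming with partial-match
   tolerance, length filtering (default 17–70 nt) and mean-Phred
   filtering (default Q ≥ 30, i.e. ≥ 99.9% per-base accuracy since
   Q = −10·log₁₀ P(error)), then collapsing to unique reads with counts
   (UMI-aware, so PCR duplicates merge but distinct molecules do not).
2. **Chimera search** (`search_reads`) under three stringencies:
   - `strict` — an intact, mismatch-free copy of a regulatory RNA at one
     end of the read, the entire remainder matching a target perfectly;
     no junction gap or overlap.
   - `scored` — alignment-based fragments (match +1, mismatch −2, affine
     gaps) tolerating short indels; a single best-scoring interpretation
     per read.
   - `exhaustive` (default) — the most sensitive: every qualifying
     interpretation of every read is reported, up to 4 nt of junction
     overlap and 10 hits per fragment by default. Strict results are
     always a subset of exhaustive results, and the scored pick is always
     an element of them.
3. **Duplex energy** (`duplex_fold`, `score_chimeras`): minimum free
   energy of the intermolecular hybrid between the two fragments, by
   dynamic programming over a nearest-neighbor model (Watson–Crick and
   GU-wobble stacking, duplex initiation, terminal AU/GU penalties,
   affine bulge/internal loops; parameters shipped as a human-readable
   table). Lower dG = more thermodynamically favorable = more likely a
   genuine interaction.
4. **Aggregate and report** (`group_interactions`, `view_by_*`,
   `annotate_regions`): per-read chimeras grouped into (regulatory,
   target) interactions with merged binding sites; browse views by
   regulatory RNA, by target, and by pair (ranked by read count or by
   energy); optional 5′UTR/CDS/3′UTR site annotation; everything exported
   as deterministic CSV.
5. **Simulate** (`synth_config`, `generate_references`,
   `generate_library`, `evaluate_recovery`): synthetic CLASH libraries
   with planted chimeras and a ground-truth manifest, used throughout the
   test suite and usable for power/parameter exploration.

## Worked example

```r
library(clashr)

# a synthetic library: 50 chimeric + 20 background reads, no errors
cfg  <- synth_config(seed = 42, n_chimeric_reads = 50,
                     n_background_reads = 20, error_rate = 0)
refs <- generate_references(cfg)
lib  <- generate_library(refs, cfg)
d <- file.path(tempdir(), "demo"); write_library(refs, lib, d)

res <- run_pipeline(run_config(
  reads      = file.path(d, "reads.fastq"),
  regulatory = file.path(d, "regulatory.fa"),
  targets    = file.path(d, "targets.fa"),
  out_dir    = file.path(tempdir(), "demo_out"),
  barcode5   = "NNNNNN", adapter3 = "AGAUCGGAAGAGC",
  algorithm  = "strict"))

read.csv(file.path(tempdir(), "demo_out", "counts.csv"))
#>                metric value
#> 1             n_input    70
#> 2        n_after_trim    70
#> 3 n_unique_after_trim    70
#> 4          n_chimeric    50
#> 5      n_interactions    20
```

All 70 reads survive trimming (error-free library), 50 are classified
chimeric (the planted ones; the 20 background reads are rejected), and
they support 20 distinct RNA–RNA interactions. The pair view ranks sites
by read support, with the mapped site (1-based coordinates on the target)
and the hybrid free energy:

```r
head(read.csv(file.path(tempdir(), "demo_out", "by_pair.csv"))[, 1:6], 5)
#>   reg_name tgt_name tgt_start_1based tgt_end_1based read_count hybrid_dG
#> 1  reg_006  tgt_006               79            105          5    -47.77
#> 2  reg_014  tgt_014              289            310          5    -47.16
#> 3  reg_001  tgt_001              116            134          5    -31.35
#> 4  reg_017  tgt_017              296            323          4    -52.02
#> 5  reg_013  tgt_013              272            300          3    -64.92
```

A single duplex can be folded and drawn directly — here the *lin-4*
miRNA against its exact reverse complement:

```r
duplex_fold("UCCCUGAGACCUCAAGUGUGA", revcomp_rna("UCCCUGAGACCUCAAGUGUGA"))
#> <duplex_result> dG = -40.95 kcal/mol, 21 pairs
#> UCCCUGAGACCUCAAGUGUGA
#> |||||||||||||||||||||
#> AGGGACUCUGGAGUUCACACU
```

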