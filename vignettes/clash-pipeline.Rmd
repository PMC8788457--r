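---
title: "Identifying RNA-RNA interactions from CLASH chimeric reads"
author: "clashr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying RNA-RNA interactions from CLASH chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clashr)
```

## The problem and the data

CLASH (crosslinking, ligation and sequencing of hybrids) turns transient,
protein-mediated RNA-RNA contacts into sequence evidence: while a
regulatory RNA (miRNA, piRNA, snoRNA, ...) is base-paired with its target
inside an Argonaute-family complex, the two molecules are ligated and
sequenced as a single chimeric cDNA. A chimeric read therefore contains a
fragment of the regulatory RNA and a fragment of the target, joined at a
ligation junction, flanked by library adaptors and often a 5' barcode
containing a unique molecular identifier (UMI). The analysis task is to
recognize these chimeras among a majority of ordinary single-molecule
reads, decide which (regulatory, target) pair each one supports, locate
the binding site on the target, and rank the resulting interactions by
read support and by the thermodynamic plausibility of the hybrid.

`clashr` implements this as five composable stages: preprocessing,
chimera search, duplex-energy scoring, aggregation/reporting, and a
synthetic-data generator that provides ground truth for every claim the
test suite makes.

## Preprocessing

Reads are trimmed in a fixed order mirroring the library layout from the
5' end inward: (1) optional fixed 5' adaptor, (2) 5' barcode pattern,
where each `N` position is extracted into the read's UMI and fixed bases
must match exactly (a mismatch discards the read), (3) the 3' adaptor.
The 3' trimmer removes the leftmost occurrence of an adaptor prefix of at
least `min_adapter_overlap` (default 3) bases that runs through the
read's 3' end, tolerating a mismatch fraction of
`max_trim_mismatch_rate` (default 0.1). These two partial-match
parameters are this package's choices: the protocol delegates 3'
trimming to general-purpose adaptor trimmers whose defaults behave
similarly.

Filtering keeps reads whose trimmed length lies in `[min_len, max_len]`
(defaults 17 and 70 nt, the usual CLASH size-selection window) and whose
*mean* Phred score is at least `min_phred` (default 30), both bounds
inclusive. The mean-quality rule is a deliberate single-parameter choice;
per-base truncation schemes exist but add knobs without changing any
downstream contract. Phred scores relate to base-call accuracy as
$1 - 10^{-Q/10}$, so Q30 means 99.9% and Q50 means 99.999%.

Collapsing merges reads with identical sequence - and identical UMI, when
the barcode pattern contains `N` - summing their counts. UMI-aware
collapsing treats same-sequence/different-UMI reads as distinct
molecules; no UMI error correction or clustering is attempted, since the
protocol only specifies trimming the UMIs.

## Chimera search

Both fragments of a chimera map *sense* to their references: the chimeric
cDNA contains both molecules' sequences, and complementarity between them
is a thermodynamic property assessed later, not an alignment criterion.
No reverse-complement mapping is performed. All internal coordinates are
0-based half-open; every CSV report uses 1-based inclusive coordinates
and says so in its column names.

Three stringencies are provided, reflecting the spectrum used in
published CLASH reanalyses (an intact-guide/perfect-match search, a
scored single-interpretation search, and an exhaustive
all-interpretations search):

* **strict** requires a full-length, error-free copy of a regulatory
  reference at the 5' or 3' end of the read, and the *entire* remaining
  sequence (at least `min_fragment_len` nt) to match some target
  reference exactly. No gap or junction overlap is tolerated. Both
  orientations (regulatory-first and target-first) are searched, since
  ligation produces chimeras in both orders; each candidate records which
  one it is.
* **scored** aligns the read locally against every reference (match +1,
  mismatch -2, gap open 5, gap extend 2, applied as `open + L * extend`
  for a length-L gap), tolerating short indels, keeps hits scoring above
  `0.8 * min_fragment_len` and spanning at least `min_fragment_len` read
  bases, pairs regulatory and target hits whose read spans overlap by at
  most `max_overlap` (default 4) and are separated by at most
  `max_gap_between` (default 4), and returns the single interpretation
  with the highest combined score (sum of alignment scores minus the
  overlap). Ties break lexicographically by (regulatory name, target
  name), then orientation and spans, so results are reproducible.
* **exhaustive** (the default) reports *all* interpretations: every
  qualifying fragment pair, with at most `max_hits_per_fragment`
  (default 10) hits per side, sorted by descending combined score. One
  read may legitimately support several interactions here; the per-read
  report preserves the read-to-interpretation mapping so support is never
  silently double-counted.

Exact matching is seed-and-extend over a complete k-mer index (k = 12 by
default; k never exceeds `min_fragment_len`, so no match of qualifying
length can be missed - a fact the test suite verifies against a
brute-force diagonal-scan oracle on hundreds of random instances).
`min_fragment_len` defaults to 16 nt, long enough that chance exact
matches against transcriptome-scale references are rare.

One design point deserves explanation. The exhaustive candidate pool is
defined as the union of alignment-derived pairs, exact maximal-match
pairs, *and* the strict-mode interpretations, deduplicated; the scored
mode picks the argmax of that same pool. This makes the stringency
nesting - strict results are a subset of exhaustive results, and the
scored pick is an element of them - a structural property rather than a
statistical one. Without the union, a best-local alignment can extend a
fragment across the ligation junction by one or two chance-matching
bases, yielding spans that differ from the strict interpretation of the
same read; the extra interpretations are genuine (exhaustive means
exhaustive) and cost only deduplication.

## The duplex energy model

Each candidate's regulatory and target fragment sequences are folded
against each other by a dynamic program over *intermolecular* pairings
only: pairs ascend along one sequence and descend along the other
(antiparallel), with no pseudoknots and no intramolecular structure of
either monomer. The energy of a structure is

$$\Delta G = \Delta G_{init} + \sum_{\text{stacks}} \Delta G_{stack}
  + \sum_{\text{loops}} \Delta G_{loop} + \Delta G_{\text{terminal}}$$

with nearest-neighbor stacking over all Watson-Crick and GU-wobble
dinucleotide steps, affine bulge and internal-loop penalties
(`open + per_nt * length`), a duplex initiation penalty, and a terminal
penalty for AU/GU closing pairs at either end. The parameter table ships
as `inst/extdata/rna_duplex_params.tsv` (kcal/mol at 37 C): Watson-Crick
stacks use the standard Turner-style values, while GU stacks and loop
terms are package defaults chosen to preserve the established qualitative
ordering (GC-rich stacks most stabilizing; the tandem GG/UU wobble
destabilizing). A custom table can be substituted via the
`energy_params` option; loading validates completeness, the rotational
symmetry that makes `duplex_fold(a, b)` and `duplex_fold(b, a)` agree,
and that the GC/GC stack is the most stabilizing entry.

Because no accessibility or intramolecular term is included, these
energies are hybridization-only and are *not* numerically comparable to
tools that include target-structure corrections; they are used exactly as
the reports use them - to rank candidate interactions, where lower dG
means more favorable. Structures that cannot reach dG <= 0 are reported
as "no stable duplex" and carry dG = 0 in the tables so that means and
rankings remain well defined.

Numerical choices: energies are compared with a 1e-7 tolerance inside the
DP; ties prefer structures with more pairs, then the leftmost
alternative, making the reported structure deterministic. Loop sides are
capped at 30 unpaired bases (`max_loop`), the usual window for duplex
scanners; for the fragment lengths this pipeline folds (<= 70 nt) the cap
is rarely binding. The DP is exact: on all sequence pairs up to length 6
it reproduces the minimum over an explicit enumeration of every valid
pairing, a check the acceptance suite runs on 200 random pairs, both with
the shipped initiation penalty and with a zero-initiation variant so that
the structural optimum (not merely the stability verdict) is exercised.

## Aggregation and reports

Candidates are grouped by (regulatory, target). Within a pair, candidate
target spans overlapping by at least 1 nt merge into one *site* (abutting
spans stay separate); the merge threshold is the simplest reproducible
clustering and is deliberately conservative. A site's read count sums the
collapsed counts of its distinct supporting reads; its reported span
covers the merged members, and its energy and diagram come from the
lowest-dG member. In strict and scored modes each read contributes at
most one interpretation, so summed interaction read counts exactly equal
the number of reads classified chimeric - an invariant the acceptance
suite checks. In exhaustive mode a multi-mapping read counts once per
interpretation, each row carrying its read id; the headline interaction
count counts each interpretation once.

Three browse views are exported: by regulatory RNA (number of distinct
targets), by target (unique chimeras and distinct regulatory partners),
and by pair (site-level, ranked by read count with lower dG breaking
ties, or by energy with higher count breaking ties). Optional region
annotation labels each site by the region (e.g. 5UTR/CDS/3UTR) containing
the majority of its target span, with exact ties going to the
downstream-most region; transcripts absent from the table yield
"unannotated". Region tables load from TSV (1-based inclusive) or BED4
(0-based half-open, converted on load). The region summary reports raw
site counts per label - the classical 3'UTR enrichment of animal miRNA
sites shows up as a count excess, and no statistical test is attached.

Every run also writes a parameters table (every setting used, verbatim)
and a counts table (input reads, reads and unique reads after trimming,
chimeric reads, interactions). All outputs are byte-deterministic for
identical inputs and settings.

## The synthetic-data generator

`generate_references` and `generate_library` emulate the library
structure: each read is `adapter5 + barcode/UMI + insert + adapter3`,
where a chimeric insert joins the full regulatory sequence to a target
fragment in either order (30% target-first by default). Defaults describe
a small but realistic experiment: 20 regulatory RNAs of 19-31 nt, 20
targets of 200-1500 nt, each target carrying one planted site that is the
exact reverse complement of its partner regulatory RNA, a 6-nt UMI, a
standard 3' sequencing adaptor, and a 0.5% per-base substitution error
rate (errored bases drop to Q20, everything else Q40). Targets pair 1:1
with regulatory RNAs so planted fragments are unique; recycling partners
(`n_target > n_regulatory`) or `decoy_multimap` (a 20-mer copied into two
targets) deliberately create multi-mapping ambiguity. Random-ligation
decoy chimeras (`n_decoy_reads`) take their target fragment at a random,
non-complementary position and are flagged in the manifest, providing
the negative control against which the energy ordering of true chimeras
is measured. Background reads split 50/50 between single-reference
fragments and uniform random sequence, exercising both non-chimeric
pathways.

UMIs are sampled *without replacement* from the 4^N barcode space, so
every molecule is distinguishable and ground-truth accounting by read id
survives collapsing. The substitution-only error model (no indels) keeps
strict-mode recovery provable at error rate 0; an indel-free model is
also what the strict search assumes. The generator is fully deterministic
under its seed (Mersenne-Twister with fixed sample semantics, pinned
explicitly so libraries reproduce across R versions).

What the simulator does *not* emulate - position-dependent Illumina error
profiles, PCR-family structure beyond identical copies, expression-
weighted target abundance, partial or truncated guide fragments -
bounds what passing tests show: they demonstrate correctness of the
algorithms under the stated read model, not performance on any particular
biological library.

## Problem sizes and runtime

The test and acceptance workloads use libraries of 35-500 reads against
20+20 references, 500 random instances for the exact-search oracle, 200
short pairs for the duplex enumeration oracle, and five seeds for the
stochastic energy-ordering check; the full suite runs in about two
minutes on one core. These sizes were chosen so every check re-runs
comfortably while still exercising multi-read aggregation, multimapping
and both chimera orientations.

## Known limitations

* Single-end reads only; no SAM/BAM or genome-coordinate (spliced)
  mapping - references are transcript sequences.
* Quality encoding is fixed to Sanger+33; +64 data must be re-encoded.
* The energy model reports hybridization-only energies (no accessibility,
  ensemble or temperature dependence); values are rankings, not
  predictions of measured free energies.
* Strict mode requires the intact regulatory sequence; guides shortened
  by trimming or degradation fall through to the scored/exhaustive modes.
* The scored mode's combined score is this package's definition
  (alignment score sum minus junction overlap); it is recorded in the
  parameters table for transparency.
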