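---
title: "Ortholog profiling and NHD-based model-organism ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog profiling and NHD-based model-organism ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthorank)
```

## The problem and the model

A model organism is useful for a given biological process only to the
extent that the set of proteins executing that process is shared. This
package quantifies that sharing: it compares a reference proteome against
many target organisms, decides for every reference protein whether each
organism carries an ortholog, only more distant homologs, or nothing
detectable, and then summarizes the result per biological process or
pathway as a distance between binary protein-presence vectors. Organisms
with small distances for a process are the ones for which the reference
is a credible model of that process.

The unit of input is a pairwise alignment hit (one HSP): e-value, percent
identity, percent similarity ("positives"), alignment length, 1-based
alignment coordinates on both sequences, and both sequence lengths. Any
aligner that emits the 12-column tabular dialect (`qseqid sseqid evalue
pident ppos length qstart qend sstart send qlen slen`) can feed the
pipeline; nothing in the method depends on BLAST itself.

## Classification rules

Hits above the collection cutoff (e-value $10^{-10}$, inclusive) are
never considered. Among collected hits:

* **ortholog candidate**: the alignment spans more than 85% of either
  sequence (ungapped aligned residues over full length) **and** either
  the e-value is below $10^{-36}$ or the identity exceeds 30%;
* **homolog**: every other collected hit.

Three deliberate reading decisions are baked in:

* *Strict boundaries.* "Below", "higher than" and "over" are strict
  inequalities, so a hit at e-value exactly $10^{-36}$, identity exactly
  30% or span exactly 0.85 is a homolog; the collection cutoff
  $\le 10^{-10}$ is inclusive. Tests pin all four boundaries.
* *The rule gap.* A pair with identity above 30% but span at or below
  85% satisfies neither rule read literally. Since the pipeline
  partitions all collected pairs into exactly two bins, such pairs are
  homologs. This is the only consistent two-bin completion.
* *"Either sequence".* Span is evaluated on the query and on the target
  independently; covering 85% of either one suffices.

Multiple HSPs per protein pair are collapsed to the single best HSP
(smallest e-value; ties by longest alignment, then smallest target start)
before classification — per-pair thresholds make HSP stitching
unnecessary, and the best HSP is a conservative summary.

## The composite orthology score

When several proteins of one organism are candidates for the same
reference protein, the ortholog is the candidate maximizing

$$F = F_1 + F_2 - F_3, \qquad
  F_1 = \tfrac{1}{2}\left(\tfrac{S}{100} + \tfrac{I}{100}\right), \qquad
  F_2 = \tfrac{AL'}{PL}, \qquad
  F_3 = \tfrac{G_1}{L_1} + \tfrac{G_2}{L_2},$$

with $S$/$I$ percent similarity/identity, $AL'$ the ungapped aligned
query residues, $PL = L_1$ the query length, $G_1$/$G_2$ the gap counts
in the aligned query/target rows and $L_2$ the target length. These
algebraic forms are this package's choice: the constraints they must
satisfy — $F_1, F_2 \in [0,1]$, $F_3 \ge 0$ vanishing only without gaps,
$F \le 2$ with the maximum at a full-length gapless identical alignment,
monotone in the obvious directions — admit more than one formula, and the
simplest forms meeting all of them were adopted. The whole formula set
lives behind the single `fscore()` interface so an alternative scoring
(e.g. a logarithmic gap penalty, which would let $F$ diverge to
$-\infty$) can be swapped without touching classification. Remaining
candidates become in-paralogs of the chosen ortholog. Ties in $F$ are
broken by smaller e-value, larger identity, then lexicographic target
identifier, making runs reproducible; ties are measure-zero for real
alignment statistics.

The reference organism is never compared against itself; self-hits are
excluded by construction of the organism panel.

## From calls to distances

Every (protein, organism) cell carries exactly one of three statuses —
ortholog found / homolog only / absent — and absence is always explicit,
so status counts partition the proteins × organisms grid. The presence
matrix has one row per organism plus an all-ones reference row and one
0/1 column per reference protein (1 = the organism contributes a
sequence to that protein's ortholog cluster; a mode switch also counts
homolog-only cells, for homolog-level analyses). In-paralogs never add
extra presence: presence is binary per cluster.

For a functional term, comparison vectors are laid over the term's
**superset**: the sorted union of the reference's annotated members and
an optional extension listing members known only from other organisms.
The extension is what makes the comparison two-sided — without it, an
organism whose pathway proteins are a strict superset of the reference's
would look identical to it. The reference's own vector is 1 exactly at
its annotated members, so extension positions count against any organism
that also lacks them but never against the reference artificially.

The Hamming distance is the count of disagreeing positions; the
normalized form divides by the per-term maximum across all organisms in
the run, giving NHD ∈ [0, 1] with 0 = identical protein set and 1 = the
most different set observed for that term. A run-level global maximum is
available behind a flag but per-term normalization is the default, since
it is the definition of the metric. Terms on which every organism ties
the reference have a zero denominator; they are flagged degenerate and
reported with NHD 0 rather than dropped, so matrices stay aligned across
namespaces. "Overall NHD", used to order heat-map rows, is the mean NHD
across terms (reference first, ties by identifier); hierarchical
clustering of rows would be a presentation choice, not part of the
metric, and is intentionally not the default.

## Annotation handling

Annotations arrive as flat protein → term maps (TSV, or GAF 2.x for GO
namespaces). Flat GO-slim style terms are assumed: no ontology-graph
propagation is performed. GAF qualifiers are ignored except `NOT`, which
drops the association; evidence codes are not filtered, matching the use
of curated slim annotations. Proteins without any term in a namespace go
into an `UNANNOTATED` pseudo-term — real proteomes leave most proteins
without a curated pathway, and keeping them in an explicit bucket both
documents that and keeps them out of per-pathway distance matrices. A
`min_genes` filter (default 1) excludes small terms; setting it to 5
reproduces a "more than 4 genes" validation filter.

## The synthetic fixture generator

The simulator emulates every input format the pipeline consumes, with
ground truth known by construction. Its defaults are the package's
standard study conditions: 20 pathways × 25 genes (a 500-protein
reference), 20 organisms on an ortholog-retention gradient of 0.9 / 0.7
/ 0.5 / 0.3 with five replicate organisms per level, and a 0.5
probability that a lost ortholog remains detectable as a homolog. Ten
percent of proteins are left without a KEGG annotation, mirroring the
fact that curated pathways cover only part of any proteome. Sequence
content is random filler: classification consumes alignment statistics,
so statistics are sampled directly from parameter boxes ("regimes")
placed strictly inside the classification regions — ortholog hits at
e ≤ 10⁻⁴⁰, identity ≥ 40%, span ≥ 0.90; homolog hits at e ∈
[10⁻³⁰, 10⁻¹²], identity ≤ 25%, span ≤ 0.80 on both sequences. A
corner-enumeration check (`regime_check()`) verifies at configuration
time that every box classifies uniformly, and the ortholog box is split
into a primary band and an in-paralog band whose composite scores cannot
overlap, so the intended ortholog always wins selection. Statuses are
drawn independently per (protein, organism); there is no shared
phylogeny, no correlated loss, and no realistic e-value distribution.
Passing end-to-end tests therefore demonstrates the mechanics of
classification, scoring and the distance metric — not robustness to real
evolutionary signal, boundary-hugging alignments, or annotation error.

## Numerical and degenerate-input choices

* An e-value printed as `0.0` is accepted and compares below every
  positive threshold.
* Gap counts are derived from coordinates
  (`gaps = aln_len − (end − start + 1)`), which is authoritative even
  when a table carries a `gapopen` column, and doubles as a row validity
  check (negative derived gaps are a parse error with a line number).
* Empty hit tables are legitimate (an organism with no collected hits);
  empty FASTA or annotation files are errors.
* Zero-length sequences are rejected before scoring.
* Superset order is pure lexicographic on identifiers, identical across
  platforms and runs.

## Problem sizes and verification

The test suite verifies the classification rules against an
independently coded restatement on 10,000 random hits, the score bounds
on sweeps of up to 100,000 records, the Hamming distance against a
position-wise count on 1,000 random vector pairs, and the full pipeline
against simulator ground truth (100% status and ortholog-identity
agreement) plus retention recovery within three binomial standard errors
and rank recovery (Spearman |ρ| ≥ 0.95) under the standard study
conditions above. These sizes were chosen to exercise the full parameter
space while keeping the suite quick to run; all are generated in code at
test time.

## Known limitations

* Orthology is unidirectional from the reference proteome; no
  reciprocal-best-hit or tree-aware reconciliation is attempted, so
  lineage-specific duplications in the target appear as in-paralogs of
  whichever candidate scores best.
* NHD carries no phylogenetic correction and no significance test;
  it is a descriptive ranking metric.
* The published supersets of real pathway databases (e.g. pathways
  extended with all possible EC numbers) are not recoverable from the
  reference annotation alone; the `extensions` mechanism accepts them
  when available but cannot invent them.
* Heat-map color semantics are qualitative: green for low distance
  through red for complete absence of the term's protein set.
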