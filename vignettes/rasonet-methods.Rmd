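---
title: "Methods: RASopathy interactome and phosphoproteomics harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RASopathy interactome and phosphoproteomics harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasonet)
```

## The scientific problem

RASopathies are developmental syndromes caused by germline mutations in
genes of the RAS/MAPK signalling pathway (Noonan syndrome and its
variants, neurofibromatosis type 1, Costello and cardiofaciocutaneous
syndromes, and related disorders). Because the causative proteins sit in
one signalling cascade, their protein–protein association neighborhoods
overlap heavily, and the downstream consequence of a pathogenic variant
is remodeling of the phosphoproteome. `rasonet` implements, as an
offline and fully testable pipeline, the standard in-silico workflow for
this family of diseases:

1. grow an **interactome** from a curated seed panel of causative
   proteins over a confidence-scored association network;
2. quantify **overlap** between the seeds' neighborhoods, their pairwise
   intersections, per-syndrome partitions, and degree-based **hubs**;
3. **harmonize** heterogeneous phosphosite measurements (different
   organisms, assays and studies) onto human sequence coordinates and
   assemble a site-by-syndrome **dysregulation matrix** with cluster
   labels;
4. census the catalogued phosphosites of the seed proteins by evidence
   throughput class; and
5. test annotation sets for **over-representation** among dysregulated
   phosphoproteins.

No live database access is performed anywhere: association tables,
sequences, ortholog pairs, catalogs and annotation sets are read from
files, and a synthetic-data generator produces inputs with known ground
truth.

## Interactome model and parameters

An association network is an undirected graph whose edges carry a
confidence in [0, 1]. Input tables in the STRING protein-links dialect
use permille integers (0–1000); the reader detects this and rescales, so
0.700 — the conventional "high confidence" STRING cutoff and the
package default `min_confidence` — corresponds to a combined score of
700. Duplicate undirected rows collapse to the maximum confidence;
self-loops are dropped with a warning. Protein identity is the
accession throughout; gene symbols are display-only, and display groups
on the panel (a RAS node standing for HRAS/KRAS/NRAS, an RRAS node for
RRAS/RRAS2/MRAS, MEK1/2 for the two MAP2K paralogs) are expanded to
member accessions at load time so analyses always run on members.

For each seed the neighbor set is its direct partners at or above the
cutoff (the seed itself excluded; other seeds count as partners).
The interactome records both the partner total *with* duplicates and
the deduplicated union — the two totals a practitioner reports when the
same partner is reached from several seeds. Per-seed overlap is
`100 * |N(s) ∩ ∪_{t≠s} N(t)| / |N(s)|`: membership in the union of the
*other* seeds' neighbor sets, not direct seed–seed edges, which is the
reading under which a seed whose every partner is reachable from
another seed overlaps fully. The summary "mean overlap" is the
unweighted mean of per-seed percentages over seeds with at least one
partner.

Hubs are nodes whose degree strictly exceeds `multiplier × mean degree`
(default multiplier 4), with the mean taken as 2E/V over the whole
analyzed network *including* degree-0 nodes. The hub search is run on
the subnetwork induced on the interactome (union plus seeds) at the
same confidence cutoff. Ties in hub and shared-pair rankings are broken
lexicographically by accession so output is deterministic.

The syndrome partition assigns to each syndrome the union of its seeds'
neighbor sets plus the seeds, then intersects with the union of all
other syndromes' sets. Because a protein can belong to several
syndrome sets, percentages are ambiguous in base; both are emitted
(share of the per-syndrome listing total, and share of the unique
protein count) and the caller chooses.

## Phosphosite harmonization

Phosphosite measurements arrive as one record per (protein, site,
syndrome, study): quantitative fold changes from MS screens, or
direction-only immunoblot calls. Fold changes are assumed normalized to
total protein abundance per condition
(`normalize_fold_change()` implements the ratio-of-ratios
`(pᵈ/tᵈ)/(pᶜ/tᶜ)` for sources that report raw abundances).

**Cross-species mapping.** Records from model organisms (mouse, rat,
monkey, zebrafish) are paired with their human ortholog through an
explicit ortholog table — no homology search is performed — and the
site coordinate is transferred by global Needleman–Wunsch alignment
(BLOSUM62, gap opening 10, gap extension 0.5, end gaps penalized). The
human residue aligned opposite the source site must be a
phospho-acceptor: an identical residue is the normal case, a
conservative S/T exchange is accepted with a flag, and a site aligned
to a gap or a non-acceptor is recorded as unmapped with its reason
rather than raising an error. No alignment tool or parameter set is
canonical for this task; the choice here is the standard deterministic
one and is pinned by oracle tests (identity and prefix-shift laws, and
planted-indel recovery in the generator). Positions are 1-based on the
sequence as given; no isoform arithmetic is attempted.

**Thresholding.** A record is upregulated when its fold change is at or
above the threshold (default 1.5) and downregulated at or below the
reciprocal 1/1.5 ≈ 0.667 — symmetric on the log scale, both boundaries
inclusive, so a study reporting exactly 1.5-fold is kept. A
quantitative value inside the band is *reported unchanged*: measured,
but not altered — a state deliberately kept distinct from missing data
and rendered `0*` in exports. Qualitative records pass through on their
stated direction and never enter the numeric matrix; they feed the
direction tallies, which are therefore emitted in two variants
(quantitative-only and including qualitative calls).

**Matrix and clusters.** Matrix rows are human sites labelled
`PROTEIN:SITE`; repeated quantitative measurements of the same site and
syndrome by different studies become separate rows with prime tags
(`'`, `''`, …) recomputed after mapping so the same human site reached
through different organisms is tagged consistently. Comparing the NS
and NSML columns, each dysregulated row is labelled `a` (up in both),
`b` (down in both), `c` (dysregulated in NS only — NSML missing *or*
reported-unchanged), `d` (NSML only), or `discordant` (opposite
directions, the PTPN11-Y62-like case) — discordance is kept as an
explicit fifth category rather than forced into the four concordant
clusters. Undefined phosphosites (known phosphorylation, position not
determined, as happens with commercial phospho-stains) are carried with
a missing position, excluded from mapping and matrix, and counted in
the qualitative tallies.

## Census and enrichment

The phosphosite census counts distinct catalogued sites per panel
protein — site identity is (residue, position), however many references
support it — and sums supporting references by throughput class (LTP:
targeted assays; HTP: MS screening). Whether a published split counts
references or site-reference pairs is often ambiguous, so both tallies
are emitted. Proteins at or above 20 sites (configurable) are flagged
as the heavily phosphorylated subgroup and their summed site count
reported. The bubble table lists one row per (syndrome, protein) panel
assignment, repeating multi-syndrome proteins with the same count.

Over-representation uses the one-sided exact hypergeometric tail
P(X ≥ k) per annotation term, Benjamini–Hochberg correction across all
tested terms (no hierarchy-aware correction — a flat FDR cutoff,
default 0.01), and a default background equal to the union of all
annotation members since no reference background ships offline. Terms
with fewer than two in-background members are untestable and skipped.
Exact database term lists from any given annotation release are out of
scope; the test is generic over GMT input.

## The synthetic-data generator

The generator exists so that every stage can be validated against
known ground truth. Its defaults emulate the study conditions: 27 seed
proteins over a ~500-protein pool with 35–45 high-confidence partners
each, a communal pool (fraction 0.3 of each neighbor set) that is the
only *systematic* source of shared partners, three planted hubs topped
up to degree 80, 1800 background edges among non-seed interactome
members (these set the mean degree the 4× hub cutoff is measured
against while leaving seed degrees below it), and 300 sub-cutoff decoy
edges that must be filtered out. The phospho plan plants, per
syndrome, NS 40 up / 13 down, NSML 55 up / 20 down, NF1 6 up / 2 down
quantitative sites (mirroring the relative scale of published
per-syndrome counts), a few qualitative calls and replicate
re-measurements, and cross-syndrome structure (2 sites up in both NS
and NSML, 2 down in both, 1 discordant, 1 up-in-NS/unchanged-in-NSML).
Measurements are attributed to human, mouse or zebrafish models;
non-human coordinates live on ortholog sequences derived from the
human ones by substitutions (rates 0.08 and 0.15; replacements never
create an acceptor residue, and planted sites are never touched) and
1–2 short indels placed at least 6 residues from any planted site, so
alignment-based mapping must recover the planted human coordinate
exactly.

All randomness flows from one integer seed through an isolated RNG
(the global stream is saved and restored); confidences are rounded to
3 decimals so files round-trip exactly through the permille dialect.
The truth record stores each seed's neighbor set, all pairwise
intersection sizes, the realized hub list (planted hubs are validated
to exceed the realized cutoff strictly — generation fails loudly
otherwise), every planted human site coordinate, and the expected
downstream tallies.

What the generator does *not* emulate: scale-free degree
distributions, correlated evidence channels, MS detection bias,
isoform-level coordinate offsets, and noisy or ambiguous ortholog
pairings. Passing recovery tests therefore demonstrates correctness of
the bookkeeping and the coordinate transfer under clean conditions,
not robustness to curation noise in real compilations.

## Numerical and degenerate-input choices

* Confidence is stored as a fraction; permille is an input dialect
  only. Score-dialect auto-detection calls a file permille when all
  scores are whole-numbered and any exceeds 1.
* A seed absent from the network (and from extra sources) gets an
  empty neighbor set with a warning, not an error; overlap on a seed
  with zero partners is reported missing and excluded from the mean.
* Overlap requires ≥ 2 seeds; hub detection refuses an empty network;
  the enrichment query must be non-empty and contained in the
  background (offenders are listed).
* Duplicate matrix cells (same row label, syndrome and study) keep the
  first value with a warning.
* `threshold ≤ 1` and non-positive abundances/fold changes are
  rejected at the door, with the offending row named where possible.

## Problem sizes used by the tests

Module tests run on toy instances (≤ 50 nodes, N ≤ 30) where naive
loop/set/summation oracles are fast; the pipeline and acceptance tests
run the generator at its default 27-seed configuration, with 20
replicate studies for parameter recovery, which completes in a couple
of minutes on a single core. `scripts/acceptance.R` reports recovery
rates over 10 replicate studies plus single-study summary statistics.

## Known limitations

* Real association snapshots and supplementary study tables are not
  bundled; analyses of published data require the user to supply those
  files, and exact published counts depend on the database release
  they were drawn from.
* Site mapping assumes the catalogued position refers to the supplied
  sequence; isoform or signal-peptide offsets must be resolved
  upstream.
* The dysregulation matrix treats studies as exchangeable replicates;
  no meta-analytic weighting or significance testing of individual
  fold changes is attempted (the upstream screens rarely report
  per-site statistics).
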