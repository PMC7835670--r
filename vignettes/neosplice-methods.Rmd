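---
title: "Models and methods behind neosplice"
author: "neosplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosplice)
```

# Scope

`neosplice` implements an end-to-end discovery cascade for splice-derived
immunotherapy targets in tumors: Bayesian percent-spliced-in (PSI)
quantification of local splice variations (LSVs) from junction-count
tables, differential splicing, a tumor-specific "neojunction" filter,
projection of junctions onto cell-surface protein topology (CAR-target
nomination), junction-spanning peptide derivation with decoy-estimated FDR
confirmation against a peptide database, a single-cell specificity screen,
HLA class-I neoantigen filtering through a pluggable binding predictor,
and RNA-binding-protein motif scanning. Because every biological
conclusion of such a cascade depends on patient cohorts and external
databases that cannot ship with a package, the package is built around a
synthetic-cohort generator with planted ground truth: every stage is
exercised, and every test is a recovery or oracle-equivalence check
against that truth.

# The PSI model

An LSV is a reference exon together with two or more competing junctions
sharing its donor (source LSV) or acceptor (target LSV). For junction
reads $r_1,\dots,r_k$ in one sample, the posterior over the selection
frequencies $\psi$ is Dirichlet:

$$\psi \mid r \sim \mathrm{Dir}(\alpha_1 + r_1, \dots, \alpha_k + r_k),
\qquad \alpha_j = 1/k ,$$

with the symmetric $1/k$ prior chosen as uninformative. Expectations are
the closed-form posterior means $E(\psi_j) = (\alpha_j + r_j)/\sum_i
(\alpha_i + r_i)$; 95% credible intervals and the binned posterior come
from the Beta marginal $\mathrm{Beta}(\alpha_j + r_j, \sum_{i \ne j}
(\alpha_i + r_i))$. An LSV is quantifiable in a sample when its total
reads exceed `min_reads_lsv` (default 10); de novo (unannotated)
junctions are kept only above `min_denovo_reads` (5) total reads; a
group is quantifiable when more than `min_experiments_fraction` (0.5) of
its samples are. The `prior_min_reads_junction` threshold (20) is
recorded in `quant_thresholds()` for completeness but feeds no empirical
prior here: read evidence arrives as total junction counts, not
per-position alignments, so position-level bootstrapping and GC
correction have no input to act on and the statistical contract (a
posterior over PSI with credible intervals) is preserved without them.

Group pooling averages the per-sample binned posteriors (arithmetic mean
of quantifiable samples, renormalised). The pooling rule is a design
choice; averaging treats each sample as an equally weighted draw from the
group and keeps multi-modality visible instead of collapsing it into a
single pseudo-count update.

## Differential splicing

For two groups, the distribution of $\Delta\psi = \psi_a - \psi_b$ is the
cross-correlation of the two binned posteriors under an independence
assumption. Two numerical choices matter:

* **Bin count.** Binned posteriors use $B = 80$ equal bins on $[0,1]$
  (configurable via `quant_thresholds(n_bins=)`). With 40 bins the
  convolution can disagree with exact Monte-Carlo sampling of the two
  posteriors by up to ~0.015 in $P(|\Delta\psi| > 0.1)$ for diffuse
  low-count posteriors; 80 bins keeps the worst disagreement under 0.005,
  which the oracle-equivalence tests then hold to a 0.01 tolerance.
* **Within-bin kernel.** Mass in a bin pair is not treated as a point at
  the bin-center difference but spread as the difference of two
  within-bin uniforms — a mean-zero triangular kernel of half-width one
  bin. This removes the quantisation of the decision boundary
  $|\Delta\psi| > 0.1$ at bin edges; $E(\Delta\psi)$ is unchanged because
  the kernel is mean-zero.

A junction is differentially spliced when $|E(\Delta\psi)| > 0.1$ with at
least 95% posterior mass on $|\Delta\psi| > 0.1$.

## The tumor-specific filter

A neojunction passes when (1) it has **exactly zero** supporting reads in
every normal sample, and (2) the pooled tumor posterior puts at least 95%
mass on $\psi > 0.1$. Criterion (1) is the only observable event
compatible with "PSI = 0 in all normals" with certainty, and it is
enforced as a hard structural check, never a statistical one: a single
normal read vetoes the call regardless of tumor evidence. Criterion (2)
defaults to the pooled-group interpretation; `mode = "per-sample"`
instead requires a majority of quantifiable tumor samples to satisfy the
tail criterion individually, since the source analyses do not pin down
which of the two was used. A junction that belongs to both a source and
a target LSV is called on its best evidence and reported at both
granularities.

# Coordinates, protein projection and windows

All internal coordinates are 0-based half-open; GFF3 I/O converts to and
from 1-based inclusive at the boundary. Junctions are keyed
`contig:donor-acceptor:strand` with the excised intron as `[donor,
acceptor)` and `donor < acceptor` regardless of strand.

Each gene's representative transcript is the one with the longest
annotated CDS. A junction's protein locus is the residue whose codon
contains the first coding base on the acceptor (3') side of the junction
in transcript orientation — the junction alters the protein from that
residue onward, which is what matters for epitopes. Junctions landing
upstream/downstream of the CDS map to UTR5/UTR3; transcripts without CDS
give `noncoding`. Domain labels come from interval containment in the
surface-protein topology table; when donor and acceptor flank different
domains, the acceptor-side residue alone decides. In region
classification (`classify_region`), exonic bases of non-coding
transcripts are counted as `intron` (non-coding gene body), since the
five-class scheme (CDS, UTR5, UTR3, intron, intergenic) has no separate
non-coding-exon class.

Junction windows are "symmetrically centered" in spliced (mRNA) space —
up to `flank` bases on each side of the splice in coding orientation,
with any sequence between donor and acceptor excised — not in genomic
space, because a junction-spanning peptide must cross the splice and a
genomic window would include intron. Defaults: 24 nt per side (48-nt
windows) for peptide derivation, 25 per side (50-nt) for neoantigen
enumeration, 300 per side (600-nt) for single-cell references. Truncation
at transcript ends is recorded, and the junction sits at `midpoint =
actual_left`.

Peptides come from all three reading frames, split at stop codons, and
only fragments whose codon span covers the midpoint are kept (stop-codon
handling is truncation, the simplest rule consistent with ribosome
behaviour). Mass-spectrometry search is out of scope; confirmation is
exact peptide matching (equality or substring of a database entry) with
reversed-peptide decoys and the decision rule FDR $\le 0.05$ estimated as
decoy hits over target hits. Palindromic peptides get a seeded shuffle so
no decoy equals its target.

# Single-cell screen

Reads are matched to 600-nt junction references by exact substring
search in both orientations, counted only when the match covers the
junction midpoint with at least `min_overhang = 10` nt on each side, and
assigned to at most one junction (longest minimal overhang, then
lexicographic id). Exact matching replaces an aligner deliberately: the
synthetic reads are error-free, and what the screen needs to establish is
junction-spanning evidence; the matcher sits behind a small interface so
an external aligner could be substituted for error-prone data.
Neoplastic specificity requires at least one neoplastic cell (stem +
differentiated) expressing the junction and **zero** glia, immune or
endothelial cells — again an absolute veto. The minimum neoplastic-cell
count is a config knob (default 1) because the source analyses state no
threshold. Stem enrichment is the ratio of per-type expression fractions,
with `Inf` when only stem-like cells express and `NA` when neither
compartment does.

# Neoantigen filtering

Candidates are all junction-spanning, stop-free 8–11-mers from the three
frames of the 50-nt window. Binding prediction sits behind a one-function
interface (`function(peptides, allele) -> scores`); the default is a
deterministic, stateless mock with allele-specific position weights, so
tests never depend on an external tool, and a real predictor can be
plugged in unchanged. Percent rank compares a score to a seeded
length-matched background drawn with natural amino-acid frequencies:
$100 \cdot \#\{\text{background} \ge \text{score}\} / \text{size}$,
strong binders at rank < 0.5. The background defaults to 10,000 peptides
per (allele, length) — rank is distributional, so the desk-scale
background estimates the same quantile as the full-scale 400,000 set
with sampling error ~0.07 rank points at the 0.5% quantile; the size is
a parameter for anyone wanting the full-scale set. Proteasomal cleavage
modeling is reduced to k-mer enumeration.

# Motif scanning

PWMs arrive as JASPAR-like 4-row count tables and are scanned as log2
odds against the background, ambiguous bases contributing zero. The hit
threshold defaults to 80% of the maximal achievable score because the
original database thresholds are not reproducible outside it. The
scanned sequence universe defaults to the spliced representative
transcript plus 250 nt of each intron end (intronic binding sites are
reported in this field), with a whole-pre-mRNA mode as the alternative;
each scanned segment is genomically contiguous so hits map exactly back
to genomic coordinates for BED output. Exon-level enrichment is hits/kb
in the exon versus the whole gene span.

# The synthetic cohort

The generator is first-class, tested code, and its defaults are the
study conditions for every recovery test: 20 genes (one planted event
each: 70% cassette exon, 15% alternative 5', 15% alternative 3'), 10
tumor + 10 normal samples, mean LSV coverage 50 (Poisson), and a
five-type single-cell compartment (stem/differentiated neoplastic, glia,
immune, endothelial) of 270 cells. Between-sample PSI heterogeneity is
Beta-distributed around the group truth with concentration 50 — the
generative model is a package choice (none is stated for the real
cohorts) picked to give realistic overdispersion for the
credible-interval calibration tests. Tumor-only events have alternative-
junction PSI drawn in [0.3, 0.6] in tumors and exactly 0 in normals, so
zero normal reads hold by construction; shared events draw PSI in
[0.2, 0.8], a quarter of them with a planted 0.15–0.3 between-group
shift. CDS validity (length divisible by 3, start/stop codons, no
internal stops) holds by codon-level construction, and excision-boundary
bases are planted to be discriminating, so that any junction-crossing
k-mer — even with a single-base overhang — cannot re-occur in the
reference isoform; this is what makes the junction-span guarantee
testable at the nucleotide level.

What the generator does **not** emulate: sequencing errors and base
qualities, per-position read evidence, GC bias, UMIs and ambient RNA in
the single-cell data, tryptic-digest peptide detectability, and real
protein topology (the three-segment domain partition is a toy). Passing
tests therefore demonstrate the correctness of the statistical machinery
and the filter cascade under clean evidence, not robustness to real-data
noise; the absolute-veto filters in particular are exactly as brittle to
contaminating reads on real data as they are strict here.

# Problem sizes and reproducibility

All randomness flows from a single integer seed per config; generators
derive stage-specific sub-seeds from it, and two runs with the same
config are byte-identical. The bundled analyses and checks use
desk-scale sizes chosen to keep a laptop run comfortable: 1000 simulated
LSVs for CI calibration (coverage 100), 50 posterior pairs against a
$10^6$-draw Monte-Carlo sampler for the dPSI oracle, 100 genes / 200
competing junctions with 20 planted events for the recovery check, and
500 single-cell reads against 50 references for the matcher-oracle
equivalence. The acceptance script (`scripts/acceptance.R`) recomputes
all of these from scratch at any seed.

# Known limitations

* Intron retention is classified only when junctions are supplied
  pre-called as such; no retention detection from intronic coverage.
* The tumor-side 95% criterion is pooled-group by default; per-sample
  mode exists but the two can disagree near the threshold.
* The mock predictor's scores are arbitrary (deterministic hash); only
  rank-based behaviour is meaningful.
* Multi-gene contigs, overlapping genes and paralogs are outside the
  generator's world, so projection ambiguity across genes is untested.
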