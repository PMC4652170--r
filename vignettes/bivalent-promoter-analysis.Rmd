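---
title: "Consensus classification of bivalent promoters: models and methods"
author: "bivalscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus classification of bivalent promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bivalscan)
```

## The problem

In embryonic stem (ES) cells many developmental regulators carry a
*bivalent* chromatin signature: the activating H3K4me3 and the repressive
H3K27me3 histone modifications are present simultaneously at the same
promoter, which is thought to keep the gene poised for either activation
or silencing during differentiation. Individual ChIP-seq experiments
disagree substantially on which promoters are bivalent, mostly because
H3K27me3 — a broad, diffuse mark — is detected much less reproducibly
than the sharp H3K4me3 peaks. `bivalscan` implements a meta-analysis
strategy: call a per-sample chromatin state for every promoter in every
available H3K4me3/H3K27me3 sample pair, and keep only states seen in a
clear super-majority of samples.

## The consensus model

For each promoter (a strand-aware window from 1,000 bp upstream to
2,000 bp downstream of a TSS) and each sample pair, the state is

| H3K4me3 peak | H3K27me3 peak | state     |
|--------------|---------------|-----------|
| yes          | yes           | BIVALENT  |
| yes          | no            | ACTIVE    |
| no           | yes           | REPRESSED |
| no           | no            | LATENT    |

where "peak" means at least 1 bp of a called peak overlaps the window
(half-open coordinates; no minimum-fraction rule). A promoter is assigned
the high-confidence class `HC_<STATE>` when that state occurs in
**strictly more than 70%** of the samples — the smallest qualifying count
is `floor(0.7 n) + 1`, i.e. 8 of 11 or 6 of 8 samples — and is
`UNCLASSIFIED` otherwise. Because the threshold exceeds 50%, at most one
state can qualify, so the class is unique. With per-sample H3K27me3
detection probability *p* on a truly bivalent promoter (and reliable
H3K4me3), HC-bivalent recall is the binomial tail
*P*(Bin(*n*, *p*) ≥ *k*); at *n* = 8, *p* = 0.8, *k* = 6 this is 0.797,
which the acceptance suite checks by simulation.

Supporting analyses mirror the figures such a study reports: detection
curves (promoters showing a state in ≥ *n* samples), per-sample QC
(state counts, cross-sample mean/SD/relative SD, Pearson correlation
with read depth), the overlap of each sample's top-scoring H3K27me3
promoters with the HC set, and the within-promoter co-location of the
two marks' peaks.

## Tunable parameters

* `upstream`/`downstream` (bp, default 1000/2000): promoter window; the
  minus-strand window mirrors the plus strand in transcript-relative
  coordinates.
* `fraction` (default 0.7): consensus super-majority, strict inequality.
* CpG profile: `span` 5000 bp each side, `bin` 100 bp, so 100 bins; the
  read-density matrices use the same grid so displays can be aligned.
* Motif profile: `span` 2000, `bin` 50, both strands.
* Enrichment: one-sided upper-tail hypergeometric test; the universe
  defaults to all classified promoters including `UNCLASSIFIED`
  (overridable); no multiple-testing correction by default, matching the
  raw-p / alpha = 1e-3 convention of the source analyses.
* `low_expression_threshold` = 4 FPKM; "non-expressing" in a single cell
  means FPKM exactly 0.

## CpG density

The CpG observed/expected ratio follows Gardiner-Garden & Frommer:
`(N_CpG * L) / (N_C * N_G)` over a window of length `L`, defined as 0
when the window has no C or no G; `N` bases never match. Profiles tile
±5 kb around the TSS into independent 100-bp bins (a CG dinucleotide
straddling a bin boundary belongs to neither bin); minus-strand windows
are reverse-complemented first so bin 1 is always 5'-most. CpG islands
are consumed as a BED track, not re-derived.

## Read density and clustering

Density matrices count fragments overlapping each bin (a fragment
spanning two bins counts in both — robust for broad H3K27me3 domains),
scaled to reads per million. For clustering, each factor's matrix is
scaled to unit maximum before concatenation so deep-coverage factors do
not dominate; rows are clustered with k-means (k = 4 by default, ≥ 10
restarts, fixed seed) and cluster labels are renumbered by descending
mean of the first factor's block, which makes the output labelling
invariant to the seed for well-separated data. Display transforms use
log10(x + 1).

## Cross-species comparison

Consensus classes of two species are joined over a one-to-one ortholog
table (duplicated genes are an input error). The overlap matrix counts
(class A, class B) pairs with both sides classified; row-normalized
percentages are reported in both directions, and the reverse direction
is exactly the transpose. Divergence groups default to I = both
bivalent, II = both active, III = both latent, IV = bivalent in A /
active in B, and V = its mirror; the source analysis labels IV
explicitly but never defines V, so V is a declared assumption and the
group map is user-overridable. Region-level liftOver comparison is out
of scope; the gene-level ortholog join is the primary analysis.

## Motif statistics

The motif module scans fixed k-mers (the bivalent-associated `TCCCC`
and active-associated `CGGAA`) rather than performing de-novo discovery
(an external-tool task). The containing fraction counts sequences with
at least one match of the motif or its reverse complement (overlaps
allowed); the positional profile assigns each fully-contained occurrence
to the bin of its 5'-most base in transcript coordinates. On i.i.d.
uniform sequence the expected per-position rate is 2·(1/4)^k for a
non-palindromic k-mer, which the tests use as an analytic control.

## What the synthetic generator emulates — and what it does not

`simulate_reference()` and friends build a fully self-contained study:

* 2,000 promoters on loci spaced 12 kb apart (class mix: 25% bivalent,
  35% active, 10% repressed, 30% latent — repressed is kept well above
  its tiny real-world share so per-class statistics are testable);
* CpG-suppressed background (~40% GC, obs/exp ≈ 0.2, via 80% C→T
  deamination of CG dinucleotides) with a 1.5-kb CpG-rich core (60% GC)
  and a CpG-boosted 300-bp centre at bivalent and active promoters,
  recorded in the CGI track;
* `TCCCC` planted in 50% of bivalent and `CGGAA` in 40% of active
  promoters at offsets within ±250 bp of the TSS. Both motifs and their
  reverse complements are first scrubbed from every promoter
  neighbourhood, because at promoter-window length a 5-mer occurs by
  chance in essentially every window — without scrubbing, the containing
  fraction would measure sequence composition, not planting;
* per-sample peak detection: H3K4me3 at 0.97 per sample (stable, a few
  percent relative SD in marked-promoter counts), H3K27me3 drawn per
  sample from U(0.4, 0.95) (>20% relative SD, mirroring the strong
  cross-sample variability of the real compendium), 1% spurious peaks;
* fragment libraries of 1e5-4e5 fragments (desk scale; real studies run
  14-100M reads) with 70% of fragments placed where marks truly are —
  peak-calling misses are a detection phenomenon, not an absence of
  signal — and per-promoter log-normal strengths making H3K27me3
  stronger at bivalent than repressed promoters and H3K4me3 stronger at
  active than bivalent ones;
* class-dependent expression (log-normal medians 30/3/1/0.3 FPKM with
  class-dependent zero inflation and single-cell dropout over 63 cells)
  and 30 perturbation gene lists drawn with odds 8 for bivalent genes;
* a second species with per-class conservation rates (bivalent 0.66,
  the headline mouse-to-human rate), generated at the class level with a
  one-to-one ortholog table.

A green test on this world establishes that the *pipeline machinery*
recovers what was planted at the stated noise; it does not establish
biological claims. The generator has no sequencing errors, no antibody
or culture-condition batch structure, no input-control subtraction, no
chromatin domains beyond promoter-centred peaks, and the second species
shares no genome — only classes. Note also that at the stated H3K27me3
detection variability the strict >70% rule recovers only a minority of
truly bivalent promoters as HC; that low recall (with high precision) is
a property of the consensus design itself, visible in the real study's
small HC set, and the end-to-end checks are written against it.

## Numerical choices and degenerate inputs

* `consensus_threshold()` guards the `fraction * n` product with a 1e-9
  tolerance so binary floating point cannot shift a strict cutoff.
* The hypergeometric tail is computed in log space (`phyper(...,
  log.p = TRUE)`) and exponentiated, stable down to the 1/184,756-scale
  values the tests pin.
* Zero denominators (no C or G in a window, empty classes, zero-mean QC
  counts) yield 0 or NA markers rather than errors; empty clusters
  return zero profiles with a flag; ties in top-signal ranking break by
  promoter id ascending, making the selection deterministic.
* All randomness flows from one master seed through a documented
  `sub_seed(seed, i)` derivation, so every artefact is byte-reproducible.

## Known limitations

Peak calling, read alignment, BAM/bigWig input, GO-term databases,
de-novo motif discovery, liftOver-based region mapping and
batch-effect correction are out of scope by design; peak BEDs, CGI
tracks, expression tables and ortholog tables are inputs. Gene-level
results collapse per-TSS calls by gene id; with multiple TSSs per gene
the caller chooses the collapse rule.
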