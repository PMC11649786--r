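---
title: "epimeta: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epimeta: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimeta)
```

# Scope

`epimeta` is the downstream analysis layer for studies that combine m⁶A
RIP-seq peak calls with ChIP-seq co-binding, differential expression, mRNA
stability and drug-combination readouts. Everything upstream — read QC,
alignment, transcript quantification, DESeq2 model fitting, MACS2 peak
calling, motif discovery — is out of scope by design: those tools' *output
files* are this package's inputs. This vignette documents the models the
package implements, the conventions it fixes where the field leaves room,
and what its synthetic-data generators do and do not emulate.

# Coordinate conventions

All internal coordinates are 0-based half-open. GTF is read as 1-based
inclusive and converted on entry; BED, narrowPeak and bedGraph are read as
0-based half-open natively. The TSS of a transcript is the 5′-most exon
base in transcript orientation (so a minus-strand transcript spanning
`[100, 200)` has its TSS at 199). Signed TSS distances are positive
downstream in transcript orientation.

# The metagene model

Positional m⁶A analysis uses a composite axis built from five segments:
a fixed-width upstream flank, the 5′UTR, the CDS, the 3′UTR, and a
fixed-width downstream flank. Region bins (default 100 per region) are
*scaled*: each transcript's region is linearly stretched onto its bin band,
so transcripts of different lengths contribute comparably. Flank bins are
*fixed-width* (default 20 bp per bin over 1 kb, i.e. 50 bins per flank):
a flank is the same physical distance on every gene, and scaling it would
distort distances near the TSS/TES. The literature rarely states either
choice; both bin counts and flank geometry are arguments of
`build_metagene_model()`.

One representative transcript per gene is used: the isoform with the
largest *summed exon length* (not genomic span), with ties broken by the
lexicographically smallest transcript id so the choice is independent of
annotation order.

Projection rules (`project_to_metagene()`):

* exonic positions map through the spliced transcript offset into the
  matching region band;
* intronic positions return `NA` rather than snapping to the nearest
  region — peak-based density concerns mature-transcript features, and
  silently relocating intronic signal would bias the CDS band;
* positions in the flanks map through fixed-width bins; anything beyond
  returns `NA`;
* transcripts with no annotated UTRs are projected as all-body (CDS band):
  the package stays usable on partial annotations, and zero-width UTR
  bands would otherwise swallow positions;
* minus-strand transcripts are mirrored, so coordinate 0 is always the
  5′-distal flank edge.

# Relative density

`relative_density()` implements the count-proportional-area contract: with
conditions `c` having `n_c` projected peaks, condition `c`'s density
integrates to `n_c / Σ n_c` and the conditions together integrate to 1.
This makes the *areas* of two curves directly comparable as peak-count
shares — the property that makes cross-condition metagene figures readable.
The smoother is deliberately decoupled from the contract: histogram mode is
exact bin counting (used by the tests as the direct-count oracle), kernel
mode is a Gaussian kernel (default bandwidth 5 bins) with reflection at the
domain edges; areas are rescaled exactly after smoothing, so they depend
only on counts, never on bandwidth.

# Spike-in scaling

Scaling factors are computed within batch as
`factor_s = min(batch counts) / count_s`, so the batch-minimum sample has
factor exactly 1 and every other sample is scaled *down*. The convention
mirrors downsampling of alignment files: no sample is ever upsampled, which
would manufacture reads. A zero spike count is a hard error naming the
sample — there is no defensible factor for it. `apply_scaling()` offers a
deterministic `expected` mode (multiplication) and a seeded `thinning` mode
(each count unit kept with probability `factor`), which emulates read-level
downsampling on count signal; thinning's expectation equals the
deterministic mode, and the tests verify this by averaging seeded
replicates.

# Peak annotation

Peaks are anchored at their summit when present (the natural MACS2 anchor)
and at their midpoint otherwise. The anchor receives exactly one feature
class by precedence `promoter > utr5 > utr3 > cds_exon > intron > tts >
intergenic`, evaluated over all representative transcripts; the assigned
gene is the one with the nearest TSS, with intergenic anchors farther than
100 kb from every TSS left unassigned. The promoter and TTS windows default
to ±1 kb, consistent with TSS-profile windows used in this literature.

Two consequences worth knowing:

* with symmetric ±1 kb windows the promoter class *shadows* short 5′UTRs
  (precedence puts promoter first, and a 150 bp 5′UTR lies wholly within
  +1 kb of the TSS). This matches the behaviour of feature-precedence
  annotators; when the downstream shadow is unwanted, pass an asymmetric
  window such as `promoter_window = c(1000, 0)` — the planted-label
  recovery test does exactly that;
* the nearest-TSS gene can in principle differ from the feature-owning
  gene in dense annotations; the synthetic genome keeps ≥ 6 kb gaps so the
  two coincide and planted truth is exactly recoverable.

# Peak-count permutation test

The test of a total peak-count difference between two conditions uses
statistic `|nA − nB|` and a null that reassigns each of the `nA + nB`
pooled peaks to a condition with probability ½ (the source literature
names only the test and its 1000 permutations, not the scheme; this label
reshuffle is the simplest exchangeable null for a count difference and is
swappable). The p-value uses the add-one correction
`(1 + #{perm ≥ obs}) / (n_perm + 1)`, so it is never zero and is valid for
any seed. Under matched Poisson generators this null is exact, which is
what the calibration criterion exploits.

# DEG filtering and set intersections

`filter_deg()` applies the standard thresholds strictly: `|log2FC| > 1`
*and* adjusted `p < 0.01`, matching the printed inequality symbols; a gene
sitting exactly on a threshold is excluded. `intersect_gene_sets()` returns
all `2^n − 1` exclusive Venn regions, which sum to the union — the
bookkeeping the tests verify against direct membership counting.

# ChIP integration

`overlap_peak_sets()` partitions two peak sets by any-overlap (≥ 1 bp under
half-open semantics by default): each peak counts once even if it overlaps
several partners — the convention of common ChIP overlap tooling — and
co-bound regions are the merged unions of overlapping pairs, making the
partition symmetric. `signal_matrix()` computes exact interval-integral
mean coverage per bin from bedGraph semantics (absent positions read 0),
reverses minus-strand rows, and reports the column-mean profile; defaults
are ±1 kb / 10 bp bins for TSS profiles and ±4 kb / 50 bp bins for
peak-centered heatmap matrices.

`compare_peak_burden()` reports group medians of peaks-per-gene and a
two-sided Mann–Whitney p-value (normal approximation, tie-corrected). The
source literature names a matched-pairs signed-rank test for two groups of
*unequal* sizes, which cannot be paired as printed; the unpaired rank test
is the defensible reading and is documented as such.

# Decay and drug-response models

mRNA stability series are fit to `N(t) = N₀·e^(−kt)` by least squares,
initialized from the log-linear regression slope and polished by
quasi-Newton steps; `t½ = ln 2 / k`. The constant 0.693 often printed for
ln 2 is a rounding — outputs reported to three decimals match it. Fitted
`k ≤ 0` is flagged (`decaying = FALSE`, `t½ = ∞`) rather than erroring:
non-decaying genes are a result, not a failure.

Monotherapies are fit with a four-parameter log-logistic curve
`y(d) = floor + (ceiling − floor) / (1 + (midpoint/d)^slope)`, monotone and
invertible on `(floor, ceiling)` for positive slope. The Loewe reference
for a combination cell `(d₁, d₂)` solves `d₁/D₁(y) + d₂/D₂(y) = 1` by
bisection (tolerance 1e-6, ≤ 200 iterations) on the overlap of the two
curves' response ranges; cells with no root there are undefined and
excluded. The overall synergy score is the mean per-cell excess
(observed − expected) over *defined combination cells only* — monotherapy
rows and columns are excluded, since they are inputs to the reference, and
the cited web tool's exact cell weighting is version-dependent, so the
simplest defensible mean is used. Viability inputs are converted to
inhibition (`100 − viability`) explicitly in the reader. Classification
uses the printed thresholds (> 10 synergistic, < −10 antagonistic,
otherwise additive).

# The synthetic world

The generators produce every input format with sidecar ground truth so the
pipeline is testable offline. The stated world:

* **genome** — two 1.2 Mb chromosomes, 200 genes on both strands, each
  with a 100–200 bp 5′UTR, a 500–1500 bp CDS over 1–3 exons
  (150–400 bp introns) and a 200–600 bp 3′UTR; 1–3 isoforms per gene with
  the full model flagged longest. Inter-gene gaps are 6–9 kb. A 2 × 1 Mb
  layout was considered but cannot hold 200 genes *and* gaps wide enough
  to make nearest-TSS assignment unambiguous, so the chromosomes are 20%
  longer — exact planted-truth recovery was judged more valuable than the
  rounder genome size;
* **peaks** — anchors drawn per region-bias weights (default 55% 3′UTR,
  matching the 3′UTR enrichment typical of m⁶A), widths 100–300 bp,
  summit at the anchor, per-condition counts 1000 and 700 (unequal, in the
  spirit of the real conditions' differing totals, at desk scale);
* **ChIP** — zero-baseline Gaussian promoter bumps (σ = 150 bp, amplitude
  8–12) for two factors with a configurable co-binding fraction (default
  0.3) — high-SNR by construction so planted bound sets are exactly
  recoverable;
* **expression** — null `log2FC ~ N(0, 0.25)`, 10% DEGs shifted ±3, Wald
  p-values BH-adjusted;
* **decay** — `100·e^(−kt)` at 0/3/6 h (the real assay's time points) with
  5% multiplicative lognormal noise at t > 0, t = 0 pinned at 100%;
* **dose matrices** — built *under* Loewe additivity from two 4PL curves
  plus a planted uniform excess δ on combination cells (δ = 0 → exactly
  additive); noiseless by default, so classification tests are sharp.

What the generators do **not** emulate: read-level noise, sequence content,
overlapping genes, ambiguous isoform structure, background ChIP signal,
dispersed DE effect sizes, or plate noise in viability assays. A green test
therefore establishes algorithmic correctness on a well-posed world — not
robustness to every pathology of real sequencing data.

# Numerical notes

* Half-open interval logic everywhere: `[100,200)` and `[200,300)` do not
  overlap.
* Representative-transcript ties, Venn region order and generator output
  are all deterministic; every stochastic routine takes an explicit seed.
* The kernel density reflection avoids edge leakage of the metagene
  domain; areas are renormalized exactly after smoothing.
* 4PL fitting runs a bounded L-BFGS-B pass followed by Nelder-Mead and
  BFGS polish; on exact data parameters are recovered to ~1e-6, which the
  tests assert.
* The bisection bracket for the Loewe solve is shrunk inward by a 1e-9
  relative margin to keep the inverse curves finite at the endpoints.

# Known limitations

* Peak-based metagenes only; no read-coverage metagene mode.
* bedGraph only (no bigWig); tracks are held in memory.
* The Loewe scorer offers no Bliss/ZIP/HSA references and no bootstrap
  confidence intervals.
* Gene assignment by nearest TSS can misattribute features in gene-dense
  regions (see above); an assignment radius of 100 kb bounds, but does not
  remove, this.
* The decay model is single-phase; plateau or biphasic decay is out of
  scope.
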