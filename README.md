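# epimeta

Downstream analysis toolkit for studies that integrate m⁶A RIP-seq
(MeRIP-seq) with ChIP-seq, expression and drug-response data — the kind of
epitranscriptomic work done in stem-cell differentiation and neuroblastoma
models. The package takes the *outputs* of the standard primary pipeline
(called peaks, coverage tracks, DESeq2-style tables, spike-in counts,
time-course and viability readings) and provides the analysis layer on top:

- **Spike-in normalization** — per-batch scaling factors from exogenous
  (E. coli) spike-in read counts, `factor = min(batch)/count`, with
  deterministic scaling or seeded binomial thinning of count signal.
- **Transcript models & metagene axis** — GTF parsing, longest-isoform
  selection (maximal summed exon length), and a strand-aware composite
  coordinate system: 1 kb upstream flank (fixed 20 bp bins) / 5′UTR / CDS /
  3′UTR (100 scaled bins each) / 1 kb downstream flank.
- **Peak analytics** — BED/narrowPeak readers, summit-anchored annotation to
  `promoter > utr5 > utr3 > cds_exon > intron > tts > intergenic`,
  peaks-per-gene burdens, m⁶A-positive gene sets, a seeded permutation test
  for peak-count differences, DEG filtering at |log₂FC| > 1 and adjusted
  p < 0.01, and exclusive Venn-region cardinalities for gene-set overlaps.
- **Relative metagene density** — per-condition peak density over the
  metagene axis where each condition's area equals its share of the total
  projected-peak count and the areas sum to 1.
- **ChIP co-binding integration** — interval-overlap partitions (A-only /
  B-only / co-bound with merged regions), promoter-bound gene sets,
  Mann–Whitney peak-burden comparisons, and anchor-centered coverage signal
  matrices / mean profiles from bedGraph tracks.
- **Response models** — one-phase exponential decay fits
  (N(t) = N₀·e^(−kt), t½ = ln 2 / k) for actinomycin-D time courses, 4PL
  dose-response fits, and Loewe-additivity synergy scoring
  (d₁/D₁(y) + d₂/D₂(y) = 1; overall score > 10 synergistic, < −10
  antagonistic, otherwise additive).
- **Synthetic data with planted truth** — seeded generators for every input
  format (GTF, narrowPeak, bedGraph, TSV tables, dose matrices) so the whole
  pipeline is testable offline with known ground truth.

## Worked example

```r
library(epimeta)

cfg   <- sim_config(seed = 7)                 # toy genome, 200 genes, 3'UTR-biased peaks
ann   <- sim_annotation(cfg)
genes <- select_representative_transcripts(parse_annotation(ann$gtf))
mg    <- build_metagene_model()               # 50+100+100+100+50 = 400 bins

pr <- lapply(c("hESC", "tNCC"), function(cond) {
  ps <- sim_peakset(cfg, cond, genes)
  project_peak_set(read_peaks(ps$narrowpeak, "narrowPeak", cond), genes, mg)
})
names(pr) <- c("hESC", "tNCC")

profile <- relative_density(pr, mg)
profile
#> DensityProfile: 2 condition(s), 400 bins; hESC=1000 tNCC=700
density_areas(profile)
#>      hESC      tNCC
#> 0.5882353 0.4117647

permutation_test_counts(length(pr$hESC), length(pr$tNCC), n_perm = 1000, seed = 7)
#> peak-count difference: 300   p = 0.000999001

fit <- fit_decay(c(0, 3, 6), c(100, 54.9, 30.1))
sprintf("k = %.3f /h, t1/2 = %.3f h", fit$k, fit$t_half)
#> "k = 0.200 /h, t1/2 = 3.465 h"

dm <- sim_dose_matrix(cfg, delta = 15)        # planted +15-point synergy excess
fa <- fit_dose_response(dm$matrix$doses_a, dm$matrix$response[, 1])
fb <- fit_dose_response(dm$matrix$doses_b, dm$matrix$response[1, ])
synergy_score_and_classify(dm$matrix, loewe_reference(dm$matrix, fa, fb))
#> SynergyResult: overall score 15.00 (synergistic) over 25 combination cell(s)
```

Reading the numbers: the two conditions carry 1000 and 700 projected peaks,
so their density areas are forced to 1000/1700 ≈ 0.588 and 700/1700 ≈ 0.412
(count-proportional areas, totalling 1). The 300-peak difference is far
outside the pooled binomial null, so the seeded permutation test bottoms out
at its minimum achievable p of 1/1001. The decay series was generated with
k = 0.2 h⁻¹, recovered exactly, giving t½ = ln 2 / 0.2 ≈ 3.465 h. The dose
matrix was built under Loewe additivity plus a planted uniform +15-point
excess on the 25 combination cells, which the scorer recovers and classifies
as synergistic (> 10).

## Command line

```sh
Rscript exec/epimeta simulate --seed 7 --out simdata
Rscript exec/epimeta spikein  --counts simdata/spikes.tsv --out factors.tsv
Rscript exec/epimeta metagene --gtf simdata/annotation.gtf \
    --peaks simdata/peaks_hESC.narrowPeak:hESC,simdata/peaks_tNCC.narrowPeak:tNCC \
    --out profile.tsv
Rscript exec/epimeta permtest --n-a 600 --n-b 400 --n-perm 1000 --seed 1
Rscript exec/epimeta decay    --table simdata/decay.tsv
Rscript exec/epimeta synergy  --matrix simdata/dose_matrix.tsv
```

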