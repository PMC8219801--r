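# nascentUV

Downstream analysis of nascent-RNA sequencing (Bru-seq) time courses after
UVC irradiation, for studies of transcription repression and recovery after
DNA damage — e.g. asking whether a chromatin factor (a histone chaperone, a
transcription-coupled-repair factor) is required genome-wide for
transcription restart, and whether that requirement is confined to genes
that actually carry UV lesions.

## What it computes

**Quantification with biological scaling.** Gene-body abundance is
RPKM(g, s) = counts(g, s) / (len_kb(g) · libsize_M(s)), on the full
annotated gene body (nascent transcripts retain introns). Because
depth normalisation erases genome-wide shifts — and UV globally silences
transcription — every RPKM is multiplied by an externally measured
correction factor f(condition, timepoint) (e.g. mean EU incorporation per
nucleus relative to the unirradiated sample of the same condition,
f(c, 0) ≡ 1). Per-gene responses are then ratios to the unirradiated
baseline, r(g, c, t) = scaled(g, c, t) / scaled(g, c, 0), for genes with
baseline RPKM > 0.

**Classification.** In control conditions a gene is *UV-repressed* if
r(2.5 h) ≤ 1/2 and *UV-induced* if r(0.5 h) ≥ 2 (timepoints are midpoints
of a 30-min labelling pulse started 0, 2, 6, 24 h after UVC). Repression is
*fast* if already r(0.5 h) ≤ 1/2 (the cis signature of a lesion-blocked
gene), otherwise *slow* (trans repression). *Transcription recovery* is the
24.5 h level normalised to the same condition's baseline; with
ρ = recovery(knockdown)/recovery(control), a repressed gene is
**stimulated** by the knocked-down factor (requires it) if ρ ≤ 0.90,
**independent** if 0.90 < ρ < 1.10, **inhibited** if ρ ≥ 1.10. Genes are
partitioned by median length, median baseline RPKM and coding potential,
with cutoffs recomputed on each analysed set.

**Poisson lesion-load model.** At the reference dose of 10 J/m² UVC makes
about 1 lesion / 6 kb of double-stranded DNA, i.e. 1 / 12 kb on the
transcribed strand where lesions stall RNA polymerase II. With
λ(L) = L · (dose/10) / 12000, per-gene lesion counts are Poisson(λ), so
P(damaged) = 1 − e^(−λ); contrasting the mean predicted damaged fraction
with the observed stimulated fraction over short repressed genes asks
whether recovery control extends beyond damaged genes.

**Peaks and overlaps.** ChIP-seq peaks (kept at FDR < 1 and fold
enrichment > 10, both strict) are intersected with transcripts extended
5 kb upstream of the TSS (strand-aware, half-open coordinates); gene-list
overlaps are tested with the two-sided Fisher's exact test over the
analysed-gene universe.

**Synthetic cohorts with planted truth.** `cohort_config()` /
`simulate_uv_experiment()` generate gene cohorts (log-normal lengths and
baselines, Poisson-placed lesions, cis-fast vs trans-slow repression,
planted dependency classes, true scaling factors, Poisson counting noise)
so every stage can be validated by parameter recovery.

## Worked example

```r
library(nascentUV)

cfg   <- cohort_config(n_genes = 2000, seed = 42)   # defaults emulate a
sim   <- simulate_uv_experiment(cfg)                # 10 J/m2 Bru-seq course
peaks <- generate_peaks(sim$annotation, target_fraction = 0.62, seed = 42)
run   <- run_pipeline(sim, peaks = peaks)
run
```

```
UV-response run: 2000 genes, 2000 analysed (baseline RPKM > 0)
  repressed 1859 | induced 2 | unchanged 134 | excluded 5
  kinetics: 95.2% fast / 4.8% slow
  knockdown_A: stimulated 87.6% / independent 4.2% / inhibited 8.2% (n = 1858)
  shortest-quartile repressed genes (<= 26,741 bp): 70% predicted damaged vs 86% knockdown-dependent
  peak targets vs repressed: p = 0.324
```

Reading: of 2000 genes detectable before UV, 1859 lose ≥2-fold nascent
transcription by 2.5 h; 87.6% of them need the knocked-down factor to
recover by 24.5 h (the planted plan was 88 / 4.3 / 7.7%), and the
requirement exceeds the Poisson damage prediction on the shortest
repressed quartile. Five genes with a zero baseline replicate were
excluded, mirroring the complete-case rules used on real data. The damage
model itself:

```r
p <- lesion_params(dose = 10)
expected_lesions(48667, p)   # 4.0556 lesions on the transcribed strand
prob_damaged(48667, p)       # 0.983
```

`plot(run)` draws the repressed-gene recovery curves (mean ± sd), the
dependency pie and the predicted-vs-observed bar pair;
`write_run_report(run, dir)` writes the per-gene classification TSV, the
length-ranked heatmap matrix and a summary JSON. Real data enter through
`run_pipeline_files(counts, samples, factors, annotation, peaks)`; a thin
command-line wrapper lives in `inst/scripts/uv-pipeline.R`.

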