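---
title: "Methods: models, conventions and design choices in degrontx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in degrontx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degrontx)
```

# Scope

`degrontx` implements the quantitative core of an acute Pol II degradation
study: spike-in anchored normalization, a minimal negative-binomial test for
differential expression, coverage-derived transcription indices, pulse-chase
half-life estimation, and the gene-set definitions built on top of them.
This vignette is the package's own account of the science: the models, the
conventions, every tunable that matters, and the choices made where the
design was genuinely open.

# Coordinates and windows

All internal coordinates are **0-based half-open** (BED convention); GTF
input (1-based inclusive) is converted on ingest and converted back on
export, so the round trip is the identity. One arithmetic convention
everywhere eliminates off-by-one drift between modules.

Anchors are strand-aware: for a `+` gene TSS = `start`, TES = `end − 1`;
for a `-` gene TSS = `end − 1`, TES = `start` (forced by the half-open
convention: the last base of the interval). "Downstream" always means sense
orientation — decreasing genomic coordinate on the `-` strand.

The analysis windows, per gene:

| window | sense-orientation extent | used by |
|---|---|---|
| `tss` | −30 bp to +300 bp of the TSS | pausing index (numerator) |
| `body` | +300 bp of the TSS to the TES | pausing (denominator), elongation index, strand-specific counting |
| `pre_term` | the 2 kb ending at, and including, the TES | readthrough (denominator) |
| `term` | the 2 kb starting just past the TES | readthrough (numerator) |

Two bookkeeping choices here were open and are now fixed: the TES base is
counted once (in `pre_term`, not `term`), and both termination windows are
exactly 2000 bp — an inclusive-bracket reading would make the upstream
window 2001 bp, an asymmetry with nothing to support it. Genes of 330 bp or
less have no valid `tss`/`body` windows and are flagged `short_gene`;
windows reaching past a chromosome edge are clipped and flagged rather than
dropped (explicit over silent loss).

"Signal" in every index means the **mean per-base value** over the window,
not the sum: the ratio of means is invariant to the two windows' unequal
lengths, and for pausing/readthrough (numerator and denominator from the
same track) invariant to any multiplicative rescaling of the track.

The readthrough index defaults to each gene's **own sense strand** of a
stranded track pair — readthrough transcription continues on the template
the polymerase is already on. Track-level workflows sometimes score every
gene on the forward strand; `mode = "forward"` reproduces that. Neighbouring
genes are *not* masked out of the termination windows; the simulator
guarantees the layouts it produces cannot collide (see below), but on real
annotations closely spaced genes will contaminate each other's readthrough
windows, and users should filter such pairs.

# Spike-in normalization

Two estimators, matching the two data types:

* **Tracks** (`chip_scale_factors`): `s_j ∝ 1 / N_j^{spike}` where
  `N_j^{spike}` is the per-sample spike-in read count, rescaled so the
  geometric mean of `s_j` is 1. Only the proportionality is substantive; the
  geometric-mean-1 convention is symmetric and indifferent to how many
  conditions are compared. Whether `N^{spike}` is counted per mapped or per
  deduplicated read does not matter to the estimator, but the choice must be
  consistent across samples.
* **Counts** (`spikein_size_factors`): median-of-ratios restricted to
  spike-in genes, `s_j = median_g ( N_gj / geomean_{j'} N_{gj'} )`, the
  median taken in log space (the reference estimator's convention;
  identical except at even-count ties). Genes with a zero in any sample drop
  out of the geometric mean; with fewer than 5 usable genes the estimator
  falls back to total spike-in count ratios with a warning. Restricting to
  spike-in genes is the entire point: the factors are provably invariant to
  anything that happens to target genes.

`naive_size_factors` (all-gene median-of-ratios, or total counts) is
provided deliberately: under a regime where 80% of genes drop 5-fold, the
all-gene median tracks the repressed majority, the treated samples get
divided by ≈ 0.2, and truly unchanged genes surface as ≈ 5-fold "induced".
The package's tests assert this contrast directionally rather than assuming
it.

RPKM and TPM (`rpkm_tpm`) exclude spike-in genes from both the rows and the
per-sample denominators — spike-in abundance reflects the mixing ratio, not
the transcriptome.

# The differential-expression test

A deliberately minimal two-group NB Wald test (`nb_wald_test`), built for
transparent thresholding logic rather than bit-compatibility with a full GLM
framework:

1. normalized counts `q_gj = N_gj / s_j`;
2. group means `μ̂_C, μ̂_T` and a per-gene method-of-moments dispersion on
   the normalized scale, `α̂ = (v − μ̂)/μ̂²` pooled across the two groups by
   residual df and floored at `1e-8` (an optional `dispersion = "common"`
   mode uses the across-gene median — steadier on tiny toy matrices);
3. `log2FC = log2((μ̂_T + ½)/(μ̂_C + ½))` — pseudocount 0.5, no shrinkage;
4. delta-method standard error from `Var(μ̂) = (μ̂ + α̂ μ̂²)/n`;
5. two-sided p-value for `z = log2FC / SE` against a **t reference with
   `n_C + n_T − 2` df**, then BH adjustment.

The t reference is the one deliberate departure from a textbook Wald test:
with 2–3 replicates the dispersion estimate is noisy, a normal reference is
anticonservative (empirically ~0.12 at nominal 0.05 with 3 vs 3), and
referring the statistic to a t with the residual df is the standard
small-sample correction. The package's null-simulation test pins the
empirical size to the 0.03–0.07 band.

Working entirely on the normalized scale makes the test *exactly* invariant
to multiplying any sample's counts and its size factor by the same
constant — a property the tests assert to `1e-12`. The trade-off is that
shot noise is treated as `μ̂` on the normalized scale rather than rescaled
per sample; with size factors near 1 (the geometric-mean-1 conventions
above) the difference is negligible.

Calls (`call_de`) use the study's convention: `up` iff `log2FC ≥ 1` and
FDR < 0.05, `down` symmetrically, with an optional expression floor that
reroutes genes to `low_expr`. No multi-factor designs, no outlier handling,
no independent filtering — out of scope by design.

# Pulse-chase half-lives

The pipeline (`halflife_table`) is: optional spike-in size-factor division →
stable-transcript scaling → baseline expression filter → per-gene fit.

**Stable-transcript scaling.** The real experiment anchors between-sample
scale on the geometric mean of seven stable transcripts (ribosomal proteins
and Gapdh). Here `c_j = geomean_{g∈stable} TPM_gj / ref`, with `ref` the
same quantity geometric-averaged over the condition's timepoint-0 samples;
every value is divided by `c_j`. Stable genes with a non-positive value
anywhere are dropped with a warning (all dropped is an error). In the
noise-free limit the recovered `c_j` equal the simulated per-sample
distortions exactly — an algebraic identity the tests check numerically.

**Filter.** Genes are kept iff mean TPM across the baseline condition's
timepoint-0 samples is **strictly** greater than 0.2 — the threshold text
says "> 0.2", so a gene at exactly 0.2 drops. Filtered genes stay in the
output with flag `filtered_low_expr` and no estimate.

**Fit.** First-order decay, fitted log-linearly:
`log E(t) = log A − k t`, `t½ = ln 2 / k`. Log-linear least squares was
chosen over nonlinear fitting because the model class is not specified
beyond "first-order decay", the log-linear fit is closed-form and
deterministic, and it is exactly invariant to rescaling all values (only
the intercept shifts) — a config-gated nonlinear refinement was considered
and rejected as an unnecessary degree of freedom. Three choices were open
and are fixed as:

* zeros are **dropped**, not pseudocounted, before the log (pseudocounts
  bias `k` precisely where expression is low; the dropped count is
  recorded);
* replicate measurements at one timepoint are **averaged on the log scale**
  before fitting, so each timepoint carries equal leverage
  (`average_replicates = FALSE` fits all points);
* a fitted `k ≤ 1e-10 /h` is flagged `nondecaying` with `t½ = ∞` — the
  tolerance absorbs round-off on exactly flat series; fewer than
  `min_points = 3` usable timepoints flags `insufficient_points`.

With two conditions the paired table reports
`log2(t½ cond / t½ baseline)`, `NA` whenever either fit is missing or
infinite.

# Gene classification

* **Length classes**: Short iff `L ≤ 10 kb`, Medium iff `10 < L ≤ 75 kb`,
  Long iff `L > 75 kb`. The 10 kb boundary goes to Short ("0–10 kb" read as
  inclusive); one convention, stated and tested at both boundaries.
* **Degradation-upregulated genes**: called `up` in *both* degron
  constructs and max RPKM across samples > 1. Which sample the RPKM filter
  inspects was unspecified; the maximum is used because these genes are low
  at baseline by nature, so a baseline-only filter would contradict the
  set's intended size. The threshold and the choice are arguments.
* **Control genes**: `L < 10 kb` (strict), not histone, not upregulated.
  The histone list is caller-supplied — no annotation of histone genes is
  baked in; an empty list warns.
* **Peak-bound genes**: ≥ 1 bp overlap between a peak and the gene extended
  `promoter_upstream = 3000` bp upstream in sense orientation. The source
  convention says only "intersected"; 3 kb mirrors the ±3 kb TSS windows
  used for display, is configurable, and binding calls are provably
  monotone in the extension.

# The simulators

The synthetic-data module is first-class, tested code; its defaults *are*
the study conditions the package is validated under, and they are not
adjusted per test.

* **Annotation** (`simulate_annotation`): lognormal gene lengths (meanlog
  `log(8000)`, sdlog 1, clamped to 2.5–200 kb) spanning all three length
  classes; genes placed sequentially on toy chromosomes with a 5 kb
  intergenic gap. 2 kb would suffice to keep TES windows off neighbouring
  genes; 5 kb also keeps the simulated TSS bumps and post-TES tails of
  convergent neighbours from touching, so constructed indices are exact by
  layout. Packing into a fixed `chrom_length` that cannot fit is an error.
* **Counts** (`simulate_counts`): `N_gj ~ NB(μ = depth_j · a_g · f_g,
  variance μ + αμ²)` with lognormal relative abundances `a_g` (spike-in
  share 10%, mirroring a 10% spike-in cell mix), dispersion `α = 0.05`,
  depth 2 × 10⁶, 3 vs 3 replicates. Treated-condition effects `f_g`: 10% of
  target genes up 4-fold (`log2FC = 2`), 10% unchanged, 80% repressed
  5-fold; spike-in genes always `f = 1`. Treated libraries are *not*
  renormalized to constant depth — global repression genuinely shrinks
  them, which is the regime under study. A second construct reuses the
  truth assignment with fresh noise.
* **Pulse-chase** (`simulate_pulse_chase`): `E_g(t) = E_g(0) e^{−k_g t}`,
  half-lives log-uniform on 0.5–24 h, seven designated stable genes with
  `k = 0` drawn at high expression, timepoints 0/1/3/12 h, multiplicative
  lognormal noise (CV 0.1, mean 1), and per-sample scale distortions
  uniform on 0.7–1.3 (timepoint-0 samples undistorted, so recovered factors
  are directly comparable to truth). Lognormal noise preserves positivity
  and makes the CV directly configurable.
* **Tracks** (`simulate_tracks`): per gene, a TSS bump over −30..+300 bp at
  `PI_g · b_g`, a uniform body at `b_g`, and a post-TES tail over 2 kb at
  `RI_g · b_g`, in 10 bp bins with mean-1 lognormal noise (CV 0.1) — so the
  measured indices equal `PI_g`/`RI_g` exactly at zero noise and in
  expectation otherwise.

All randomness flows from one master seed through a fixed splitting scheme
(one derived sub-seed per simulator stage), so identical configurations are
byte-identical across runs — the pipeline's determinism check hashes every
output file of two independent runs.

**What the simulators do not emulate — and hence what passing tests do not
show about real data:** no read-level error, mappability, GC or positional
bias; no gene overlap, antisense transcription or multi-isoform structure
(gene-level records only; union-vs-canonical-transcript ambiguity is left
to the annotation supplier); dispersion shared across genes rather than
mean-dependent; pulse-chase decay exactly first-order with no labeling or
incorporation kinetics; track noise independent across bins. Recovery
results bound what the estimators can do under their own model, not their
robustness to violations of it.

# Problem sizes and runtime posture

The validation suite runs the study conditions at the sizes the recovery
statements are made about: 2 000 target + 200 spike-in genes (3 vs 3) for
the normalization contrast, 10⁴ genes for the null size check, 500 genes ×
4 timepoints for half-life recovery, 200 genes for index recovery, and the
full default pipeline twice for the determinism check. These sizes were
chosen so each claim rests on enough genes for a stable median while the
entire suite remains a desk-scale computation.

# Known limitations

* The DE test has no dispersion shrinkage across genes and no fold-change
  shrinkage; with < 3 replicates per group it refuses to run, and its
  per-gene dispersion estimates are noisy by construction (the t reference
  compensates for size, not for power).
* Readthrough windows are not masked against neighbouring genes on real
  annotations.
* Half-life fitting assumes a single first-order component; biphasic decay
  will fit an average `k` with inflated residuals (inspect `rmse_log`).
* BigWig is not read or written; bedGraph is the native track format.
* No batch correction, no multi-factor designs, no enrichment statistics —
  adjacent analyses, out of scope here.
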