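---
title: "Models and methods behind barseqnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barseqnoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqnoise)
```

# The measurement problem

In a pooled fitness competition, hundreds of uniquely DNA-barcoded microbial
lineages grow together through serial transfers, and the pool's barcode
composition is sequenced at several timepoints. A lineage's fitness `s` is
the log-linear rate of change of its frequency relative to a benchmark, per
transfer interval. Even at very high sequencing coverage such measurements
vary: between technical replicates, between replicate competitions, and most
of all between "batches" — sets of experiments run on different days, by
different hands, in subtly different environments. barseqnoise provides a
generative simulator of the entire measurement chain with ground truth
attached, plus the inference and diagnostic machinery to dissect where the
variation enters.

# The generative model

## Growth and bottlenecks

Published analyses of such experiments rarely specify a growth model, so the
package adopts the minimal one whose log-frequency-ratio slope equals `s` by
construction: per transfer interval, a deterministic relative-exponential
update

\[ f_i \leftarrow \frac{f_i e^{s_i}}{\sum_j f_j e^{s_j}} \]

followed by multinomial resampling of `bottleneck_size` cells (the transfer
bottleneck). `bottleneck_size = 0` is a sentinel selecting the deterministic
infinite-population mode, used by tests that need closed-form trajectories.
Timepoints are expressed in transfer intervals; a `generations_per_interval`
scalar rescales the fitness unit, defaulting to 1 because the number of
generations per transfer is an experiment-specific convention we leave to
the user.

## Batch and replicate environmental effects

Every batch draws a deviate `delta_b ~ N(0, sigma_batch)` and every replicate
within it `eps_r ~ N(0, sigma_rep)`; a lineage's effective fitness in that
vessel is

\[ s_{\mathrm{eff}} = s_i + g_i \,(\delta_b + \varepsilon_r), \]

with `g_i` a per-lineage environmental sensitivity (0 for references, 1 for
mutants by default). One shared deviate per vessel reproduces the signature
observation that adaptive lineages move up or down in fitness *together*
across replicates, so genotype *contrasts* are far more stable than genotype
means. Defaults are `sigma_batch = 0.1 > sigma_rep = 0.03`, putting batch
effects on the scale of the between-batch spread seen in multi-year pooled
competition studies and comfortably above replicate effects.

## The default pool

`lineage_pool()` emulates a pool of ~500 lineages: 40 neutral reference
lineages spiked in at 10% total frequency (benchmark coverage erodes as
adaptive mutants sweep, so references are spiked high), 21 strongly adaptive
lineages ("IRA1", `s = 0.7` per interval, i.e. roughly a doubling of
relative frequency), 13 intermediate ones ("GPB2", `s = 0.4`), and 426
near-neutral background lineages (`s ~ N(0, 0.05^2)`). Barcodes are random
26-nt sequences.

## Library preparation and sequencing

`simulate_sequencing()` models the two sampling layers of library prep: a
multinomial draw of `pcr_molecules_per_sample` template molecules (each
tagged with a uniform random 8-nt UMI; collisions are allowed, as real UMIs
collide), then `reads_per_sample` reads drawn uniformly over those
molecules, so PCR duplicates share a UMI. There is no base-call error model,
no quality scores, and no adapter structure — reads carry identifiers, not
error-prone sequence — because the phenomena under study are sampling and
index misassignment, not sequencing error.

## Index misassignment

The amplicon geometry is a homologous 167-bp middle region carrying the
barcode (centred by default; the true position within real constructs is not
documented, so it is a parameter), flanked by the two inline indices and two
constant 40-bp regions before the Illumina adapter indices. Two mechanisms
corrupt reads on the simulated patterned flow cell:

* **Template switching** (probability `p_template_switch` per read): the
  read becomes a chimera with a partner drawn uniformly from all reads on
  the lane (frequency-weighted, a flow-cell-level mechanism), with a
  breakpoint uniform over the 247-bp amplicon. A middle-region breakpoint
  (167/247 ≈ 67.6% of events) joins one parent's left-end indices to the
  other's right-end indices — the definitive cross-end signature. A flank
  breakpoint (≈ 32.4%) exchanges only the outer Illumina index on that side
  and is indistinguishable from an index hop. For middle breakpoints, the
  barcode travels with whichever parent owns its side of the breakpoint;
  the UMI rides the forward inline primer.
* **Index hopping** (probability `p_hop`): one Illumina index (N or S,
  uniform choice) is replaced by a uniform draw from the scheme's pool —
  occasionally redrawing the original index, which is then a hidden event.

An event is recorded as **hidden** when the resulting tuple is still a valid
sample tuple, i.e. when no index check could flag it. This covers
within-sample chimeras and same-index partners, and also swaps that land
exactly on another sample's tuple (silent misassignment under saturated or
combinatorial schemes) — the common thread is undetectability, which is
what the truth label exists to track.

# Index schemes and the swap classifier

Three scheme kinds are supported: combinatorial (free combinations, cheap,
undetectable swaps), unique dual (two dedicated primers per sample — 192
primers for 96 samples), and nested unique dual, where each inline F index
is exclusively paired with one Illumina N and each R with one S, so 12 F/N
pairings × 8 R/S pairings label 96 samples with 40 primers while keeping
single-swap detectability.

`classify_reads()` applies the category definitions in strict precedence:
unmatched pools → correct tuple → cross-end template switch → single swap
(Illumina vs inline by mismatched position) → double swap → unmatched.
Two deliberate resolutions where the definitions overlap:

* when a tuple is one mismatch away from different samples at different
  positions, Illumina-index explanations are preferred over inline ones
  (hops and flank switches, the plausible single-swap mechanisms, touch
  Illumina indices only);
* three or more mismatches are `unmatched` — only four misassignment
  categories are defined.

On nested schemes with once-used indices the categories are provably
disjoint; the test suite checks the vectorised classifier against a
brute-force oracle that enumerates all samples and chimera pairs, on every
scheme kind with up to 12 samples.

A consequence worth stating plainly: a nested scheme whose combination grid
is (nearly) saturated — e.g. 95 samples from 12 × 8 pairings — cannot detect
middle-region template switches at all, because the chimera of two valid
half-pairs is itself a valid sample. Detection of the template-switching
*mechanism* therefore requires a library in which each index is used only
once; detection *rates* are correspondingly underestimated when few samples
share a lane, since a partner from the same sample leaves no trace
(probability 1/8 with 8 samples vs 1/95 with 95). The package's
under-detection property test compares all-unique schemes at those two sizes
for exactly this reason.

# Fitness inference

Frequencies are regularised as `(count + pc) / (total + pc * n_barcodes)`
with pseudocount `pc = 0.5` per (barcode, timepoint), so zero-count
timepoints remain usable (affected lineages are flagged rather than
dropped). Estimates on lineages with all counts ≥ 50 move by far less than
1e-3 when the pseudocount varies in [0.1, 1].

**Reference mode** pools the raw counts of all reference barcodes into one
aggregate benchmark frequency — pooling maximises effective depth precisely
when the references are being diluted away — and fits an unweighted OLS
slope to `ln f_i(t) - ln f_ref(t)`. Standard errors come from the
regression residuals. With 5 timepoints the slope has 3 residual degrees of
freedom, so a ±2·SE interval has nominal coverage `P(|t_3| <= 2) ≈ 86%`,
not 95% — the test suite checks the achieved coverage against that
t-distribution value, and users averaging over few timepoints should use
t-quantiles, not 2, for intervals.

**Mean-fitness mode** serves pools without spiked-in references: initial
slopes of `ln f_i(t)` seed the estimates, the population mean fitness
`xbar(t) = sum_i f_i(t) s_i` is integrated (trapezoidally) and added back,
and the two steps are iterated to a fixed point satisfying
`sum_i f_i(t) s_i = xbar(t)`. One subtlety is intrinsic: frequencies from a
closed pool identify only fitness *differences* — adding a constant to all
`s_i` and to `xbar` changes nothing observable — so the iteration needs a
gauge. The package recentres each iteration so the frequency-weighted mean
of the estimates is zero (fitness relative to the population mean). All
meaningful quantities (pairwise differences, the offset against
reference-mode estimates) are gauge-invariant, and with the gauge fixed the
iteration converges immediately because the mean-fitness correction is
common to all lineages.

`fitness_fold_change()` implements the two-timepoint estimator used by deep
mutational scans; on noiseless data it equals the slope, on noisy data its
variance is larger than the multi-timepoint slope's, which the tests verify
by Monte Carlo.

# Noise decomposition

`replicate_r2()` scores technical replicate pairs as the squared Pearson
correlation of log10 pseudo-frequencies over the *union* of barcodes —
a barcode absent from one member is kept at pseudocount level, since
dropping it would bias reproducibility upward. (The transform is
configurable because published reproducibility figures rarely state it;
log10 is the default as the natural scale for frequencies spanning decades.)
Coverage classes split at mean reads per barcode 20 and 600, boundaries
inclusive on the moderate side.

`variance_decomposition()` collects descriptive standard deviations
(sample SD, n−1 throughout) in three nested categories:

* **within experiment** — across the lineages of one genotype group inside
  one vessel (≥ 2 members): pure sampling/technical noise;
* **across replicates** — per barcode across the replicates of one batch;
* **across batches** — per barcode across all replicates of all batches.

The two lineage-wise categories are restricted to barcodes observed in at
least two batches. This separates the pool lineages tracked across a whole
study from batch-specific spike-ins (engineered genotype sets present in a
single batch), which would otherwise contribute degenerate "across-batch"
observations; with that rule, a design of 28 replicates in 9 batches
carrying 21 + 13 pool lineages everywhere and two engineered sets in one
4-replicate batch yields exactly 36, 306, and 34 observations in the three
categories. Groups with fewer than 2 members are skipped and logged, and
whether single-replicate batches should contribute across-replicate SDs is
resolved the same way: they cannot (≥ 2 required).

`genotype_contrast()` computes the per-replicate difference of genotype
means — the statistic that cancels shared environmental shifts — alongside
the SD of each genotype's per-replicate medians for comparison.
`estimate_condition_effect()` contrasts two conditions with the naive
`sigma/sqrt(n)` standard error a replicate-count argument would quote, and
flags fully confounded designs (no batch contains both conditions), where
the batch effect is inseparable from the condition effect and that naive SE
overstates precision. `summarize_box()` uses type-7 (linear interpolation)
quantiles for hinges — the common boxplot convention, unstated in most
figure captions — whiskers at the most extreme values within 1.5 × IQR, and
notch half-width `1.58 * IQR / sqrt(n)`.

# The pipeline

`run_pipeline()` chains simulate → sequence → misassign → classify →
deduplicate → fit → decompose, treating each batch as one sequencing lane
(its replicate × timepoint samples share a scheme, and misassignment mixes
reads within the lane). Every stochastic stage derives its seed from the
single config seed, so a configuration hash plus seed identifies a run and
reruns are byte-identical. `preset_one_big_batch()` (4 replicates, one
batch) and `preset_nine_batches()` (28 replicates over 9 batches, 3 + 3 +
... + 4) mirror the two designs a noise study contrasts; both use
scaled-down pools (~95 lineages) and depths (5,000 reads/sample) chosen so a
full run stays interactive on one core.

# What the simulator does and does not show

Passing tests demonstrate that the inference and diagnostics behave
correctly *under the generative model*: multinomial sampling at every
physical bottleneck, additive shared environmental shifts, uniform
breakpoints, uniform partner choice, exact index identifiers. Real data add
ingredients deliberately out of scope — PCR jackpotting and amplification
bias, base-call errors in barcodes and indices, chimera formation biased by
local homology length, lineage-by-environment interactions richer than one
shared deviate, and sequencer-specific swap-rate structure. Conclusions
about mechanism detectability and estimator behaviour transfer; absolute
noise magnitudes do not.

Problem sizes in the test suite (full pool of 500 lineages at 10^5
reads/timepoint for recovery checks; 10–20 seed replicates for each
stochastic property; 10^5+ breakpoints for the geometry fractions) were
chosen as the smallest sizes at which the Monte-Carlo error of each checked
quantity is well below its assertion margin.
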