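---
title: "From patch-clamp sweeps to maturation biomarkers: the patchseqr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From patch-clamp sweeps to maturation biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchseqr)
library(dplyr)
```

## The problem

Cultured human neurons derived from pluripotent stem cells mature at very
different rates: within one dish some cells fire trains of sharp action
potentials while their neighbours are barely excitable. Patch-seq couples a
whole-cell patch-clamp recording of a neuron with RNA sequencing of that same
cell, so the electrophysiological maturity of each cell can be used as a
quantitative trait against which gene expression is analysed. `patchseqr`
implements that analysis end to end:

1. extract a nine-parameter electrophysiological phenotype per cell from raw
   current- and voltage-clamp sweeps;
2. collapse the phenotype into a single maturity axis (Dim1 of a PCA) and a
   three-level maturity grouping;
3. build a signed weighted co-expression network over all samples (neurons
   plus non-neuronal contrast samples) and detect gene modules, identifying
   the neuron-specific module;
4. correlate every gene with Dim1 to define maturation gene programs (a
   mature-enriched "magenta" cluster and an immature-enriched "green"
   cluster);
5. intersect the magenta cluster with the neuron-specific module and
   cross-reference an external maturity gene list to nominate candidate
   maturation biomarkers;
6. score gene sets by one-sided Fisher's exact tests.

A synthetic-data generator produces the whole study — maturity-graded voltage
sweeps and a structured expression matrix with planted gene programs — so the
pipeline can be validated against known ground truth without any download.

## Electrophysiological features

Six action-potential parameters are measured per cell, plus the sodium
current and the frequencies of spontaneous excitatory and inhibitory
postsynaptic currents (sEPSC/sIPSC):

| parameter | definition | units | maturation direction |
|---|---|---|---|
| threshold | membrane potential at AP onset (first dV/dt crossing) | mV | down (hyperpolarises) |
| rise time | onset to peak | ms | down |
| halfwidth | width at half threshold-to-peak amplitude | ms | down |
| amplitude | threshold to peak | mV | up |
| firing rate | maximal spike count over the 0.5 s pulse | Hz | up |
| Rin | voltage deflection over first current-step amplitude | MOhm | down |
| Na current | peak inward deflection on the ramp response | pA | up |
| sEPSC / sIPSC frequency | fast / slow-decay event rates at −70 mV | Hz | up (weakly) |

Numerical choices that matter:

* **Spike onset** is operationalised as dV/dt ≥ 10 mV/ms (configurable); the
  onset is the first sample of the last super-criterion run before the peak.
  A detection additionally requires a rise of ≥ 10 mV above the crossing
  voltage *and* a subsequent repolarisation of at least half that — a noisy
  charging membrane satisfies the slope criterion transiently but never the
  downstroke, so unexcitable cells yield no spurious spikes.
* **Which AP is measured**: the first spike of the rheobase sweep (lowest
  suprathreshold current step), where the waveform is least distorted by
  adaptation.
* **Half-amplitude crossings** are linearly interpolated between samples; at
  the 5 kHz acquisition rate a sample is 0.2 ms, which is coarser than the
  halfwidth differences of interest.
* **Rin** is measured as the mean deflection in a 0.2–0.45 s window after
  pulse onset on the first (hyperpolarising) step, late enough for a membrane
  with a time constant of tens of milliseconds to settle; the sign convention
  is magnitude over magnitude, so Rin is always positive.
* **ND (not detected)** is a first-class token: an unexcitable cell's AP
  parameters are `NA` in memory and the literal `"ND"` in CSV, never a
  silent zero.
* An optional zero-phase 2 kHz low-pass (matching a typical acquisition
  filter) can be applied before extraction; it is off by default because the
  synthetic traces are already band-limited.
* **PSC classification**: events are split by decay kinetics at a 10 ms time
  constant (fast ≈ excitatory, slow ≈ inhibitory at a −70 mV holding
  potential). This is a documented stand-in for an unknowable experimental
  discrimination; the boundary is a parameter.

## The maturity index

ND values are imputed before the PCA with a direction-aware rule: a
maturation-negative parameter (e.g. halfwidth) gets the column **maximum**, a
maturation-positive parameter (e.g. firing rate) the column **minimum**, so
unexcitable cells land at the immature extreme of every axis rather than in
the middle. The direction map defaults to the correlation structure of the
variable factor map (see below) and is user-overridable.

The PCA is computed on standardised columns (the correlation matrix) because
the parameters mix Hz, mV, MOhm and pA. Eigenvector signs being arbitrary,
Dim1 is oriented so that it **anti-correlates with firing rate**: larger
Dim1 = less mature. Cells are binned into three groups (matured, maturing,
immature) by a deterministic 1-D k-means on Dim1 — centers initialised at the
k quantile midpoints and iterated to convergence, so repeated runs agree;
massive ties fall back to a tertile split with a warning.

```{r maturity, eval = FALSE}
cohort <- simulate_cohort(n = 20, seed = 1)
params <- build_parameter_table(lapply(cohort$cells, function(x) x$sweeps))
mat <- maturity_index(params)
glance(mat)        # variance explained, Dim1-firing-rate correlation
autoplot(mat)      # cells along Dim1/Dim2, coloured by group
plot_variable_map(mat)
```

## The co-expression network

Genes expressed at ≥ 0.1 FPKM in at least one sample (an inclusive boundary,
applied on the raw FPKM scale) enter the network. Gene–gene Pearson
correlations are computed on log2(FPKM + 1) across **all** samples — neurons
and contrast — so the dominant axis of co-variation is neuron-ness, which is
what makes the neuron-specific module detectable.

* **Signed adjacency** `a = ((1 + r) / 2)^beta` preserves correlation sign:
  anti-correlated genes get weight 0, not weight 1.
* **Soft power** is the smallest exponent whose scale-free topology fit
  (R^2 of the log–log connectivity-distribution regression, sign-corrected)
  reaches 0.8 over the grid 1..20; if none qualifies, the argmax power is
  used with a warning. Data dominated by a two-class design (neurons versus
  blood) are genuinely not scale-free, so the fallback is the expected path
  there.
* **Topological overlap** rewards shared neighbourhoods; `1 - TOM` is the
  clustering distance for average-linkage hierarchical clustering.
* **Module detection** is a two-stage dynamic cut. Tight module cores
  assemble low in the dendrogram, whereas unclustered genes accrete in
  near-continuous chains of merge heights reaching almost to the root, so no
  single cut height can trace the membership boundary. Stage one extracts
  maximal subtrees assembled entirely below half the tallest merge
  (configurable), recursively split where both sub-branches are sizeable and
  height-separated (`deep_split` 0–4 relaxes the gap). Stage two refines
  membership by **module eigengene correlation (kME)**: each core's
  eigengene is the first principal component of its standardised expression,
  every gene joins the module whose eigengene it correlates with most — if
  that correlation reaches 0.7 — and is otherwise left grey. The kME stage is
  what trims chance-correlated background genes (at 41 samples, absolute
  chance correlations run up to ~0.5, well below the 0.9+ of genuine module
  members) and rescues core genes the tree cut missed.
* **Hubs**: node centrality is the summed within-module adjacency; ties in
  the hub ranking break lexicographically. The top-100 within-module edges
  are exportable as a three-column tab-delimited file (VisANT dialect).

## Maturation gene programs and biomarkers

Each gene's log2 expression across the neuron samples only is correlated with
Dim1; the p-value is the classical two-sided Student transform
`t = r * sqrt((n - 2) / (1 - r^2))` with n − 2 degrees of freedom. Thresholds
are strict: `r > 0.4` with `p < 0.05` defines the green (immature-enriched)
cluster, `r < -0.4` with `p < 0.05` the magenta (mature-enriched) cluster —
remember Dim1 points away from maturity. **No multiple-testing correction is
applied**: the raw-p convention is a deliberate reproduction choice and is
the main reason these clusters should be read as screening sets, not
discoveries; a Benjamini–Hochberg option exists in the enrichment reporter
for practical use.

Candidate biomarkers are the intersection of the magenta cluster with the
neuron-specific module (mature-enriched *and* neuron-specific), optionally
cross-referenced against an external maturity gene list after upper-casing
both sides (an optional two-column synonym map absorbs cross-study symbol
drift). Enrichment of any gene collection is scored by the one-sided
Fisher's exact test (upper hypergeometric tail), with the filtered gene set
as the default universe.

```{r pipeline, eval = FALSE}
bundle <- generate_dataset("study", synthetic_config(seed = 15))
res <- run_pipeline(
  sweep_sets = bundle$paths$sweeps,
  expr = bundle$paths$expression,
  classes = bundle$paths$classes,
  gmt = bundle$paths$gmt,
  external = bundle$paths$external
)
length(res$biomarkers)
```

## What the synthetic study emulates — and what it does not

The generator reproduces the *structure* of a small Patch-seq maturation
study: 20 neurons spanning the full immature-to-mature range, 21 blood-like
contrast samples, and a 2000-gene FPKM matrix containing a 300-gene
neuron-specific block (+4 log2 over contrast), a 120-gene maturation-up
program and a 60-gene maturation-down program (±2 log2 across the maturity
range, neuron samples only), 80 genes pinned below the 0.1 FPKM floor, and a
latent-factor background (40 factors with follower counts falling off as
1/rank, loadings giving within-factor correlations of 0.5–0.7) that gives the
matrix the heavy-tailed connectivity spectrum real transcriptomes show. Sixty
of the maturation-up genes also carry the neuron offset: they are the planted
biomarker candidates, mirroring the partial overlap between a mature-enriched
cluster and a neuron-specific module; the synthetic external list shares
exactly 39 of them (padded with symbols absent from the matrix, lower-cased
to exercise identifier normalisation).

The ephys simulator is an integrate-and-fire caricature: passive exponential
charging plus stereotyped triangular spike waveforms stamped at analytically
known times, with cell parameters interpolating linearly in maturity
(Rin 800→150 MOhm, amplitude 40→90 mV, halfwidth 4→1 ms, threshold
−30→−45 mV, maximal firing 2→40 Hz, Na current 200→2000 pA, PSC rate
0.1→2 Hz — ranges bracketing values typical of stem-cell-derived neurons, not
claims about any particular dataset). Cells below maturity 0.1 may draw an
unexcitable phenotype, exercising the ND machinery. Recording noise is
0.2 mV, consistent with a 2 kHz-filtered whole-cell recording.

Passing tests on this material therefore demonstrate that the *algorithms*
recover known structure under realistic noise; they do not demonstrate
performance on real recordings, where spike waveforms adapt within trains,
baselines drift, expression noise is heteroskedastic and gene programs
overlap. The simulator deliberately omits channel kinetics, read-level
sequencing noise, dropouts and doublets.

## Problem sizes and numerical conventions

The shipped validation runs at the study's own scale — 20 + 21 samples,
2000 genes, 21 sweeps of 3500 samples per cell, 50 cells for the feature-
recovery checks, 200 replicate matrices for the null-calibration check —
sizes chosen to match the emulated study design while keeping the whole
suite fast on a laptop. Degenerate inputs are contracts, not accidents: a
zero-variance parameter column names itself in the PCA error; an empty
module, an all-ND column without a direction, a duplicated cell id, a
double log-transform and a query outside the enrichment universe all raise
informative errors; ties in hub ranking and edge export break
lexicographically so outputs are deterministic.

## Known limitations

* The dynamic cut is a documented approximation of the dynamic hybrid
  tree-cut family; it is not bit-for-bit any third-party implementation.
* With only ~40 samples, chance gene–trait correlations are sizeable; the
  raw-p cluster definitions inherit that (by design, as discussed above).
* The soft-power criterion rarely succeeds on strongly two-class data; the
  argmax fallback is reported via a warning and the chosen power recorded in
  the result.
* sEPSC/sIPSC discrimination by decay kinetics is a heuristic stand-in.
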