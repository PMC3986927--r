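---
title: "Profiling yeast stress tolerance from phenotypic-microarray kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling yeast stress tolerance from phenotypic-microarray kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmscreen)
```

## The measurement and the statistic

Phenotypic microarrays measure metabolic output of a microbial culture
through a redox-sensitive tetrazolium dye: a plate reader photographs each
well every 15 minutes and converts pixel intensity to an arbitrary-unit
*redox signal intensity* (RSI). A strain growing on glucose at 30 °C over
96 h produces a sigmoidal accumulation curve; under an osmotic, ethanol,
temperature, weak-acid, furan or phenolic stress the curve is attenuated
and/or delayed.

`pmscreen` condenses each strain × stress pair into the percentage redox
signal intensity of control,

$$\%\mathrm{RSI} = 100 \cdot \frac{S_{\text{stress}}(t_{\text{end}})}
                               {S_{\text{control}}(t_{\text{end}})},$$

where both endpoint signals are read from baseline-anchored, monotone-smoothed,
replicate-averaged curves at the condition's endpoint — 50 h by default,
24 h for assays at 40 °C, which have to be truncated because of evaporation.
Values above 100 % (stimulation, e.g. at 35 °C) are retained. Strains are
then ranked per condition (most tolerant first), the extremes labelled
(10 tolerant / 5 sensitive by default, mirroring the usual summary-table
layout), and the whole phenotypic profile of each strain is expressed as
log2 ratios against a reference strain (S288C by default), clipped to
±3 — the displayed range of TreeView-style heat maps — and clustered.

## Curve preprocessing

**Baseline transform.** Each curve is shifted so its first sample is 0 and
floored at 0. This preserves the arbitrary-unit scale of the endpoint
values (control endpoints typically fall in the 35–75 unit range) while
removing well-to-well offsets. The floor only matters for early negative
excursions of noisy wells.

**Monotone smoothing.** Cumulative dye conversion cannot decrease, so
negative slopes are measurement noise. `smooth_monotone()` applies a
centred moving average, sequentially increasing the window over odd widths
1, 3, 5, … until no negative slope remains, capped at `w_max = 25` points
(≈ 6 h at 15-min sampling), which in practice suffices for plate noise.
Edge windows truncate to the points available inside the centred span;
truncation, rather than symmetric shrinking, keeps the smoothed values at
the curve ends close to their local level instead of collapsing to the raw
endpoint, and is what the worked example in the test-suite pins down. If
the cap is reached with negative slopes left, their count is recorded and
a final running-maximum pass enforces monotonicity, so every downstream
endpoint read sees a non-decreasing curve. Smoothing is idempotent: a
smoothed curve re-enters at window 1 unchanged.

**Replicate averaging.** A minimum of three replicate runs per assay is
the norm; curves are averaged pointwise after smoothing (the mean of
monotone curves is monotone). Scores are computed on these mean curves,
not as means of per-replicate ratios — the ratio of means is more stable
when control endpoints are small.

**Endpoint rule.** The endpoint signal is the value at the latest sample
at or before `t_end` — no interpolation; on the 0.25 h grid the 50 h and
24 h endpoints are exact grid points (index 200 and 96 from 0).

**Guarding small denominators.** Controls below `eps = 1` unit (poor
growth; compare the "<20 units" poor-utilisation regime for pentose
sugars) make the ratio meaningless. Such scores are set to 0, flagged
`low_control`, ranked last, and excluded from the log-ratio matrix rather
than propagated as near-infinities.

## Clustering

Strain profiles (rows of the clipped log-ratio matrix) are compared with
the centred Pearson metric, $d = 1 - r \in [0, 2]$, over
pairwise-complete conditions (minimum two shared columns; zero-variance
profiles get $r = 0$ and are flagged). Agglomeration is the
Sokal–Michener unweighted pair-group method (UPGMA), written from
scratch: the matrix is scanned for its minimum distance — equivalently the
highest similarity — the pair is merged at that height, and the merged
cluster's distance to the rest is the size-weighted mean
$d(k, i{\cup}j) = (n_i d_{ki} + n_j d_{kj}) / (n_i + n_j)$, i.e. the
plain mean of all original member-pair distances. UPGMA heights are
non-decreasing, and the cophenetic distance between two leaves is the
height of their lowest common ancestor.

Numerical choices worth noting:

* **Tie-breaking.** Tied minima resolve to the pair with the smallest
  node creation indices (leaves in input order, then internal nodes in
  merge order), and the older node becomes the left child. The reference
  tools' own tie rule is undocumented; determinism is the requirement
  here, not bit-compatibility with them.
* **Exactness on ties.** When the two children are equidistant from a
  third cluster the common value passes through unchanged instead of
  being recomputed as a weighted mean; this keeps UPGMA on an ultrametric
  input an exact fixed point (its cophenetic matrix reproduces the input
  bit for bit), which the test suite asserts.
* **Export conventions.** The `.gtr` file stores similarity `1 - height`
  per merge, as Cluster 3.0 does for correlation-based runs; the `.cdt`
  table lists rows in dendrogram leaf order. Newick branch lengths follow
  the ultrametric convention — each internal node sits at half its merge
  height — so patristic distances between leaves equal cophenetic
  distances.

## Fermentation progress curves

Mini-fermentations monitored by weight loss give cumulative progress
curves; the practical question is by how many hours an inhibitor cocktail
slows a sensitive strain. `estimate_time_shift()` answers it by exhaustive
search over grid shifts, minimising the mean squared difference over the
overlapping window. The resolution is deliberately one grid step (15 min)
— the magnitude of interest is "about 2 h", and sub-grid interpolation
would suggest spurious precision. A monotonicity guard rejects genuinely
non-monotone inputs but tolerates single-step dips below 5 % of the curve
range, so realistic measurement noise does not abort the analysis.

## The synthetic-study generator

No raw plate export accompanies the study design this package targets, so
validation rests on a generator with known ground truth. It emulates the
design: 90 strains, one glucose control at 30 °C plus nine stress
conditions (sorbitol, ethanol, 35 °C, 40 °C, acetic and formic acid,
furfural, HMF, vanillin), three replicates, 15-min sampling over 96 h
(24 h at 40 °C). Each curve is a logistic,

$$S(t) = b + \theta A \,/\, (1 + e^{-r (t - t_m - \delta)}) + \varepsilon_t,$$

floored at 0, with amplitude $A \sim U(35, 75)$ per strain (the observed
control endpoint spread), rate $r = 0.3\,/\mathrm{h}$ and midpoint
$t_m = 20$ h (a mid-run sigmoid that is within 1 % of its plateau at the
50 h endpoint), baseline $b = 5$ units, and additive Gaussian noise
$\sigma = 2$ units (3–6 % of the endpoint range). The logistic family is
an explicit stand-in: the real dye chemistry is not modelled, only the
sigmoid shape class.

Stress enters through two failure modes visible in real data: amplitude
attenuation $\theta \in [0,1]$ and lag $\delta$. Per stress condition a
planted tolerant block draws $\theta \sim U(0.8, 1.0)$ and a sensitive
block $\theta \sim U(0.1, 0.3)$; the remaining strains draw from
$U(0.35, 0.75)$ (a range chosen once to fill the gap between the blocks);
controls have $\theta = 1$, $\delta = 0$. Because stress and control share
the logistic shape, the noiseless pipeline %RSI has the closed form
$100\,\theta$, which the suite checks to 1e-9 — an analytic end-to-end
oracle. Block membership is fixed at the strain level (10 tolerant, 5
sensitive, reference intermediate) so ranking and clustering see a
consistent structure. Randomness is reproducible: study-level parameters
come from the study seed, each curve's noise from a substream derived
deterministically from (seed, strain, condition, replicate).

A second, direct generator (`simulate_logratio_blocks()`) plants two
strain blocks with opposite alternating condition profiles plus
log2-scale noise (σ = 0.3) for clustering validation; flat block profiles
would be invisible to a centred-correlation metric, which is itself a
useful reminder of what that metric ignores (overall level) and what it
sees (profile shape).

What passing these synthetic checks does **not** show: robustness to
plate-edge and evaporation artefacts, dye-chemistry saturation,
non-logistic kinetics (diauxic shifts), batch effects between plate runs,
or correlated noise — real OmniLog data have all of these. The generator
validates the arithmetic and the algorithms, not the biology.

## Problem sizes and runtime

The default validation study (90 strains × 10 conditions × 3 replicates,
2 700 curves of up to 385 points) runs the full pipeline in a few seconds
on one core; the test suite's property checks use 1 000 random curves for
smoothing and 200 random matrices (n ≤ 8) against a brute-force UPGMA
re-scan oracle. These sizes were chosen to exercise the study-scale code
paths while keeping a full check-and-test cycle interactive.

## A small run

```{r demo, eval = FALSE}
res <- pm_demo(outdir = tempfile(), seed = 42, n_strains = 20)
summary(res)
head(res$ranks$sorb10[, c("rank", "strain_id", "percent_rsi", "class")])
plot(res)   # TreeView-style heat map with the UPGMA strain tree
```

## Known limitations

* %RSI is an endpoint statistic; rate phenotypes (doubling times, maximal
  slopes) are out of scope, and no significance testing is attached to
  rank differences.
* Aggregation of per-condition rankings into an overall "all stress"
  ordering has no canonical definition; none is provided beyond the
  per-condition tables.
* Column (condition) clustering is not performed; rows (strains) only.
* The wide-plate converter (`wide_to_long()`) is a convenience for simple
  rectangular exports, not a parser for proprietary instrument formats.
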