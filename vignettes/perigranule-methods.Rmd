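---
title: "Methods: condensate segmentation, small RNA enrichment and binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condensate segmentation, small RNA enrichment and binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perigranule)
```

`perigranule` bundles the quantitative methods used to study perinuclear
germ granules (P granules and mutator foci) in the *C. elegans* germline:
hierarchical K-means (HKM) segmentation of fluorescent condensates with
per-granule morphometry, normality-gated group statistics on germline
means, reads-per-million small RNA quantification with exact hypergeometric
gene-set tests, law-of-mass-action Kd fitting for thermophoresis
titrations, and iBAQ-based IP-MS enrichment scoring. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
choices made where the method description left the design open.

## Hierarchical K-means segmentation

### Level finding

Granule images are single confocal slices with a calibrated pixel size.
Segmentation thresholds are found by frequency-weighted agglomerative
K-means on the intensity histogram. With intensity range
$r = i_{max} - i_{min}$:

1. $K_0$ levels (default 16) are placed evenly through $[i_{min}, i_{max}]$,
   regardless of bin frequency.
2. Each populated bin is assigned to its nearest level; a bin exactly
   equidistant between two levels goes to the lower one (deterministic
   tie-break).
3. Each level moves to the count-weighted mean of its bins; levels with no
   bins are dropped.
4. Adjacent level pairs closer than the merging distance $m = r / K_a$ are
   merged into their mass-weighted mean, lowest pair first, and $m$ is
   recomputed from the new $K_a$ after every merge.
5. Sweeps repeat until assignments are stable and no level moves more than
   the convergence tolerance (default $10^{-6} r$), with
   $2 \le K_a \le K_0$ throughout.

Because $m$ grows as levels merge, any sufficiently large $K_0$ converges
to the same final levels; the package tests this for $K_0 \in \{4, 8, 16,
32\}$. The method description is silent on whether centroid updates are
frequency-weighted; unweighted updates would ignore the histogram
entirely, so weighted updates are used. The merge-before-next-assignment
schedule with lowest-pair-first ordering is one deterministic reading of
"recalculated for each iteration"; the K0-stability and oracle tests pin
its behaviour.

A histogram can be effectively single-class — granule-free noise, for
example. In that case merging is stopped only by the $K_a \ge 2$ floor and
the two surviving levels sit closer than $m$. `hkm_levels()` flags this as
`separable = FALSE` and `extract_objects()` returns nothing: a clustering
that found no separable intensity classes provides no evidence of objects.
This is what makes the pipeline return zero detections on pure-noise
inputs at any noise amplitude. The flip side is that genuinely low-contrast
images (granules barely above background) are also declared empty; users
with such data should inspect the `separable` flag rather than trust an
empty result.

### Object extraction, gating, reclustering

Levels are applied as strict (`>`) thresholds in ascending order. At each
level, unclaimed pixels above the level are labelled with 8-connected
components. The size range is an equivalent-circle radius interval
(default 0.1–0.6 µm, so areas $\pi r^2$); "radius range" is not defined
as diameter or volume anywhere in the original description, and radius →
area is the reading used throughout. In-range components are accepted and
their pixels claimed; oversized components are deferred to the next level,
where higher thresholds may split them; undersized components are claimed
as *fragments* at the lowest level where they appear.

Accepted regions then pass a low-intensity gate: a global threshold
(default Otsu, computed once over all analysed pixels, not per level)
removes regions whose *mean* pixel intensity falls below it. Fragments are
gated the same way before reclustering — the reclustering step exists to
reconstruct bright objects split across levels, not to assemble background
speckle, and gating first also avoids a quadratic blow-up when a noisy
image produces thousands of sub-minimum noise fragments. Surviving
fragments are merged agglomeratively (closest centroid pair first, merge
allowed only if the union stays within the maximum area and the centroids
lie within one maximum diameter); merged fragments at or above the minimum
area are reported as regions, the rest discarded.

### Morphometry

Per granule the package reports mean pixel intensity (the original
description names "intensity" without defining it; the mean is robust to
region size, unlike integrated density), area in µm², circularity
$4\pi A / P^2$ capped at 1, and the signed Euclidean distance from the
region centroid to the nearest nucleus-boundary pixel (negative inside a
nucleus, preserving the perinuclear/internal distinction). The perimeter
$P$ is the traced 8-connected boundary chain with Vossepoel–Smeulders step
weights (0.948 axial, 1.340 diagonal), which corrects most of the
rasterisation bias of a naive chain length; digital disks land slightly
above 1 and are capped.

## Group statistics on germline means

Granule metrics are averaged per germline, and germlines are the
statistical unit. For a control/test comparison both groups (≥ 3 germlines
each) are tested for normality with Shapiro–Wilk at α = 0.05 (the α was
not stated; 0.05 is assumed, and both groups must pass — the conservative
reading of "on normally distributed data"). If both pass, a two-sided
equal-variance Student's t-test is used (the method names Student, not
Welch); otherwise a two-sample two-sided Kolmogorov–Smirnov test
(`stats::ks.test`, exact for small samples without ties). P values are
coded `+++` (< 0.001), `++` (< 0.01), `+` (< 0.05), `-` (≥ 0.05); the
four bands partition [0, 1]. No multiple-testing correction is applied
across table cells, matching the original reporting. Intensity fold
changes are computed within experiment: each germline is divided by the
mean intensity of that experiment's control germlines, so controls average
to 1 by construction and session-to-session gain cancels.

A null simulation (both groups drawn from one normal distribution, n = 10
germlines per group, 2000 replicates) holds the empirical type-I error of
the gated procedure at 0.05 ± 0.02; the acceptance suite re-runs it.

## Small RNA quantification and enrichment

Counts are normalised to reads per million *uniquely mapping* reads per
sample. The expressed universe is genes with mean rpm strictly above 50
across all samples of the comparison ("over 50" → strict). Per-gene fold
change is mean mutant rpm over mean wild-type rpm, displayed as natural
log; genes with wild-type mean 0 have undefined fold change and are
excluded from both the universe and every test set (the original text does
not address them). The twofold-reduced set is fold change strictly below
0.5. piRNA-sensor reads are normalised by H2B-mapping reads instead of
library totals, since the sensor is an H2B transgene.

Set overlaps are tested with the exact hypergeometric tail: upper tail
$P(X \ge k)$ for enrichment, lower tail $P(X \le k)$ for depletion (used
for the csr-1-target case). Reported bounds reach $10^{-194}$, far below
double underflow for naive products, so the tail is summed in log space:
log-gamma terms for each pmf value combined with a max-shifted
log-sum-exp. Tests verify agreement with arbitrary small-case brute-force
sums (all $N \le 60$ cases sampled) to $10^{-9}$ on the log10 scale,
complementarity of upper and lower tails, and agreement with
`stats::phyper(log.p = TRUE)` on the extreme published counts —
`phyper` is the independent cross-check, never the implementation.

Read classification applies the 18–32 nt retention window, then calls
21-mers with 5′ U "21U" (piRNAs) and 22-mers with 5′ G "22G" (secondary
endo-siRNAs).

## Binding isotherm fitting

Thermophoresis titrations are modelled by the exact law-of-mass-action
fraction bound at finite labelled concentration $L$:

$$FB(T) = \frac{(L + T + K_d) - \sqrt{(L + T + K_d)^2 - 4LT}}{2L},$$

with signal $= s_{free} + (s_{bound} - s_{free})\,FB$. Both baselines are
fitted (the standard MST treatment; whether they were fixed originally is
not stated). The model is linear in the two signal parameters, so they are
profiled out by linear least squares and the profiled residual sum of
squares is minimised over $\log K_d$ — a 13-point log-spaced grid
($10^{-1}$–$10^5$ nM) brackets the global basin and Brent optimisation
resolves the minimum to machine precision. The signal axis is standardised
internally, making the recovered $K_d$ exactly invariant to affine
rescaling of the input signal. Uncertainties are Gauss–Newton
local-curvature standard errors; whether the originally printed ± values
were fit SEs or replicate SDs is ambiguous, so the fit SE is reported and
labelled as such. Fits with $K_d$ at the grid edge are flagged
(`at_grid_bound`).

## IP-MS enrichment

iBAQ columns are divided by their totals (idempotent total-sum
normalisation), log10 transformed after flooring zeros at half the
smallest nonzero normalised value (the missing-data rule was unstated; the
floor is configurable), then each protein is tested bait-IP versus control
with a two-sided equal-variance t-test, with fold change the difference of
group medians on the log10 scale. Candidates pass both a p and a
fold-change cutoff and are ranked by fold change. Under a simulated global
null the p distribution is uniform within Kolmogorov distance 0.05 at 1000
proteins.

## Synthetic data: what it emulates, and what it does not

Every pipeline stage is exercised on generated data with known truth; all
generators are pure functions of their spec plus a seed.

* **Images** (`simulate_germline_image()`): 260 × 260 px at 0.05 µm/px,
  disk nuclei of radius 1.5 µm on a jittered grid, 8 granules per nucleus
  on the nucleus perimeter (angularly uniform with jitter, 1 px radial
  jitter), radii drawn from 0.15–0.5 µm — inside the 0.1–0.6 µm analysis
  range, bracketing the ~0.25 µm scale of in vivo clusters. Granules are
  2-D Gaussian spots with σ = r/2 **clipped at 2σ**, i.e. at the nominal
  radius, so the rendered footprint area equals the planted area
  $\pi r^2$ by construction (a 3σ clip would make the rendered object 1.5×
  its nominal radius and leave "planted area" meaningless). Peak 150 a.u.
  over a background of 10, Gaussian read noise of sd 2 by default.
* **Counts** (`simulate_count_matrix()`): 2000 genes, negative-binomial
  (size 10) around log-normal baseline mean rpm (meanlog log 60, sdlog
  1.2, so roughly half the genes clear the 50 rpm filter), 3 replicates
  per genotype as in the sequenced libraries, library totals ~2 × 10⁶,
  multiplicative effects applied to designated gene sets in the mutant.
* **Titrations** (`simulate_titration()`): 16-point 1:2 dilution from
  20 µM, 10 nM labelled species, noise sd 2% of the amplitude.
* **iBAQ** (`simulate_ibaq()`): log-normal abundances, 4 bait vs 3 control
  samples, spike proteins multiplied in the bait group.

The image generator deliberately omits optical realism: no PSF
convolution, no z-structure, no autofluorescence gradients, no intensity-
dependent shot noise, and granules never overlap nuclei interiors. Passing
segmentation tests therefore demonstrate the algorithmic contract
(levels, extraction, gating, measurement) — not robustness to deconvolution
artefacts or densely packed real germlines, where manual curation of the
analysed region remains necessary, as it was in the original workflow.
Count, titration and iBAQ generators likewise capture the statistical
skeleton (overdispersion, design, noise scale) rather than protocol-level
artefacts such as adapter bias or ratio compression.

## Numerical choices and degenerate inputs

* Non-integer intensity data are binned to 256 equal-width bins before
  clustering; integer data keep one bin per distinct value.
* Coordinates are 1-based (row, column) matrix indices; connectivity is
  8-connected for granules and for nuclei.
* A constant image (zero intensity range) is a degenerate-range error for
  level finding; an empty mask is an error; a mask of all-background
  yields an empty region list, not an error.
* Problem sizes in the test and acceptance suites (260 px fields, three
  seeds for recall/precision, 2000-replicate null, 50 titration refits,
  brute-force hypergeometric checks at N ≤ 60) were chosen so each check
  completes in seconds while leaving the estimates' Monte-Carlo error well
  inside the asserted tolerances.

## Known limitations

* The agglomerative schedule of the original plugin (merge before or after
  the assignment sweep) is not recoverable from its description; the
  implemented order is fixed, documented, and oracle-tested, but other
  orders could yield slightly different level sets on pathological
  histograms.
* Condensate length along the perinuclear membrane — measured manually in
  the original work — is intentionally not automated here.
* Reclustered (merged-fragment) regions may be disconnected pixel sets;
  their circularity uses the summed component perimeters and should be
  interpreted with care.
* `segment_nuclei()` is a convenience (Otsu + hole filling + size filter);
  it does not split touching nuclei. Externally curated masks can be
  supplied instead, mirroring manual curation practice.
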