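# perigranule

Quantitative analysis of perinuclear germ granules in the *C. elegans*
germline — and of the small RNA, binding and proteomics experiments that
accompany condensate biology.

P granules and mutator foci are membraneless condensates docked at germline
nuclei; perturbations of piRNA-pathway components (PRG-1, DEPS-1, the
mutator-class genes) change their intensity, size and shape, the abundance
of 21U piRNAs and 22G secondary endo-siRNAs, and the protein complexes
recoverable by IP-MS. `perigranule` implements the full desk-side analysis
stack for such studies:

* **HKM segmentation** — frequency-weighted agglomerative K-means on the
  image histogram yields ordered threshold levels (starting K = 16 by
  default, merging distance `m = (i_max − i_min)/K_a` recomputed each
  iteration); objects are extracted at ascending levels within an
  equivalent-circle radius range (0.1–0.6 µm), gated by a global Otsu
  low-intensity filter, and sub-minimum fragments are reclustered.
* **Morphometry & group statistics** — per-granule mean intensity, area,
  circularity (`4πA/P²`, capped at 1) and signed nucleus-boundary distance;
  germline means compared with a Shapiro–Wilk-gated choice of Student's
  t-test or Kolmogorov–Smirnov test, coded `+++ / ++ / + / −`, plus
  within-experiment intensity fold changes.
* **Small RNA enrichment** — reads-per-million normalisation by uniquely
  mapping reads, a strict >50 rpm mean-expression universe, mutant/wild-type
  fold changes (natural-log display), 21U/22G read classification, and exact
  hypergeometric enrichment/depletion tests computed in log space (accurate
  to p ~ 10⁻³⁰⁰ and below on the log scale).
* **Binding constants** — the quadratic law-of-mass-action isotherm
  `FB = ((L+T+K_d) − √((L+T+K_d)² − 4LT)) / 2L` fitted by variable
  projection over a log-spaced K_d grid, deterministic to machine precision.
* **IP-MS enrichment** — iBAQ total-sum normalisation, log10 t-tests and
  median fold changes, ranked candidate lists.
* **Synthetic data** — seeded generators for germline images, count
  matrices, titrations and iBAQ matrices with known ground truth, so every
  stage is testable without any raw-data download.

## Worked example

Simulate a germline field, segment it, and measure the granules:

```r
library(perigranule)

sim  <- simulate_germline_image(image_sim_spec(seed = 42))
regs <- segment_granules(sim$granules)        # K0 = 16, 0.1-0.6 um, Otsu
attr(regs, "levels")
#> hkm_levels: Ka = 2 (6 iterations), m_final = 80.2
#>   levels: 10.609, 95.993
length(regs)       # 19 of the 24 planted granules survive the noise floor
#> [1] 19

nuclei <- segment_nuclei(sim$dapi)
recs <- measure_granules(regs, sim$granules, nuclei,
                         germline_id = "g1", genotype = "wild-type")
summarize_germline(recs)
#>   germline_id  genotype experiment_id mean_intensity area_um2 circularity
#> 1          g1 wild-type            e1            126    0.114           1
#>   nucleus_distance_um n_granules
#> 1               0.014         19
```

The two threshold levels sit at the background (≈10.6 a.u.) and granule
(≈96 a.u.) intensity classes; the summary says granule centroids sit
essentially on the nucleus boundary (mean signed distance 0.014 µm), as
planted. With `noise_sd = 0` all 24 granules are recovered with centroids
within 2 px of truth.

Overlap statistics on printed set sizes — e.g. 259 of 447 genes
twofold-reduced in one mutant overlapping 704 in another, in a universe of
2012 expressed genes:

```r
hypergeometric_tail(N = 2012, K = 704, n = 447, k = 259, tail = "upper")
#> hypergeometric upper tail: k = 259 of n = 447 vs K = 704 of N = 2012; log10 p = -29.01
```

Fit a binding constant from a synthetic thermophoresis titration (10 nM
labelled species, 1:2 dilution, 2% noise, true K_d 855 nM):

```r
fit_isotherm(simulate_titration(855, noise_sd = 0.02, seed = 7)$curve)
#> binding_fit: Kd = 1021 nM (SE 73.7), signals 0.23 -> 1.219
```

A single noisy 16-point curve carries real uncertainty; averaging 50
replicate refits recovers the generating value (849.6 nM for seed 1 — see
below).

End-to-end reports are available as `run_condensate_report()` (comparison
table + fold changes from a table of images) and `run_srna_report()`
(abundance, fold changes, set enrichment, including a direct-entry mode for
printed `(N, K, n, k)` counts). A thin command-line wrapper lives at
`inst/cli/perigranule.R` with `segment`, `simulate`, `srna` and `mst-fit`
subcommands.

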