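# clonedrift

Normal, sun-exposed human skin is a patchwork of somatic mutant clones, many
carrying cancer-gene mutations, detectable by deep targeted sequencing of
small biopsies. The central question this package addresses is whether the
observed clone sizes are compatible with neutral stem-cell dynamics — and if
not, what kind of competitive advantage and spatial mechanism produces the
observed clone-size distributions. It is written for researchers analysing
subclonal mutation data from epithelial sheets and for modellers of stem-cell
clonal dynamics.

clonedrift provides three connected layers:

* **A hexagonal-lattice simulator** of stem-cell clonal dynamics (`run_lattice()`):
  a death-first voter model — each stem cell is lost at rate λ (0.5 per cell
  per week in the basal layer) and replaced by the division of a uniformly
  chosen neighbour — with neutral mutations at rate ω, advantaged mutants
  whose loss rate φ < λ, stochastic migration, and an optional heterogeneous
  stem/transit-amplifying compartment with energy-gated migration.
* **Closed-form clone-size models** with fitting. Neutral drift gives
  P_n(t) = e^(−n/rλt)/(n ln rλt), whose first incomplete moment decays as
  e^(−(n−n₀)/rλt) (`fit_incomplete_moment()`); the voter-model saturation
  time is T = N(ln N + 1/(2r))/λ (`klein_saturation_time()`); boundary
  nucleation of passenger clones at the rim of an expanding mutant clone
  yields an inverse-cubic clone-size tail, β(∞) = −3 (`boundary_M()`,
  `boundary_beta()`); exponential clone growth yields an exact inverse-square
  law (`exponential_M()`); empirical tails are fitted on the log–log scale
  (`fit_power_law()`).
* **A strand-aware beta-binomial variant caller** (`call_variants()`):
  per-site per-strand background error means with one shared overdispersion ρ
  fitted on a control panel, a likelihood-ratio test against a shared-mean
  alternative (χ², 2 df), per-sample Benjamini–Hochberg correction at
  q < 0.05, matched-control subtraction, coverage (>50 reads), support
  (≥5 reads) and 5-bp merge filters — validated by Monte-Carlo spike-ins
  (`benchmark_spikein()`) on synthetic panels (`simulate_counts()`).

## A worked example

How large can a clone get by neutral drift alone? For the largest clones
seen in real biopsies (VAF 0.2 in a 16 mm² biopsy ≈ 64,000 basal cells):

```r
library(clonedrift)

vaf_to_cells(0.2, area_mm2 = 16, linear_density = 100)
#> # A tibble: 1 × 4
#>     vaf cell_fraction cells area_mm2
#>   <dbl>         <dbl> <dbl>    <dbl>
#> 1   0.2           0.4 64000      6.4

# time for one clone to take over a 64,000-cell patch under neutral drift
weeks_to_years(klein_saturation_time(64000, lam = 0.5))
#> [1] 29600.84

# probability of a >= 64,000-cell clone after 100 years of neutral drift
cumulative_tail(64000, N = 160000, r_lambda = 0.5, t = 100 * 365.25 / 7)
#> [1] 1.11e-13
```

Neutral drift would need tens of millennia; the largest observed clones
cannot be neutral. The simulator shows the same thing forwards: three
simulated years of neutral drift on a 200 × 200 lattice, then the
incomplete-moment fit of the detectable clone sizes:

```r
p   <- sim_params(200, 200, omega = 1e-3, duration = 3 * 365)
sim <- run_lattice(p, seed = 1)
sizes <- sim$clones$cells[sim$clones$label != 0]
fit <- fit_incomplete_moment(sizes[sizes >= 20])
fit
#> Incomplete-moment fit: r*lambda*t = 36.83, n0 = 24.91 (R^2 = 0.9920, n = 693 clones)
```

The decay constant ≈ 37 cells is the neutral scale (clones born throughout
the run average half the maximal age, rλt/2 ≈ 39), n₀ sits at the detection
cutoff, and the near-perfect exponential fit (R² = 0.99) is the neutral
drift signature; clones tens of thousands of cells across are unreachable.
Runs with advantaged mutants (`theta > 0`, `phi < lam`) reproduce the same
shape at a much larger scale.

The methods vignette (`vignettes/clonedrift-methods.Rmd`) documents the
models, parameter conventions and design decisions in detail.

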