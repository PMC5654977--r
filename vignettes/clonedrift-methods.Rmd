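---
title: "Models and methods behind clonedrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonedrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedrift)
```

clonedrift studies how somatic mutant clones compete in a two-dimensional
stem-cell compartment such as the basal layer of sun-exposed human epidermis.
Deep targeted sequencing of normal skin reveals a dense patchwork of mutant
clones; the package asks which clone sizes are compatible with neutral drift,
what dynamics are needed to explain the largest clones, and how subclonal
variants can be called reliably at error rates close to the sequencing noise
floor. Three model layers work together: a stochastic lattice simulator, a
set of closed-form clone-size distributions with fitting routines, and a
strand-aware beta-binomial variant caller, plus generators for synthetic
data so the whole pipeline is testable end to end.

## The lattice model

The basal layer is modelled as a two-dimensional hexagonal lattice. Each
site holds a wild-type stem cell (A), an advantaged mutant stem cell (B), a
transit-amplifying cell (C), or is empty. Time advances in quantised steps
of one day, and all transitions initiate and complete within one step.

The homogeneous model is a death-first voter model. Each stem cell is lost
with probability λ·dt (converted from the weekly rate, λ = 0.5 per cell per
week, as λ/7 per day), and each vacancy is refilled by the division of a
uniformly chosen occupied stem neighbour. Neutral mutations arrive at rate ω
per cell per day and assign a fresh clonal label, recorded in a forest
rooted at the founding label; the size of a clone is the recursive sum of
its own live cells and all descendant clones. Non-neutral mutations (rate θ)
convert a stem cell to type B, which differs only in its loss rate φ < λ —
the advantage is a longer residence in the stem compartment, not a faster
division clock. Migration stochastically swaps adjacent site
contents at rate κ per pair per day.

The heterogeneous extension adds the stem/TA architecture: a binary
differentiation map (circular stem clusters on a triangular grid of centres;
cluster radius 20 cells by default) marks where stem cells differentiate
into TA cells at rate ν. TA cells divide into adjacent vacancies — both
daughters incrementing the division counter — until a cap of q_max
divisions, and are lost at their own rate. A lattice energy function scores
stem cells by their TA neighbours (plus a large penalty p outside their home
territory) and TA cells by stem and empty neighbours; migration in this mode
is accepted only when it strictly lowers the total energy, which maintains
the observed segregation of stem clusters and TA belts. B cells never
differentiate, so advantaged clones also escape the stem→TA exit route.

### Choices the model statement leaves open

* **Within-day ordering.** Losses are sampled simultaneously (one binomial
  count per cell type, with uniformly chosen distinct sites — exactly
  equivalent to independent Bernoulli draws per cell); vacancies are then
  filled in uniformly random order, each choosing its donor among currently
  occupied stem neighbours; then mutations; then differentiation, TA
  division and TA loss; then migration. Random fill order avoids the sweep
  bias of any fixed scan.
* **Boundary and indexing.** Odd-row offset coordinates on a rectangular
  array; the default boundary is toroidal (no edge artefacts on clone
  growth; requires an even row count so hex parity survives the wrap), with
  a clipped boundary available.
* **Rates.** Weekly rates (λ, φ) become daily probabilities as rate/7,
  valid since λ·dt/7 ≈ 0.07 « 1. TA division defaults to the stem
  replacement rate and TA loss to ta_div_rate/q_max, so a TA belt turns over
  after about q_max divisions. The physical migration estimate (10 µm/day at
  one 10 µm cell diameter per lattice spacing) corresponds to κ ≈ 1.
* **Initial heterogeneous state.** Stem cells inside clusters, TA cells
  outside, with a 5% vacancy fraction outside clusters; all exposed as
  arguments.
* **Purging.** Clone records whose subtree has no surviving cells are
  tombstoned every 30 days; purging is observationally silent (checked in
  the tests by comparing purged and unpurged runs at identical seeds).
* **VAF convention.** Clones are heterozygous in a diploid genome, so a
  clone spanning a cell fraction f reports VAF = f/2; 0.2 VAF means 40% of
  the cell population.

## Closed-form clone-size models

**Neutral drift.** The clone-size distribution under neutral drift is
P_n(t) = e^{−n/rλt} / (n · ln(rλt)). Its normalised first incomplete moment
(the fraction of all mutant cell mass in clones of size ≥ n) is exactly
exponential, exp(−(n−n₀)/rλt), because the n in the mass term cancels the
1/n of the distribution. `fit_incomplete_moment()` fits the log moment by
unweighted least squares, returning the decay constant and the offset n₀
that absorbs the sequencing detection limit: censoring the sample below a
threshold moves n₀ to roughly that threshold while leaving the decay intact
(verified numerically in the tests). The fit drops curve points backed by
fewer than five clones so the noisy extreme tail cannot dominate. Note that
a uniform additive shift of all sizes is *not* equivalent to truncation: the
added mass decays with the count tail rather than the mass tail and distorts
the decay estimate once the shift is comparable to the scale.

`cumulative_tail()` sums P_n from s to the population size N in log space
(log-sum-exp), and `klein_saturation_time()` evaluates the voter-model
fixation time T = N(ln N + 1/(2r))/λ; weeks convert to years at 365.25/7 =
52.18 weeks per year.

**Boundary nucleation.** A primary clone with a competitive advantage
expands radially at speed α to final radius R; neutral passenger mutations
arising on its boundary are carried outward, and the expected area of a
passenger born when the primary radius is r falls as the boundary grows.
Changing variables from nucleation time to final area yields the density
M(A), which the package evaluates in a cancellation-free rearrangement
(root − u rewritten as R²/(root + u); algebraically identical to the printed
two-factor product). Its local log-log slope has the closed form
β(A) = −A(A + 2√(A² + σ²R²))/(A² + σ²R²), which runs from 0 at small areas
to −3 at large areas: the inverse-cubic tail. The magnitude of M is
returned; the raw expression is negative because dr/dA < 0.

**Exponential growth.** If clones instead grow exponentially at rate b,
secondary clones nucleate in proportion to primary area and the resulting
density is proportional to A⁻² exactly, on the support between the single
cell area a = π(σ/2)² and a·e^{bT}.

`fit_power_law()` estimates tail exponents from logarithmically binned
empirical densities (20 bins by default) by unweighted least squares on the
log-log scale, and reports residuals against the fixed −2 and −3 slopes for
model comparison, mirroring how empirical clone-size distributions are
compared against the two growth laws.

## The variant caller

Deep targeted sequencing of polyclonal tissue needs subclonal calls at VAFs
near the error floor. Errors vary by position and, unlike true variants,
PCR artefacts are strand biased. Counts for each non-reference allele k at
position j follow beta-binomials per strand, X ~ BetaBin(n, v, ρ) and
X′ ~ BetaBin(n′, v′, ρ), where v, v′ are per-site per-strand mean error
fractions estimated across the control (saliva) panel and ρ is a single
overdispersion shared across all captured sites. The parameterisation is by
mean and intraclass correlation: shape parameters α = μ(1−ρ)/ρ,
β = (1−μ)(1−ρ)/ρ. The default v estimate pools reads across controls
(weighting deeper samples; a per-sample mean is available), and ρ is
profiled on a log grid over [10⁻⁶, 0.5] with local refinement. Pooling v
from the same data biases ρ slightly downward (about 15% at 30 controls in
the tests), within the tolerance the benchmarks require. A site/strand whose
pooled control count is zero would make a single stray read in a test sample
infinitely significant, so the rate used in testing is floored at half a
read over the pooled panel depth; the reported v remains the raw fraction.

Each site/allele in a test sample is scored with a likelihood-ratio test:
the null uses the strand-specific background means, the alternative a
common mean μ = (x+x′)/(n+n′) on both strands — a genuine variant is
present equally on both strands, so single-strand signal is penalised. The
statistic is referred to χ² with 2 degrees of freedom (zero alternate reads
are never evidence, so their LR is pinned at 0). P-values are BH-corrected
within each sample (per-sample families match per-sample calling; the
cohort-wide alternative is noted but not used), and calls require q < 0.05,
absence from the matched control (not significant there and below a 0.3
control-VAF germline guard), more than 50 total reads in both sample and
matched control, and at least 5 supporting reads. Calls within 5 bases in
the same sample — typically complex deletion events with similar VAFs — are
chained transitively and reported as one spanning deletion with the average
VAF of the members.

## Synthetic data

The generators emulate the statistical structure of a 10-patient panel
rather than any real cohort: per-site error means drawn log-uniformly over
[10⁻⁵, 10⁻²·⁵] (error rates vary across genomic locations; the distribution
itself is a fixture choice), Poisson strand depths around 500× (≈1000×
total), beta-binomial background noise with one true ρ, and spikes added
binomially on both strands (or one strand, to probe the strand-aware null).
Clone-size samples draw from the neutral, inverse-cubic, inverse-square or
arbitrary power-law densities by inverse-CDF sampling. The substitution
spectrum generator is strongly C>T-weighted by default, echoing the UV
signature of skin, with illustrative (not fitted) weights.

What the synthetic data does not capture: alignment and mapping artefacts,
strand-correlated context effects, contamination, copy-number changes, or
inter-patient coverage structure. Green benchmarks therefore certify the
statistics, not the upstream bioinformatics.

## Problem sizes and numerical notes

The test suite exercises the simulator at the scales the analyses use: the
neutral ceiling on a 400 × 400 lattice over 100 simulated years (five
seeds; the largest clone reaches a fraction ~0.025 of the population), and
incomplete-moment pipelines on 200 × 200 lattices over 3 years with ω =
10⁻³ per cell per day. On simulated lattices the detection threshold is
expressed in cells (default 20 for these analyses): the biopsy-scale
threshold of 0.007 VAF corresponds to more cells than the largest neutral
clone on a feasible lattice, and the fitted n₀ absorbs whatever cutoff is
used, so the thresholds are a reporting choice rather than a model change.
For the θ-insensitivity comparison the package compares the rescaled size
distributions of non-neutral founder lineages between θ = 10⁻⁶ and 10⁻⁵;
at these lattice sizes the mixture of neutral background and mutant-driven
clones shifts with θ (there are simply more mutant clones), while the
founder-lineage shape itself collapses after rescaling.

Tail sums run in log space; the boundary density uses the stable
rearrangement above so numerical and analytic slopes agree to better than
10⁻⁶ in relative terms across the tested range; power-law fits ignore empty
bins; incomplete-moment fits refuse degenerate samples (fewer than 10
clones, or all sizes equal).

## Limitations

The lattice is a single basal layer with at most one cell per site; no
three-dimensional tissue, no explicit committed-progenitor bookkeeping (a
stem cell lost is a stem cell differentiated), and mutant advantage enters
only through the loss rate. The geometric boundary-nucleation model is
deterministic and ignores clone-clone collision, which the simulator shows
matters once mutant clones occupy an appreciable lattice fraction. The
caller assumes the control panel shares the error process of the test
samples and does not model copy number.
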