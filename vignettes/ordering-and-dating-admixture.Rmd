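---
title: "Ordering and dating multiple admixture events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering and dating multiple admixture events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixwave)
```

Most admixture-aware methods assume at most one admixture event. Many real
populations — and essentially all of the interesting ones — have instead
received gene flow repeatedly, from different sources, at different times.
`admixwave` addresses the two questions such histories raise:

1. **In what order did the ancestry components arrive?** Answered by the
   *admixture history graph* (AHG), a covariance test on individual ancestry
   proportions.
2. **When did each event happen?** Answered by a Haar-wavelet summary of
   local-ancestry block widths, calibrated against forward simulations, and
   applied *sequentially*: the most recent event is dated first, its blocks
   are masked out, and the remaining genome is re-analyzed for the earlier
   events.

A forward-in-time simulator of multi-pulse admixture ties the two together:
it validates the ordering test, provides the dating calibration, and defines
exactly what the passing tests do and do not demonstrate.

## The ordering model

Consider a population with two ancestral contributions $A$ and $B$, whose
proportions $q_A$, $q_B$ vary across individuals. When a later pulse brings
a new component $C$, each individual's $q_A$ and $q_B$ are rescaled by the
same factor $(1 - q_C)$, which varies across individuals. Consequently
$q_A$ and $q_B$ now covary with $q_C$ — but the *ratio* of the older pair is
untouched. Writing $r = q_A / (q_A + q_B)$, the correct ordering predicts

$$\operatorname{cov}(r, \; q_C) = 0,$$

while the two wrong orderings (treating $A$ or $B$ as the newcomer) leave a
systematically nonzero covariance. `trio_statistics()` therefore evaluates
all three candidates for "most recent" and chooses the one minimizing
$|\operatorname{cov}|$; with $K > 3$ components, `infer_graph()` tests all
$\binom{K}{3}$ trios and reconstructs the full arrival order by
*vote-peeling*: among the components not yet placed, the one chosen as
recent by the most trios (drawn wholly from the unplaced set) is the latest
arrival, and the recursion ends at the founding pair, whose internal order
the test cannot resolve.

Design choices worth making explicit:

* **Ratio as $A/(A+B)$, not $A/B$.** Both carry the same independence
  claim; the bounded form is defined whenever $q_A + q_B > 0$ and is
  numerically stable near zero. Individuals with $q_A + q_B = 0$ carry no
  ratio information and are excluded (an error if they exceed half the
  sample).
* **Raw $|\operatorname{cov}|$, not correlation, selects the ordering.**
  Correlations are reported for diagnostics. Normalizing by the candidate's
  standard deviation would divide by exactly the quantity whose smallness
  makes low-proportion components unreliable.
* **Sample covariance with $1/(n-1)$.** The normalization is shared by all
  three candidates, so the selection is unaffected by the convention.
* **Ties.** Votes are tie-broken by the more decisive mean margin (the
  smallest-to-second-smallest $|\operatorname{cov}|$ ratio over the trios
  that chose the candidate; smaller is more decisive). A tie surviving that
  is an error, not a silent guess.
* **Known failure modes**, surfaced by `reliability_flags()`: components
  with mean proportion below 5% (ordering accuracy demonstrably degrades —
  the acceptance suite measures it), and near-equal variances of all
  components (operationalized as max/min variance $< 2$), under which the
  covariance signal is obscured.
* `permutation_consistency()` adds a permutation support value the original
  procedure did not define: the candidate column is permuted across
  individuals and the observed $|\operatorname{cov}|$ ranked among the
  permuted ones; small values mean the observed covariance is closer to
  zero than chance.

## The dating model

Recombination breaks ancestry tracts at roughly one crossover per Morgan
per meiosis, so ancestry introduced as intact migrant genomes $g$
generations ago survives as blocks of expected genetic length

$$\ell(g, m) = \frac{100}{g\,(1 - m)} \ \text{cM}$$

for a pulse of proportion $m$ (the large-$N$ Markovian limit;
`expected_tract_length()`). Wider blocks mean more recent admixture. The
package measures block width genome-wide with an orthonormal Haar
transform: each chromosome is divided into $2^n$ equal-genetic-width
windows, a two-ancestry panel is encoded $-1/+1$ (masked or unresolved
windows as 0, the midpoint), and the mean squared detail coefficient per
scale gives a power spectrum whose count-weighted total equals the signal
variance (Parseval; asserted to $10^{-9}$ in the tests). The *wavelet
center* — the energy-weighted mean scale index, pooled across haplotypes
and chromosomes on the genetic-width axis so mixed window schemes (e.g.
1024/512/256 windows for human chromosomes) combine coherently — is the
dating statistic: it moves toward finer scales as admixture ages.

The center has no closed-form inverse, so dates come from simulation:
`build_calibration()` simulates single-pulse histories over a grid of
$(g, m)$, records the center distribution per cell ($R \ge 20$
replicates), and `estimate_generations()` inverts the monotone
center-to-$g$ relation by linear interpolation (after an isotonic fit that
irons out replicate jitter), using the $m$ column nearest the observed
admixture rate. Confidence intervals resample chromosomes with replacement
(200 draws by default) and re-invert. Centers outside the calibrated range
are an error ("beyond calibrated range"), not an extrapolation: near the
resolution limit the statistic genuinely cannot distinguish ages.

### Sequential masking

With more than two components the dating question is asked newest-first
(`date_events()`):

1. merge everything older than the most recent component into
   "population 1" and the recent component into "population 2"
   (`merge_ancestries()`);
2. compute the center and date it;
3. mask the recent component's windows (`mask_ancestry()`) and repeat with
   the next event, until the founding pair is dated against each other
   under the cumulative mask.

Masking shrinks the usable genome, which would bias a naive comparison to
unmasked simulations. The package's correction is to apply the *identical
mask positions* to every calibration simulation, which is the strictest
testable reading of "taking the reduction in genome size into account"; a
`mask_mode = "random"` alternative masks a uniformly random window set of
the same total size, for sensitivity analysis when only the masked length
is trusted. Dating refuses to continue once the cumulative masked fraction
exceeds 0.8 (configurable): too little genome remains for the spectrum to
mean anything. The observed admixture rate at each step is the mean
proportion of population 2 among callable windows; for the founding pair
the minor component plays population 2, which is immaterial to the center
(the $\pm 1$ encoding is sign-symmetric) and keeps the rate within the
default calibration grid.

## The simulator

`simulate_history()` is an explicit forward-in-time model: a constant-size
population of $N$ diploids; the founding generation $g_0$ formed of
unadmixed migrant individuals in proportions $m_A : 1 - m_A$; each later
generation produced by random mating with replacement, each meiosis drawing
Poisson($L$ Morgans) crossovers uniform on the genetic map (no
interference — standard at admixture-LD timescales); later events inject
unadmixed migrant individuals in their generation; continuous gene flow is
a pulse of the given per-generation rate in every generation of its
interval (`continuous_rate()` converts a target total contribution).
Sampled haplotypes are returned as exact tract mosaics, rasterized onto the
window grid by midpoint label, and summarized into a per-individual Q
matrix by genetic-length-weighted tract fractions — an identity asserted to
$10^{-9}$ in the tests. Everything is reproducible from one integer seed.

What the simulator emulates, and what it does not: it produces the tract
structure, drift-driven individual-level proportion variance, and sampling
noise that the ordering and dating methods consume, and
`apply_call_noise()` adds label-flip errors mimicking local-ancestry
miscalls. It does not emit genotypes, so errors specific to upstream tools
(phasing switch errors, clustering misassignment correlated along the
genome, window-level PCA noise) are only crudely approximated; passing
tests demonstrate the methods' behavior under the stated model, not
robustness to every artifact of real pipelines. Migrants enter unadmixed,
matching the pulse abstraction being dated; real source populations are
proxies at best.

## Scales, defaults and numerical choices

* **Desk-scale genome** (`desk_genome()`): 8 chromosomes × 128 cM, 256
  windows (0.5 cM) each — large enough to hold the block signal out to
  ~200 generations, small enough for thousands of replicates. The
  human-scale layout (1024/512/256 windows, `human_window_scheme()`) is
  available for real panels.
* **Validation scales.** The test suite measures ordering recovery on 200
  replicates per scenario (25 individuals for $K=3$, 50 for $K=4$,
  $N = 500$) and dating recovery on 20 replicates per cell (calibration
  $R = 20$, $N = 500$ for single-pulse grids, $N = 250$ for the two-pulse
  and continuous scenarios); the acceptance script reports the same
  quantities at 100/10 replicates. These sizes were chosen so the full
  validation remains a coffee-break computation on one core.
* **Posterior threshold 0.9** for accepting a local-ancestry call; below
  it a window is `UNRESOLVED` (encoded 0, splits block runs). Upstream
  tools rarely document a universal rule; 0.9 is conservative and
  configurable.
* **Q row sums** within $10^{-3}$ of 1 are renormalized exactly (clustering
  output is rounded text); larger deviations are rejected with the row
  index.
* **Block lengths are window-quantized** (runs × window width), so
  closed-form comparisons inherit a bias of about half a window per block;
  comparisons against $\ell(g,m)$ use grids fine enough to keep that bias
  well inside the stated tolerance.
* **Generation time** defaults to 29 years and is recorded in every date
  report; calendar dates are exactly $g \times$ generation time.
* **Coordinates**: tract files are 0-based half-open (BED convention) in
  cM; windowed files use 0-based window indices; masks serialize as the
  literal token `MASKED`.

## Known limitations

* The founding pair's internal order is unidentifiable by construction.
* **Ordering power depends on how much inter-individual ancestry variance
  survives to the present.** The covariance signal is created at the
  admixture events and diluted by every subsequent generation of random
  mating, down to a floor set by genome granularity (individual ancestry
  sd of order 0.02 after ~20 generations at realistic sizes). With a few
  dozen sampled individuals the trio covariances are then estimated at a
  signal-to-noise near one, and recovery of the event order degrades —
  markedly so for events more than ~50 generations old. Recovery improves
  quickly with the number of sampled individuals (essentially perfect at
  n = 100 in the scenarios of the acceptance suite) and is almost
  independent of population size. Populations whose admixture is recent,
  structured or assortative carry far more individual-level variance than
  neutral random mating predicts, and will be easier to order than the
  simulator suggests.
* Ordering accuracy degrades for components below ~5% final proportion and
  when all component variances are near-equal; both conditions are flagged,
  not silently absorbed.
* Continuous gene flow violates the single-pulse calibration model; the
  method returns one composite date inside the flow interval (the
  acceptance suite verifies this), not the interval itself.
* Dates older than the calibrated grid, or events leaving less than 20% of
  the genome unmasked, are reported as undatable rather than guessed.
* Calibration tables are internally consistent with this package's
  simulator; they are not numerically interchangeable with tables built
  under other simulation models.
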