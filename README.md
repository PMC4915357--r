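# admixwave

Reconstructing the chronology of complex admixture histories from
genome-wide ancestry data: in what **order** did a population's ancestry
components arrive, and **when** did each episode of gene flow happen?

Standard tools assume a tree-like history with at most one admixture
event. `admixwave` is for the other case — populations that received gene
flow repeatedly, from different sources — and provides three pieces that
work together:

* **The admixture history graph (AHG).** When a new component C enters an
  already-admixed population, every individual's older proportions are
  rescaled by the same factor `(1 - q_C)`, so the older components start to
  covary with C while their *ratio* stays independent of it. For each trio
  of components the package computes `|cov(q_A/(q_A+q_B), q_C)|` for all
  three candidate "most recent" assignments and picks the smallest; with
  K components, all C(K,3) trios vote and the full arrival order is peeled
  off newest-first (`trio_statistics()`, `infer_graph()`).
* **Wavelet dating with sequential masking.** Ancestry from a pulse of
  proportion m, g generations ago, survives in blocks of expected length
  `100 / (g (1 - m))` cM. A Haar transform of the ±1-encoded
  local-ancestry signal on 2^n-window chromosomes summarizes block widths
  as a power spectrum; its energy-weighted mean scale (the *wavelet
  center*) is inverted to generations against simulation-derived
  calibration tables (`wavelet_center()`, `build_calibration()`,
  `estimate_generations()`). Events are dated newest-first; each dated
  component's blocks are masked and the identical mask is applied to the
  calibration simulations before the next, older event is dated
  (`date_events()`).
* **A forward admixture simulator.** Wright–Fisher diploids, migrant
  pulses and continuous gene flow, Poisson recombination on a genetic map,
  exact ancestry-tract output rasterized to window grids and summarized to
  Q matrices (`simulate_history()`). It drives all validation and
  calibration.

Readers/writers cover ADMIXTURE-style `.Q` matrices with label files,
HapMap-format genetic maps, windowed local-ancestry calls and BED-like
tract intervals. Results are tibbles with `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

Simulate a three-component history — founding mixture of A and B 45
generations ago, then a pulse of C (30%) 12 generations ago — and recover
both the order and the dates:

```r
library(admixwave)

genome <- desk_genome()   # 8 chromosomes x 128 cM, 256 windows each
history <- admixture_history(
  founding = c("A", "B"), g0 = 45, m_founder = 0.5,
  events = list(admix_pulse(12, "C", 0.3)),
  N = 200, sample_size = 30
)
sim <- simulate_history(history, genome$map, genome$grid, seed = 42)

graph <- infer_graph(sim$q)
graph
#> Admixture history graph
#>   arrival order: (A,B) -> C
#>
#> # A tibble: 1 × 3
#>   trio  chosen_recent  margin
#>   <chr> <chr>           <dbl>
#> 1 A,B,C C             0.00724

dates <- date_events(sim$panel, sim$q, graph,
                     config = list(g_grid = c(6, 15, 30, 50, 75),
                                   R = 20, N = 200, seed = 1))
dates
#> # A tibble: 2 × 9
#>   event type     generations ci_lower ci_upper years m_obs masked_fraction status
#> 1 C     pulse           13.6     12.6     14.4  394. 0.290           0     ok
#> 2 A+B   founding        43.0     39.8     46.1 1247. 0.400           0.290 ok
```

Reading this: the single trio test picks C as the most recent arrival with
a decisive margin (its |cov| is ~0.7% of the runner-up's). Dating then
places the C pulse at 13.6 generations (true value 12) with no masking,
masks the 29% of windows carrying C, and dates the founding mixture at
43.0 generations (true value 45) on the remaining genome — the calibration
simulations carry the identical mask. Years use the default 29
years/generation. Block-length summaries per ancestry are available via
`block_lengths(sim$panel)`.

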