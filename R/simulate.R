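#' Specify a multi-pulse admixture history
#'
#' A history starts with a founding event at generation `g0` before present,
#' mixing two components in proportions `m_founder` and `1 - m_founder`,
#' followed by later events: instantaneous pulses and/or continuous
#' intervals of gene flow. Generations decrease strictly toward the present.
#' The receiving population has constant size `N` diploids, mates randomly
#' with replacement, and migrants enter as unadmixed haplotype pairs.
#'
#' @param founding Character vector of the two founding components.
#' @param g0 Founding generation (generations before present, >= 1).
#' @param m_founder Proportion contributed by `founding[1]`, in (0, 1).
#' @param events List of [admix_pulse()] / [admix_continuous()] entries,
#'   ordered oldest to newest.
#' @param N Diploid population size.
#' @param sample_size Number of haplotypes to sample (even; `<= 2 N`).
#' @param generation_time Years per generation (used downstream for
#'   calendar dates).
#' @return An `admixture_history` object.
#' @export
admixture_history <- function(founding, g0, m_founder, events = list(),
                              N = 500, sample_size = 50,
                              generation_time = 29) {
  if (length(founding) != 2) abort("founding event needs exactly 2 components")
  if (g0 < 1) abort("founding generation must be >= 1")
  if (m_founder <= 0 || m_founder >= 1) abort("m_founder must be in (0, 1)")
  if (sample_size %% 2 != 0) abort("sample_size must be an even haplotype count")
  if (N < sample_size / 2) abort("sample larger than the population (need N >= sample_size / 2)")
  pulses <- expand_events(events)
  if (nrow(pulses) > 0) {
    gens <- c(g0, pulses$g)
    if (any(diff(gens) >= 0)) {
      abort("event generations must strictly decrease toward the present")
    }
    if (any(pulses$m <= 0 | pulses$m >= 1)) {
      abort("event proportions must be in (0, 1)")
    }
    tot <- tapply(pulses$m, pulses$g, sum)
    if (any(tot >= 1)) abort("total migrant proportion in one generation must be < 1")
  }
  structure(list(founding = founding, g0 = as.integer(g0),
                 m_founder = m_founder, events = events, pulses = pulses,
                 N = as.integer(N), sample_size = as.integer(sample_size),
                 generation_time = generation_time),
            class = "admixture_history")
}

#' @rdname admixture_history
#' @param g Event generation (pulse) before present.
#' @param source Source component label.
#' @param m Migrant proportion of the gene pool (per generation for
#'   continuous flow).
#' @export
admix_pulse <- function(g, source, m) {
  list(type = "pulse", g = as.integer(g), source = source, m = m)
}

#' @rdname admixture_history
#' @param g_start,g_end First and last generation of a continuous interval
#'   of gene flow (`g_start > g_end`, both before present); the flow is
#'   modeled as one pulse of proportion `m` in every generation of the
#'   interval.
#' @export
admix_continuous <- function(g_start, g_end, source, m) {
  if (g_start < g_end) abort("g_start must be the older bound (g_start >= g_end)")
  list(type = "continuous", g_start = as.integer(g_start),
       g_end = as.integer(g_end), source = source, m = m)
}

#' Per-generation migrant rate matching a total contribution
#'
#' For continuous flow over `n_gen` generations, the per-generation rate r
#' such that the cumulative contribution is `total`: `1-(1-r)^n_gen = total`.
#'
#' @param total Target cumulative proportion.
#' @param n_gen Number of generations of flow.
#' @return Per-generation rate.
#' @export
continuous_rate <- function(total, n_gen) 1 - (1 - total)^(1 / n_gen)

# flatten events into a per-generation pulse table (g, source, m),
# ordered oldest -> newest
expand_events <- function(events) {
  rows <- purrr::map_dfr(events, function(e) {
    if (e$type == "pulse") {
      tibble::tibble(g = e$g, source = e$source, m = e$m)
    } else {
      tibble::tibble(g = seq(e$g_start, e$g_end), source = e$source, m = e$m)
    }
  })
  if (nrow(rows) == 0) {
    tibble::tibble(g = integer(), source = character(), m = numeric())
  } else {
    rows[order(-rows$g), ]
  }
}

#' Expected final ancestry proportions of a history
#'
#' Each later pulse of proportion m rescales all earlier contributions by
#' (1 - m); the returned proportions sum to 1.
#'
#' @param history An [admixture_history()].
#' @return Named numeric vector over components.
#' @export
expected_proportions <- function(history) {
  comps <- history$founding
  prop <- setNames(c(history$m_founder, 1 - history$m_founder), comps)
  p <- history$pulses
  for (i in seq_len(nrow(p))) {
    prop <- prop * (1 - p$m[i])
    src <- p$source[i]
    prop[src] <- (if (src %in% names(prop)) prop[[src]] else 0) + p$m[i]
  }
  prop
}

#' Components of a history in order of first arrival
#' @param history An [admixture_history()].
#' @return Character vector (founding pair first).
#' @export
history_components <- function(history) {
  unique(c(history$founding, history$pulses$source))
}

#' Closed-form expected tract length of a pulse ancestry
#'
#' In the large-N Markovian limit, ancestry introduced by a single pulse of
#' proportion `m`, `g` generations ago, forms tracts of expected genetic
#' length `100 / (g (1 - m))` cM: recombination has placed `g` crossovers
#' per Morgan of lineage history, of which a fraction `(1 - m)` switch to
#' the other ancestry.
#'
#' @param g Generations since the pulse (>= 1).
#' @param m Pulse proportion, in (0, 1).
#' @return Expected tract length in cM.
#' @export
expected_tract_length <- function(g, m) {
  if (any(g < 1)) abort("g must be >= 1")
  if (any(m <= 0 | m >= 1)) abort("m must be in (0, 1)")
  100 / (g * (1 - m))
}

# low-level simulation: returns the C++ tract table with integer labels
# (1-based into `comps`), haplotypes 1..sample_size
sim_tracts_raw <- function(history, lengths_cM) {
  comps <- history_components(history)
  p <- history$pulses
  res <- .sim_tracts_cpp(
    unname(lengths_cM), history$N, history$g0, history$m_founder,
    match(history$founding[1], comps), match(history$founding[2], comps),
    as.integer(p$g), match(p$source, comps), p$m,
    history$sample_size %/% 2L
  )
  res$comps <- comps
  res
}

#' Simulate an admixture history
#'
#' Runs the forward-in-time tract simulator over the history: the founding
#' generation is formed of unadmixed migrant individuals, each subsequent
#' generation is produced by random mating (each meiosis drawing
#' Poisson(L Morgans) crossovers uniform on the genetic map), and events
#' inject migrant individuals in their generation. The sampled haplotypes
#' are returned as exact tract mosaics, rasterized onto `grid`, and
#' summarized into a per-individual Q matrix by genetic-length-weighted
#' ancestry fractions.
#'
#' @param history An [admixture_history()].
#' @param map Optional [genetic_map()]; only the chromosome genetic lengths
#'   enter the simulation. Defaults to the lengths of `grid`.
#' @param grid A `window_grid` defining the rasterization.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `simulated_sample` list with elements `tracts` (tibble),
#'   `panel` ([ancestry_panel()]), `q` ([q_matrix()]), `history`, `seed`.
#' @export
simulate_history <- function(history, map = NULL, grid, seed) {
  lens <- if (is.null(map)) grid_lengths(grid) else chrom_lengths(map)
  counts <- grid_counts(grid)
  if (!all(names(counts) %in% names(lens))) {
    abort("grid chromosomes missing from the map")
  }
  lens <- lens[names(counts)]
  set.seed(seed)
  raw <- sim_tracts_raw(history, lens)
  comps <- raw$comps
  chroms <- names(lens)
  tracts <- tibble::tibble(
    haplotype = sprintf("hap%03d", raw$hap),
    chrom = chroms[raw$chrom],
    start_cM = raw$start_cM,
    end_cM = raw$end_cM,
    label = comps[raw$label]
  )
  # Q per individual: genetic-length-weighted ancestry of its two haplotypes
  genome <- sum(lens)
  ind <- (raw$hap + 1L) %/% 2L
  qm <- matrix(0, nrow = history$sample_size %/% 2L, ncol = length(comps),
               dimnames = list(NULL, comps))
  wlen <- raw$end_cM - raw$start_cM
  for (k in seq_along(comps)) {
    sel <- raw$label == k
    if (any(sel)) {
      s <- tapply(wlen[sel], ind[sel], sum)
      qm[as.integer(names(s)), k] <- s / (2 * genome)
    }
  }
  q <- q_matrix(qm, ids = paste0("sim", seq_len(nrow(qm))),
                components = comps, tol = 1e-9)
  # rasterize via the matrix fast path (simulated tracts are contiguous)
  mats <- raster_label_matrices(raw, lens, counts)
  lab_mat <- do.call(cbind, mats)
  H <- nrow(lab_mat)
  panel <- new_ancestry_panel(tibble::tibble(
    haplotype = rep(sprintf("hap%03d", seq_len(H)), each = ncol(lab_mat)),
    chrom = rep(rep(names(counts), counts), times = H),
    window = rep(unlist(lapply(counts, function(w) seq_len(w) - 1L),
                        use.names = FALSE), times = H),
    label = comps[as.vector(t(lab_mat))],
    posterior = 1
  ), grid, comps)
  structure(list(tracts = tracts, panel = panel, q = q, history = history,
                 seed = seed), class = "simulated_sample")
}

#' Add ancestry-call noise to a panel
#'
#' Emulates local-ancestry assignment error: each callable window is,
#' independently with probability `error_rate`, reassigned to a uniformly
#' random *different* label from the panel's label set. `MASKED` and
#' `UNRESOLVED` windows are untouched.
#'
#' @param panel An [ancestry_panel()].
#' @param error_rate Per-window error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return An [ancestry_panel()].
#' @export
apply_call_noise <- function(panel, error_rate, seed) {
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  labels <- panel_labels(panel)
  if (error_rate == 0) return(panel)
  set.seed(seed)
  callable <- which(panel$label %in% labels)
  flip <- callable[stats::runif(length(callable)) < error_rate]
  if (length(flip) > 0 && length(labels) > 1) {
    cur <- match(panel$label[flip], labels)
    shift <- 1L + floor(stats::runif(length(flip)) * (length(labels) - 1L))
    panel$label[flip] <- labels[1L + (cur - 1L + shift) %% length(labels)]
  }
  new_ancestry_panel(panel, panel_grid(panel), labels)
}
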