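# ---- internal fast path: single-pulse simulation straight to a center ----

# rasterize the raw C++ tract table to per-chromosome label matrices
# (haplotypes x windows, integer labels)
raster_label_matrices <- function(raw, lens, counts) {
  H <- max(raw$hap)
  out <- vector("list", length(counts))
  for (c_i in seq_along(counts)) {
    sel <- raw$chrom == c_i
    ends <- raw$end_cM[sel]
    labs <- raw$label[sel]
    haps <- raw$hap[sel]
    W <- counts[[c_i]]
    mids <- (seq_len(W) - 0.5) * (lens[[c_i]] / W)
    M <- matrix(0L, H, W)
    idx <- split(seq_along(ends), haps)
    for (h in names(idx)) {
      ii <- idx[[h]]
      j <- pmin(findInterval(mids, ends[ii]) + 1L, length(ii))
      M[as.integer(h), ] <- labs[ii][j]
    }
    out[[c_i]] <- M
  }
  names(out) <- names(counts)
  out
}

# pooled center of +/-1 signal matrices; mask: list of logical matrices
center_of_matrices <- function(mats, widths, mask = NULL) {
  by_chrom <- purrr::map_dfr(seq_along(mats), function(c_i) {
    S <- mats[[c_i]]
    if (!is.null(mask)) S[mask[[c_i]]] <- 0
    he <- haar_energy_matrix(S)
    n <- length(he$energy)
    tibble::tibble(chrom = names(mats)[c_i], scale = seq_len(n),
                   width_cM = widths[[c_i]] * 2^seq_len(n),
                   energy = he$energy, count = he$count)
  })
  summarize_levels(by_chrom)$center
}

# one single-pulse simulation (ancestry "2" at proportion m, g generations
# ago) -> wavelet center; draws from the current RNG stream
sim_center_once <- function(g, m, lens, counts, N, n_hap, mask = NULL) {
  raw <- .sim_tracts_cpp(unname(lens), N, as.integer(g), m, 2L, 1L,
                         integer(0), integer(0), numeric(0), n_hap %/% 2L)
  mats <- raster_label_matrices(raw, lens, counts)
  sig <- lapply(mats, function(M) {
    S <- matrix(-1, nrow(M), ncol(M))
    S[M == 2L] <- 1
    S
  })
  center_of_matrices(sig, lens[names(counts)] / counts, mask = mask)
}

# convert a mask position tibble into per-chromosome logical matrices laid
# out like the simulated haplotypes (mapped by haplotype order index)
mask_matrices <- function(mask, grid, hap_ids) {
  counts <- grid_counts(grid)
  H <- length(hap_ids)
  out <- lapply(counts, function(W) matrix(FALSE, H, W))
  if (is.null(mask) || nrow(mask) == 0) return(out)
  hi <- match(mask$haplotype, hap_ids)
  if (any(is.na(hi))) abort("mask haplotypes do not match the panel")
  for (ch in unique(mask$chrom)) {
    sel <- mask$chrom == ch
    out[[ch]][cbind(hi[sel], mask$window[sel] + 1L)] <- TRUE
  }
  out
}

randomize_mask <- function(mask_mats) {
  lapply(mask_mats, function(M) {
    k <- sum(M)
    R <- matrix(FALSE, nrow(M), ncol(M))
    if (k > 0) R[sample(length(M), k)] <- TRUE
    R
  })
}

# ---- calibration ----

#' Build a simulation calibration table for wavelet dating
#'
#' For every cell of a (generations, admixture rate) grid, simulates `R`
#' independent single-pulse histories on the configured genome, applies the
#' given mask to the simulated signals, and records the mean and spread of
#' the wavelet center. The resulting table maps an observed center back to
#' generations since admixture at the matched admixture rate and mask.
#' Center means are checked for monotonicity in g at fixed m; offending
#' cells are flagged.
#'
#' @param g_grid Ascending generations grid.
#' @param m_grid Admixture-rate grid.
#' @param mask Optional mask: a tibble `(haplotype, chrom, window)` as
#'   produced by [mask_ancestry()], applied to every simulated panel.
#' @param sim_config List: `grid` (window grid; default [desk_genome()]),
#'   `N` (diploid population size, default 500), `sample_haplotypes`
#'   (default 50), `hap_ids` (observed haplotype ids the mask refers to),
#'   `mask_mode` (`"positions"` applies the mask verbatim; `"random"`
#'   re-draws a random mask of the same per-chromosome size each
#'   replicate).
#' @param R Replicates per cell (>= 20).
#' @param seed Integer seed; the table is fully reproducible from it.
#' @return A `calibration_table`: tibble `(g, m, center_mean, center_sd,
#'   R)` with metadata attributes (`seed`, `N`, `sample_haplotypes`,
#'   `masked_fraction`, `mask_mode`, `m_step`, `flags`, `replicates`).
#' @export
build_calibration <- function(g_grid = seq(5, 200, by = 5),
                              m_grid = seq(0.05, 0.5, by = 0.05),
                              mask = NULL, sim_config = list(), R = 20,
                              seed = 1) {
  if (R < 20) abort("use at least R = 20 replicates per cell")
  if (is.unsorted(g_grid, strictly = TRUE)) abort("g_grid must be ascending")
  cfg <- utils::modifyList(
    list(grid = NULL, N = 500, sample_haplotypes = 50, hap_ids = NULL,
         mask_mode = "positions"),
    sim_config
  )
  grid <- if (is.null(cfg$grid)) desk_genome()$grid else cfg$grid
  counts <- grid_counts(grid)
  lens <- grid_lengths(grid)[names(counts)]
  n_hap <- cfg$sample_haplotypes
  hap_ids <- cfg$hap_ids
  mask_mats <- NULL
  masked_frac <- 0
  if (!is.null(mask) && nrow(mask) > 0) {
    if (is.null(hap_ids)) hap_ids <- unique(mask$haplotype)
    n_hap <- length(hap_ids)
    if (n_hap %% 2 == 1) abort("mask must cover an even haplotype count")
    mask_mats <- mask_matrices(mask, grid, hap_ids)
    masked_frac <- sum(vapply(mask_mats, sum, numeric(1))) /
      (n_hap * sum(counts))
  }
  set.seed(seed)
  reps <- purrr::map_dfr(m_grid, function(m) {
    purrr::map_dfr(g_grid, function(g) {
      centers <- vapply(seq_len(R), function(r) {
        mm <- mask_mats
        if (!is.null(mm) && cfg$mask_mode == "random") mm <- randomize_mask(mm)
        sim_center_once(g, m, lens, counts, cfg$N, n_hap, mask = mm)
      }, numeric(1))
      tibble::tibble(g = g, m = m, rep = seq_len(R), center = centers)
    })
  })
  tab <- reps %>%
    dplyr::group_by(.data$g, .data$m) %>%
    dplyr::summarise(center_mean = mean(.data$center),
                     center_sd = sd(.data$center), R = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(.data$m, .data$g)
  flags <- tab %>%
    dplyr::group_by(.data$m) %>%
    dplyr::mutate(non_monotone = c(FALSE, diff(.data$center_mean) > 0)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$non_monotone)
  if (nrow(flags) > 0) {
    warn(paste0(nrow(flags), " calibration cell(s) non-monotone in g; ",
                "flagged (increase R or widen the grid)"))
  }
  structure(tab,
            seed = seed, N = cfg$N, sample_haplotypes = n_hap,
            mask_mode = cfg$mask_mode, masked_fraction = masked_frac,
            m_step = if (length(m_grid) > 1) min(diff(sort(m_grid))) else 0.05,
            flags = flags, replicates = reps,
            class = c("calibration_table", class(tab)))
}

#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$g, y = .data$center_mean,
                                       colour = factor(.data$m))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$center_mean - .data$center_sd,
      ymax = .data$center_mean + .data$center_sd)) +
    ggplot2::labs(x = "generations since admixture",
                  y = "wavelet center (level index)",
                  colour = "admixture rate m",
                  title = "Calibration: wavelet center vs admixture age") +
    ggplot2::theme_minimal()
}

#' Convert generations to calendar years
#'
#' @param g Generations.
#' @param generation_time Years per generation (default 29).
#' @return `g * generation_time` years.
#' @export
generations_to_years <- function(g, generation_time = 29) {
  if (generation_time <= 0) abort("generation_time must be > 0")
  g * generation_time
}

#' Date one admixture event from a wavelet summary
#'
#' Selects the calibration column with admixture rate nearest the observed
#' rate (it must lie within one grid step), inverts the monotone
#' center-to-generations relation by linear interpolation (after an
#' isotonic fit that irons out simulation jitter), and attaches a 2.5-97.5%
#' confidence interval from a chromosome bootstrap: chromosomes are
#' resampled with replacement, the center re-pooled and re-inverted.
#'
#' @param summary A `wavelet_summary` from [wavelet_center()].
#' @param m_obs Observed admixture proportion of population 2.
#' @param table A [build_calibration()] table.
#' @param n_boot Bootstrap draws (default 200).
#' @param seed Seed for the bootstrap.
#' @param generation_time Years per generation.
#' @param event Optional event label carried into the result.
#' @return A `date_estimate`: list with `event`, `generations`, `ci_lower`,
#'   `ci_upper`, `years`, `m_obs`, `m_used`, `masked_fraction`, `center`,
#'   `warnings`.
#' @export
estimate_generations <- function(summary, m_obs, table, n_boot = 200,
                                 seed = 1, generation_time = 29,
                                 event = NA_character_) {
  ms <- unique(table$m)
  m_used <- ms[which.min(abs(ms - m_obs))]
  if (abs(m_used - m_obs) > attr(table, "m_step") + 1e-9) {
    abort(paste0("calibration table does not cover m = ", format(m_obs),
                 " within one grid step"))
  }
  col <- table[table$m == m_used, ]
  col <- col[order(col$g), ]
  # monotone (non-increasing in g) fit of the center means
  iso <- -stats::isoreg(col$g, -col$center_mean)$yf
  invert <- function(center) {
    if (center > max(iso) + 1e-12 || center < min(iso) - 1e-12) return(NA_real_)
    approx(x = iso, y = col$g, xout = center, ties = mean)$y
  }
  point <- invert(summary$center)
  if (is.na(point)) {
    abort(paste0("date beyond calibrated range: observed center ",
                 format(round(summary$center, 3)), " outside [",
                 format(round(min(iso), 3)), ", ",
                 format(round(max(iso), 3)),
                 "]; extend g_grid or accept the resolution limit"))
  }
  chroms <- unique(summary$by_chrom$chrom)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    draw <- sample(chroms, length(chroms), replace = TRUE)
    bc <- purrr::map_dfr(seq_along(draw), function(i) {
      summary$by_chrom[summary$by_chrom$chrom == draw[i], ]
    })
    ctr <- summarize_levels(bc)$center
    # out-of-range draws are clamped to the calibrated ends
    g <- invert(min(max(ctr, min(iso)), max(iso)))
    g
  }, numeric(1))
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  ci <- c(min(ci[1], point), max(ci[2], point))
  warnings <- character()
  if (nrow(attr(table, "flags")) > 0) {
    warnings <- c(warnings, "calibration table has non-monotone cells")
  }
  structure(list(event = event, generations = point, ci_lower = ci[1],
                 ci_upper = ci[2],
                 years = generations_to_years(point, generation_time),
                 m_obs = m_obs, m_used = m_used,
                 masked_fraction = attr(table, "masked_fraction"),
                 center = summary$center,
                 generation_time = generation_time, warnings = warnings),
            class = "date_estimate")
}

#' @export
print.date_estimate <- function(x, ...) {
  cat("Admixture date estimate", if (!is.na(x$event)) paste0(" [", x$event, "]"),
      "\n", sep = "")
  cat(sprintf("  %.1f generations (95%% CI %.1f-%.1f); %.0f years at %g y/gen\n",
              x$generations, x$ci_lower, x$ci_upper, x$years,
              x$generation_time))
  cat(sprintf("  m observed %.3f, calibrated at m = %.2f, masked fraction %.3f\n",
              x$m_obs, x$m_used, x$masked_fraction))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.date_estimate <- function(x, ...) {
  tibble::tibble(event = x$event, generations = x$generations,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 years = x$years, m_obs = x$m_obs, m_used = x$m_used,
                 masked_fraction = x$masked_fraction, center = x$center)
}

#' Sequentially date all admixture events of an inferred history
#'
#' Walks the arrival order newest to oldest. At each step the most recent
#' undated component becomes "population 2" and everything older
#' "population 1" ([merge_ancestries()]); the wavelet center of the merged
#' signal is dated against a calibration table built under the cumulative
#' mask; then the component's blocks are masked out and the walk continues.
#' The founding pair is dated last, against each other (the minor component
#' plays population 2), under the cumulative mask. The observed admixture
#' rate at each step is the mean proportion of population 2 among callable
#' windows.
#'
#' @param panel An [ancestry_panel()] whose labels cover the graph's
#'   components.
#' @param q A [q_matrix()] (kept for reporting; rates are measured on the
#'   panel).
#' @param graph An `ahg` from [infer_graph()], or `NULL` for a two-ancestry
#'   panel (single event, no masking).
#' @param config List of options: `g_grid`, `m_grid`, `R`, `N`, `seed`,
#'   `generation_time`, `n_boot`, `max_masked_fraction` (refuse dating past
#'   this cumulative mask, default 0.8), `mask_mode`, `grid`.
#' @return A `date_report`: tibble with one row per event, newest first
#'   (`event`, `type`, `generations`, `ci_lower`, `ci_upper`, `years`,
#'   `m_obs`, `m_used`, `masked_fraction`, `status`), with the
#'   `date_estimate` objects in attribute `"estimates"`.
#' @export
date_events <- function(panel, q = NULL, graph = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(g_grid = seq(10, 160, by = 10), m_grid = seq(0.05, 0.5, by = 0.05),
         R = 20, N = 500, seed = 1, generation_time = 29, n_boot = 200,
         max_masked_fraction = 0.8, mask_mode = "positions", grid = NULL),
    config
  )
  grid <- if (is.null(cfg$grid)) panel_grid(panel) else cfg$grid
  labels <- panel_labels(panel)
  if (is.null(graph)) {
    if (length(labels) != 2) {
      abort("graph is required unless the panel has exactly 2 ancestries")
    }
    order <- list(sort(labels))
  } else {
    order <- graph$arrival_order
    comps <- unlist(order)
    if (!all(comps %in% labels)) {
      abort(paste0("graph components missing from panel: ",
                   paste(setdiff(comps, labels), collapse = ", ")))
    }
  }
  later <- rev(unlist(order[-1]))  # newest first
  hap_ids <- unique(panel$haplotype)
  cum_mask <- NULL
  panel_cur <- panel
  estimates <- list()
  step <- 0

  date_step <- function(older, recent, event, type) {
    step <<- step + 1
    merged <- merge_ancestries(panel_cur, older, recent)
    callable <- merged$label %in% c("1", "2")
    m_obs <- mean(merged$label[callable] == "2")
    m_used <- cfg$m_grid[which.min(abs(cfg$m_grid - m_obs))]
    tab <- build_calibration(
      g_grid = cfg$g_grid, m_grid = m_used, mask = cum_mask,
      sim_config = list(grid = grid, N = cfg$N,
                        sample_haplotypes = length(hap_ids),
                        hap_ids = hap_ids, mask_mode = cfg$mask_mode),
      R = cfg$R, seed = cfg$seed + step
    )
    summ <- wavelet_center(merged, grid)
    est <- tryCatch(
      estimate_generations(summ, m_obs, tab, n_boot = cfg$n_boot,
                           seed = cfg$seed + step,
                           generation_time = cfg$generation_time,
                           event = event),
      error = function(e) {
        structure(list(event = event, generations = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_,
                       years = NA_real_, m_obs = m_obs, m_used = m_used,
                       masked_fraction = masked_fraction(panel_cur),
                       center = summ$center,
                       generation_time = cfg$generation_time,
                       warnings = conditionMessage(e)),
                  class = "date_estimate")
      }
    )
    est$type <- type
    est
  }

  refused <- character()
  for (i in seq_along(later)) {
    x <- later[i]
    if (masked_fraction(panel_cur) > cfg$max_masked_fraction) {
      refused <- c(refused, later[i:length(later)], "founding")
      break
    }
    older <- setdiff(unlist(order), c(x, later[seq_len(i - 1)]))
    estimates[[x]] <- date_step(older, x, event = x, type = "pulse")
    mk <- mask_ancestry(panel_cur, x)
    panel_cur <- mk$panel
    cum_mask <- dplyr::bind_rows(cum_mask, mk$mask)
  }
  if (!"founding" %in% refused) {
    if (masked_fraction(panel_cur) > cfg$max_masked_fraction) {
      refused <- c(refused, "founding")
    } else {
      pair <- order[[1]]
      callable <- panel_cur$label %in% pair
      p2 <- if (mean(panel_cur$label[callable] == pair[2]) <= 0.5) {
        pair[2]
      } else {
        pair[1]
      }
      estimates[["founding"]] <- date_step(setdiff(pair, p2), p2,
                                           event = paste(pair, collapse = "+"),
                                           type = "founding")
    }
  }
  if (length(refused) > 0) {
    warn(paste0("insufficient genome remains (masked fraction > ",
                cfg$max_masked_fraction, "); not dating: ",
                paste(refused, collapse = ", ")))
  }
  rows <- purrr::map_dfr(estimates, function(e) {
    dplyr::mutate(tidy(e), type = e$type,
                  status = if (is.na(e$generations)) "undatable" else "ok")
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(event = character(), type = character(),
                           generations = numeric(), ci_lower = numeric(),
                           ci_upper = numeric(), years = numeric(),
                           m_obs = numeric(), m_used = numeric(),
                           masked_fraction = numeric(), center = numeric(),
                           status = character())
  }
  structure(rows[, c("event", "type", "generations", "ci_lower", "ci_upper",
                     "years", "m_obs", "m_used", "masked_fraction", "center",
                     "status")],
            estimates = estimates, refused = refused,
            class = c("date_report", class(rows)))
}

#' @export
autoplot.date_report <- function(object, ...) {
  df <- object[!is.na(object$generations), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generations,
                                   y = stats::reorder(.data$event,
                                                      .data$generations))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::labs(x = "generations before present", y = "admixture event",
                  title = "Sequentially dated admixture events") +
    ggplot2::theme_minimal()
}
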