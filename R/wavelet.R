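#' Merge older ancestries into a binary panel
#'
#' Sequential dating treats the genome as two populations: everything
#' contributed by the older admixture events ("population 1", label `"1"`)
#' versus the most recent contributor ("population 2", label `"2"`).
#' `MASKED` and `UNRESOLVED` windows are preserved.
#'
#' @param panel An [ancestry_panel()].
#' @param older Character vector of the older ancestry labels.
#' @param recent The most recent ancestry label.
#' @return A binary [ancestry_panel()] with labels `"1"`, `"2"`.
#' @export
merge_ancestries <- function(panel, older, recent) {
  labels <- panel_labels(panel)
  if (length(intersect(older, recent)) > 0) {
    abort("older and recent label sets must be disjoint")
  }
  if (!all(c(older, recent) %in% labels)) {
    abort(paste0("labels not in panel: ",
                 paste(setdiff(c(older, recent), labels), collapse = ", ")))
  }
  stray <- setdiff(unique(panel$label),
                   c(older, recent, .MASKED, .UNRESOLVED))
  if (length(stray) > 0) {
    abort(paste0("panel contains unassigned label(s): ",
                 paste(stray, collapse = ", ")))
  }
  lab <- panel$label
  lab[lab %in% older] <- "1"
  lab[lab %in% recent] <- "2"
  out <- panel
  out$label <- lab
  new_ancestry_panel(out, panel_grid(panel), c("1", "2"))
}

#' Encode a binary panel as +/-1 window signals
#'
#' Population 1 maps to -1, population 2 to +1, `MASKED`/`UNRESOLVED` to 0,
#' giving one length-2^n numeric sequence per haplotype and chromosome.
#'
#' @param panel A binary [ancestry_panel()] (labels `"1"`, `"2"`).
#' @param grid The panel's `window_grid` (defaults to the panel attribute).
#' @return An `ancestry_signals` object: list of haplotype x window
#'   matrices, one per chromosome, with attributes `widths` (window width
#'   per chromosome, cM) and `callable_fraction`.
#' @export
encode_signal <- function(panel, grid = panel_grid(panel)) {
  labels <- panel_labels(panel)
  if (length(labels) == 0) abort("panel has an empty label set")
  if (!identical(sort(labels), c("1", "2"))) {
    abort("encode_signal expects a binary panel (merge_ancestries first)")
  }
  counts <- grid_counts(grid)
  lens <- grid_lengths(grid)
  haps <- unique(panel$haplotype)
  val <- ifelse(panel$label == "2", 1, ifelse(panel$label == "1", -1, 0))
  sig <- lapply(names(counts), function(ch) {
    sel <- panel$chrom == ch
    # canonical panel order: haplotype-major, window-minor
    matrix(val[sel], nrow = length(haps), ncol = counts[[ch]], byrow = TRUE,
           dimnames = list(unique(panel$haplotype[sel]), NULL))
  })
  names(sig) <- names(counts)
  structure(sig,
            widths = setNames(lens[names(counts)] / counts, names(counts)),
            callable_fraction = mean(val != 0),
            class = "ancestry_signals")
}

# Haar detail energies of a signal matrix (rows = signals), one row per
# scale: total squared detail coefficients and coefficient counts.
haar_energy_matrix <- function(M) {
  w <- ncol(M)
  n <- as.integer(round(log2(w)))
  if (2^n != w || n < 1) abort("signal length must be 2^n, n >= 1")
  energy <- numeric(n)
  count <- numeric(n)
  S <- M
  for (j in seq_len(n)) {
    odd <- S[, seq(1, ncol(S), 2), drop = FALSE]
    even <- S[, seq(2, ncol(S), 2), drop = FALSE]
    D <- (odd - even) / sqrt(2)
    S <- (odd + even) / sqrt(2)
    energy[j] <- sum(D^2)
    count[j] <- length(D)
  }
  list(energy = energy, count = count)
}

#' Haar wavelet power spectrum of one window signal
#'
#' Computes the orthonormal Haar detail coefficients of a length-2^n
#' sequence at scales `j = 1` (finest, adjacent-window differences) to `n`
#' (coarsest) and returns the mean squared detail coefficient per scale.
#' By Parseval's identity the count-weighted total,
#' `sum(power_j * 2^(n-j)) / 2^n`, equals the population variance of the
#' signal. A constant signal yields all-zero power with a warning, since it
#' carries no admixture signal to date.
#'
#' @param signal Numeric vector of length 2^n.
#' @return Numeric vector of length n: mean squared detail per scale,
#'   fine to coarse.
#' @export
haar_power <- function(signal) {
  he <- haar_energy_matrix(matrix(signal, nrow = 1))
  if (all(he$energy == 0)) warn("constant signal: no admixture signal")
  he$energy / he$count
}

#' Pooled wavelet summary and block-width center of a panel
#'
#' Pools Haar detail energies over all haplotypes and chromosomes. Scales
#' from chromosomes with different window counts are aligned on the genetic
#' width axis: a scale-j coefficient on a chromosome with window width w
#' describes ancestry-block structure at width `w * 2^j` cM, and energies
#' are pooled per distinct width. The *wavelet center* is the
#' energy-weighted mean level index on that pooled axis (1 = finest);
#' coarser centers mean wider blocks, hence more recent admixture.
#'
#' @param signals An `ancestry_signals` object from [encode_signal()], or a
#'   binary [ancestry_panel()].
#' @param grid Grid; defaults to the signals' own.
#' @return A `wavelet_summary` object: list with `levels` (pooled tibble:
#'   `level`, `width_cM`, `energy`, `count`, `power`, `p_norm`),
#'   `by_chrom` (per-chromosome energies), `center`, `callable_fraction`,
#'   `total_energy`, `total_windows`, `pooled_variance`.
#' @export
wavelet_center <- function(signals, grid = NULL) {
  if (inherits(signals, "ancestry_panel")) {
    if (is.null(grid)) grid <- panel_grid(signals)
    signals <- encode_signal(signals, grid)
  }
  widths <- attr(signals, "widths")
  by_chrom <- purrr::map_dfr(names(signals), function(ch) {
    he <- haar_energy_matrix(signals[[ch]])
    n <- length(he$energy)
    tibble::tibble(chrom = ch, scale = seq_len(n),
                   width_cM = widths[[ch]] * 2^seq_len(n),
                   energy = he$energy, count = he$count)
  })
  sm <- summarize_levels(by_chrom)
  total_windows <- sum(vapply(signals, length, numeric(1)))
  pooled_var <- pooled_signal_variance(signals)
  structure(list(levels = sm$levels, by_chrom = by_chrom,
                 center = sm$center,
                 callable_fraction = attr(signals, "callable_fraction"),
                 total_energy = sum(by_chrom$energy),
                 total_windows = total_windows,
                 pooled_variance = pooled_var),
            class = "wavelet_summary")
}

summarize_levels <- function(by_chrom) {
  lev <- by_chrom %>%
    dplyr::group_by(width_cM = round(.data$width_cM, 9)) %>%
    dplyr::summarise(energy = sum(.data$energy), count = sum(.data$count),
                     .groups = "drop") %>%
    dplyr::arrange(.data$width_cM) %>%
    dplyr::mutate(level = dplyr::row_number(),
                  power = .data$energy / .data$count)
  tot <- sum(lev$energy)
  if (tot == 0) {
    abort("cannot date: single ancestry (all signals constant)")
  }
  lev$p_norm <- lev$energy / tot
  list(levels = lev[, c("level", "width_cM", "energy", "count", "power",
                        "p_norm")],
       center = sum(lev$level * lev$p_norm))
}

pooled_signal_variance <- function(signals) {
  ss <- 0
  sm <- 0
  nw <- 0
  for (M in signals) {
    mu <- rowMeans(M)
    ss <- ss + sum(M^2)
    sm <- sm + sum(mu^2) * ncol(M)
    nw <- nw + length(M)
  }
  (ss - sm) / nw
}

#' @export
print.wavelet_summary <- function(x, ...) {
  cat("Wavelet block-width summary\n")
  cat("  center: ", format(round(x$center, 4)),
      " (level index, 1 = finest)\n", sep = "")
  cat("  callable fraction: ", format(round(x$callable_fraction, 4)), "\n",
      sep = "")
  print(x$levels)
  invisible(x)
}

#' @export
tidy.wavelet_summary <- function(x, ...) x$levels

#' @export
glance.wavelet_summary <- function(x, ...) {
  tibble::tibble(center = x$center,
                 callable_fraction = x$callable_fraction,
                 total_energy = x$total_energy,
                 pooled_variance = x$pooled_variance)
}

#' @export
autoplot.wavelet_summary <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = factor(round(.data$width_cM, 2)),
                               y = .data$p_norm)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$center, linetype = 2) +
    ggplot2::labs(x = "block width scale (cM)", y = "normalized power",
                  title = "Haar power spectrum of the ancestry signal") +
    ggplot2::theme_minimal()
}

#' Block lengths of each ancestry on the rasterized grid
#'
#' Maximal runs of identical ancestry labels are converted to genetic
#' lengths (run length x window width). `MASKED` and `UNRESOLVED` windows
#' interrupt runs and contribute no blocks, so lengths are quantized to the
#' window width.
#'
#' @param panel An [ancestry_panel()].
#' @param grid Grid (defaults to the panel's).
#' @param ancestries Labels to summarize (default: all panel labels).
#' @return A `block_length_summary`: list with `blocks` (tibble
#'   `haplotype`, `chrom`, `ancestry`, `length_cM`) and `summary` (tibble
#'   `ancestry`, `n_blocks`, `mean_cM`, `var_cM`).
#' @export
block_lengths <- function(panel, grid = panel_grid(panel),
                          ancestries = panel_labels(panel)) {
  counts <- grid_counts(grid)
  lens <- grid_lengths(grid)
  widths <- lens[names(counts)] / counts
  blocks <- panel %>%
    dplyr::group_by(.data$haplotype, .data$chrom) %>%
    dplyr::reframe({
      r <- rle(.data$label)
      w <- widths[[dplyr::cur_group()$chrom]]
      tibble::tibble(ancestry = r$values, length_cM = r$lengths * w)
    }) %>%
    dplyr::filter(.data$ancestry %in% ancestries) %>%
    tibble::as_tibble()
  summary <- blocks %>%
    dplyr::group_by(ancestry = factor(.data$ancestry, levels = ancestries)) %>%
    dplyr::summarise(n_blocks = dplyr::n(), mean_cM = mean(.data$length_cM),
                     var_cM = var(.data$length_cM), .groups = "drop") %>%
    dplyr::mutate(ancestry = as.character(.data$ancestry))
  structure(list(blocks = blocks, summary = summary),
            class = "block_length_summary")
}

#' @export
tidy.block_length_summary <- function(x, ...) x$summary

#' @export
print.block_length_summary <- function(x, ...) {
  cat("Ancestry block lengths (window-quantized)\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.block_length_summary <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$length_cM, colour = .data$ancestry)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "block genetic length (cM)",
                  y = "cumulative fraction of blocks",
                  title = "Block-length distribution per ancestry") +
    ggplot2::theme_minimal()
}

#' Mask all windows of one ancestry
#'
#' Used by sequential dating: after the most recent event is dated, its
#' ancestry blocks are excluded so the remaining genome can be analyzed for
#' the earlier events.
#'
#' @param panel An [ancestry_panel()].
#' @param label Ancestry label to mask; must be present in the panel.
#' @return List with `panel` (the masked panel), `mask` (tibble
#'   `haplotype`, `chrom`, `window` of newly masked positions) and
#'   `masked_fraction` (total `MASKED` fraction of the returned panel,
#'   cumulative over successive maskings).
#' @export
mask_ancestry <- function(panel, label) {
  hit <- panel$label == label
  if (!any(hit)) {
    abort(paste0("label ", label, " absent from the panel; nothing to mask"))
  }
  mask <- tibble::as_tibble(panel)[hit, c("haplotype", "chrom", "window")]
  out <- panel
  out$label[hit] <- .MASKED
  out <- new_ancestry_panel(out, panel_grid(panel),
                            setdiff(panel_labels(panel), label))
  list(panel = out, mask = mask, masked_fraction = masked_fraction(out))
}
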