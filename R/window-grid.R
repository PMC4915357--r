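#' Window grids
#'
#' The wavelet machinery requires each chromosome to be partitioned into a
#' power-of-two number of equal-genetic-width, half-open windows covering
#' `[0, L)` cM. A window grid is a tibble with columns `chrom`, `window`
#' (0-based index), `start_cM`, `end_cM`, carrying the per-chromosome window
#' counts and lengths as attributes.
#'
#' @param map A [genetic_map()].
#' @param scheme Named integer vector mapping each chromosome in `map` to its
#'   window count; every count must be a power of two (>= 2).
#' @return A `window_grid` tibble.
#' @export
build_window_grid <- function(map, scheme) {
  lens <- chrom_lengths(map)
  chroms <- names(lens)
  if (!all(chroms %in% names(scheme))) {
    missing <- setdiff(chroms, names(scheme))
    abort(paste0("scheme missing chromosomes: ", paste(missing, collapse = ", ")))
  }
  counts <- as.integer(scheme[chroms])
  bad <- counts < 2 | bitwAnd(counts, counts - 1L) != 0L
  if (any(bad)) {
    abort(paste0("window counts must be powers of two >= 2; got ",
                 paste(counts[bad], collapse = ", ")))
  }
  grid <- purrr::map2_dfr(chroms, counts, function(ch, w) {
    width <- lens[[ch]] / w
    idx <- seq_len(w) - 1L
    tibble::tibble(chrom = ch, window = idx,
                   start_cM = idx * width, end_cM = (idx + 1L) * width)
  })
  new_window_grid(grid, counts = setNames(counts, chroms), lengths = lens)
}

new_window_grid <- function(grid, counts, lengths) {
  grid <- tibble::as_tibble(grid)
  attr(grid, "counts") <- counts
  attr(grid, "lengths") <- lengths
  class(grid) <- c("window_grid", class(tibble::tibble()))
  grid
}

#' @rdname build_window_grid
#' @param grid A `window_grid`.
#' @export
grid_counts <- function(grid) attr(grid, "counts")

#' @rdname build_window_grid
#' @export
grid_lengths <- function(grid) attr(grid, "lengths")

#' Human-default window scheme
#'
#' The layout used for genome-wide human data: 1024 windows on chromosomes
#' 1-8, 512 on chromosomes 9-18 and 20, and 256 on chromosomes 19, 21 and 22,
#' keeping the marker density per window roughly constant across chromosome
#' sizes.
#'
#' @return Named integer vector of window counts per autosome.
#' @export
human_window_scheme <- function() {
  n <- c(rep(1024L, 8), rep(512L, 10), 256L, 512L, 256L, 256L)
  setNames(n, as.character(1:22))
}

#' Desk-scale simulation genome
#'
#' A compact genome used throughout validation and calibration: 8 chromosomes
#' of 128 cM each, 256 windows (0.5 cM) per chromosome. Small enough to
#' simulate thousands of replicates, large enough to hold the block-length
#' signal of admixture up to a couple of hundred generations old.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_cM Genetic length per chromosome, cM.
#' @param windows Windows per chromosome (power of two).
#' @return List with elements `map` (a [genetic_map()]) and `grid`
#'   (a `window_grid`).
#' @export
desk_genome <- function(n_chrom = 8, chrom_cM = 128, windows = 256) {
  lens <- setNames(rep(chrom_cM, n_chrom), as.character(seq_len(n_chrom)))
  map <- uniform_genetic_map(lens)
  grid <- build_window_grid(map, setNames(rep(windows, n_chrom), names(lens)))
  list(map = map, grid = grid)
}
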