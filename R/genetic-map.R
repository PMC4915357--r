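#' Genetic maps
#'
#' A genetic map is a tibble with one interpolation point per row, columns
#' `chrom` (character), `pos_bp` (physical position, base pairs) and `pos_cM`
#' (genetic position, centimorgans). Within each chromosome both coordinate
#' columns must be non-decreasing, genetic positions non-negative, and at
#' least two points are required so that linear interpolation is defined.
#'
#' @param x A data frame with columns `chrom`, `pos_bp`, `pos_cM`.
#' @return A `genetic_map` tibble.
#' @export
genetic_map <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("chrom", "pos_bp", "pos_cM")
  if (!all(required %in% names(x))) {
    abort(paste0("genetic map needs columns ", paste(required, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  if (any(!is.finite(x$pos_bp)) || any(!is.finite(x$pos_cM))) {
    abort("genetic map positions must be finite numbers")
  }
  if (any(x$pos_cM < 0)) abort("genetic positions must be >= 0")
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, ]
    if (nrow(sub) < 2) {
      abort(paste0("chromosome ", ch, " has fewer than 2 map points"))
    }
    if (is.unsorted(sub$pos_bp) || is.unsorted(sub$pos_cM)) {
      abort(paste0("map positions decrease within chromosome ", ch))
    }
  }
  class(x) <- c("genetic_map", class(tibble::tibble()))
  x
}

#' Read a HapMap-format genetic map
#'
#' Expects a tab-delimited file with a header and four columns in HapMap
#' order: chromosome, physical position (bp), recombination rate (cM/Mb) and
#' cumulative genetic position (cM). The rate column is read but not used;
#' interpolation is linear between the cumulative positions.
#'
#' @param path Path to the map file.
#' @return A [genetic_map()] tibble.
#' @export
read_genetic_map <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 4) abort("genetic map file needs 4 columns (HapMap dialect)")
  x <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    pos_bp = as.numeric(raw[[2]]),
    pos_cM = as.numeric(raw[[4]])
  )
  if (any(is.na(x$pos_bp)) || any(is.na(x$pos_cM))) {
    abort("non-numeric position in genetic map")
  }
  bad <- which(stats::ave(x$pos_cM, x$chrom, FUN = function(v) c(0, diff(v))) < 0)
  if (length(bad) > 0) {
    abort(paste0("genetic position decreases at line ", bad[1] + 1,
                 " of ", path))
  }
  genetic_map(x)
}

#' Chromosome genetic lengths of a map
#'
#' @param map A [genetic_map()].
#' @return Named numeric vector of total genetic length (cM) per chromosome,
#'   in order of first appearance.
#' @export
chrom_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  chroms <- unique(map$chrom)
  vapply(chroms, function(ch) {
    v <- map$pos_cM[map$chrom == ch]
    max(v) - min(v)
  }, numeric(1))
}

#' Interpolate genetic position at physical coordinates
#'
#' Linear interpolation between map points; positions outside the mapped
#' range are clamped to the ends.
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome identifier.
#' @param pos_bp Numeric vector of physical positions.
#' @return Numeric vector of genetic positions (cM).
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  stopifnot(inherits(map, "genetic_map"))
  sub <- map[map$chrom == as.character(chrom), ]
  if (nrow(sub) == 0) abort(paste0("unknown chromosome ", chrom))
  approx(sub$pos_bp, sub$pos_cM, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' Construct a uniform-rate genetic map
#'
#' Convenience constructor for simulation work: each chromosome gets two
#' anchoring points, 0 and its full length, with 1 cM per Mb.
#'
#' @param lengths_cM Named numeric vector of chromosome lengths in cM.
#' @return A [genetic_map()].
#' @export
uniform_genetic_map <- function(lengths_cM) {
  if (is.null(names(lengths_cM))) {
    names(lengths_cM) <- as.character(seq_along(lengths_cM))
  }
  genetic_map(tibble::tibble(
    chrom = rep(names(lengths_cM), each = 2),
    pos_bp = as.vector(rbind(0, lengths_cM * 1e6)),
    pos_cM = as.vector(rbind(0, lengths_cM))
  ))
}
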