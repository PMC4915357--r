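#' Local-ancestry panels
#'
#' A local-ancestry panel stores, for every haplotype and every window of a
#' [build_window_grid()] grid, an ancestry call: a label from the panel's
#' declared label set, or `"UNRESOLVED"` (call below the posterior
#' threshold, or no call), or `"MASKED"` (window excluded from analysis).
#' Represented as a long tibble with columns `haplotype`, `chrom`, `window`,
#' `label`, `posterior`, in canonical order (haplotype, then chromosome in
#' grid order, then window).
#'
#' @param calls Data frame with columns `haplotype`, `chrom`, `window`,
#'   `label` and optionally `posterior`.
#' @param grid The `window_grid` the calls live on.
#' @param labels Ancestry label set; defaults to the non-reserved labels
#'   present in `calls`.
#' @return An `ancestry_panel` tibble.
#' @export
ancestry_panel <- function(calls, grid, labels = NULL) {
  calls <- tibble::as_tibble(calls)
  if (!"posterior" %in% names(calls)) calls$posterior <- 1
  calls$haplotype <- as.character(calls$haplotype)
  calls$chrom <- as.character(calls$chrom)
  calls$window <- as.integer(calls$window)
  calls$label <- as.character(calls$label)
  counts <- grid_counts(grid)
  bad <- calls$window < 0 | calls$window >= counts[calls$chrom] |
    is.na(counts[calls$chrom])
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("window index ", calls$window[i], " out of range on chromosome ",
                 calls$chrom[i]))
  }
  if (is.null(labels)) {
    labels <- sort(setdiff(unique(calls$label), c(.MASKED, .UNRESOLVED)))
  }
  stray <- setdiff(unique(calls$label), c(labels, .MASKED, .UNRESOLVED))
  if (length(stray) > 0) {
    abort(paste0("labels outside the declared set: ",
                 paste(stray, collapse = ", ")))
  }
  # complete to the full grid: absent windows become UNRESOLVED
  haps <- unique(calls$haplotype)
  full <- tidyr::expand_grid(
    haplotype = haps,
    tibble::tibble(chrom = rep(names(counts), counts),
                   window = unlist(lapply(counts, function(w) seq_len(w) - 1L),
                                   use.names = FALSE))
  )
  out <- dplyr::left_join(full, calls, by = c("haplotype", "chrom", "window"))
  if (nrow(out) != nrow(full)) {
    abort("duplicate (haplotype, chrom, window) calls")
  }
  out$label[is.na(out$label)] <- .UNRESOLVED
  new_ancestry_panel(out, grid, labels)
}

new_ancestry_panel <- function(x, grid, labels) {
  x <- tibble::as_tibble(x)
  chrom_order <- names(grid_counts(grid))
  x <- x[order(x$haplotype, match(x$chrom, chrom_order), x$window), ]
  attr(x, "grid") <- grid
  attr(x, "labels") <- labels
  class(x) <- c("ancestry_panel", class(tibble::tibble()))
  x
}

#' @rdname ancestry_panel
#' @param panel An `ancestry_panel`.
#' @export
panel_grid <- function(panel) attr(panel, "grid")

#' @rdname ancestry_panel
#' @export
panel_labels <- function(panel) attr(panel, "labels")

#' Fraction of MASKED windows in a panel
#' @param panel An [ancestry_panel()].
#' @return Fraction in `[0, 1]`.
#' @export
masked_fraction <- function(panel) mean(panel$label == .MASKED)

#' Read local-ancestry calls
#'
#' Two dialects are supported. `windowed_tsv` is a 5-column TSV with header
#' `haplotype chrom window label posterior`; window indices are 0-based on
#' `grid`. `tract_bed` is a header-less BED-like 5-column TSV
#' `(chrom, start_cM, end_cM, haplotype, label)` with 0-based half-open
#' genetic coordinates; tracts are rasterized onto `grid` by the label
#' covering each window midpoint. Calls whose posterior falls below
#' `posterior_threshold` become `UNRESOLVED`; windows not covered by any
#' call likewise.
#'
#' @param path Input file.
#' @param dialect `"windowed_tsv"` or `"tract_bed"`.
#' @param grid Target `window_grid`.
#' @param posterior_threshold Minimum posterior for accepting a call.
#' @param labels Optional declared label set.
#' @return An [ancestry_panel()].
#' @export
read_local_ancestry <- function(path, dialect = c("windowed_tsv", "tract_bed"),
                                grid, posterior_threshold = 0.9,
                                labels = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "windowed_tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           haplotype = readr::col_character(),
                           chrom = readr::col_character(),
                           window = readr::col_integer(),
                           label = readr::col_character(),
                           posterior = readr::col_double()
                         ))
    low <- !(x$label %in% c(.MASKED, .UNRESOLVED)) &
      !is.na(x$posterior) & x$posterior < posterior_threshold
    x$label[low] <- .UNRESOLVED
    ancestry_panel(x, grid, labels = labels)
  } else {
    x <- readr::read_tsv(path, col_names = c("chrom", "start_cM", "end_cM",
                                             "haplotype", "label"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = "cddcc")
    panel_from_tracts(x, grid, labels = labels)
  }
}

#' Rasterize ancestry tracts onto a window grid
#'
#' Each window takes the label of the tract covering its midpoint
#' (deterministic and order-independent); windows whose midpoint is not
#' covered become `UNRESOLVED`.
#'
#' @param tracts Tibble with columns `haplotype`, `chrom`, `start_cM`,
#'   `end_cM`, `label` (half-open intervals).
#' @param grid Target `window_grid`.
#' @param labels Optional declared label set.
#' @return An [ancestry_panel()].
#' @export
panel_from_tracts <- function(tracts, grid, labels = NULL) {
  tracts <- tibble::as_tibble(tracts)
  tracts$haplotype <- as.character(tracts$haplotype)
  tracts$chrom <- as.character(tracts$chrom)
  counts <- grid_counts(grid)
  lens <- grid_lengths(grid)
  calls <- list()
  for (key in split(seq_len(nrow(tracts)),
                    paste(tracts$haplotype, tracts$chrom, sep = "\r"))) {
    tr <- tracts[key, ]
    tr <- tr[order(tr$start_cM), ]
    ch <- tr$chrom[1]
    if (!ch %in% names(counts)) abort(paste0("unknown chromosome ", ch))
    if (nrow(tr) > 1 && any(tr$start_cM[-1] < tr$end_cM[-nrow(tr)] - 1e-9)) {
      abort(paste0("overlapping tracts on haplotype ", tr$haplotype[1],
                   " chromosome ", ch))
    }
    w <- counts[[ch]]
    width <- lens[[ch]] / w
    mids <- (seq_len(w) - 0.5) * width
    j <- findInterval(mids, tr$start_cM)
    lab <- rep(.UNRESOLVED, w)
    cov <- j >= 1 & mids < tr$end_cM[pmax(j, 1)]
    lab[cov] <- tr$label[j[cov]]
    calls[[length(calls) + 1]] <- tibble::tibble(
      haplotype = tr$haplotype[1], chrom = ch, window = seq_len(w) - 1L,
      label = lab, posterior = 1
    )
  }
  ancestry_panel(dplyr::bind_rows(calls), grid, labels = labels)
}

#' Write local-ancestry calls
#'
#' Inverse of [read_local_ancestry()]. The `windowed_tsv` dialect is
#' lossless (labels, masks and posteriors all round-trip, and a re-written
#' re-read file is byte-identical thanks to canonical ordering). The
#' `tract_bed` dialect serializes maximal same-label runs, including
#' `MASKED`/`UNRESOLVED` runs, and drops posteriors.
#'
#' @param panel An [ancestry_panel()].
#' @param path Output file.
#' @param dialect `"windowed_tsv"` or `"tract_bed"`.
#' @return Invisibly, `path`.
#' @export
write_local_ancestry <- function(panel, path,
                                 dialect = c("windowed_tsv", "tract_bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "windowed_tsv") {
    readr::write_tsv(tibble::as_tibble(panel)[, c("haplotype", "chrom",
                                                  "window", "label",
                                                  "posterior")], path,
                     progress = FALSE)
  } else {
    tr <- panel_to_tracts(panel)
    readr::write_tsv(tr[, c("chrom", "start_cM", "end_cM", "haplotype",
                            "label")], path, col_names = FALSE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Convert a panel back to maximal-run tracts
#'
#' @param panel An [ancestry_panel()].
#' @return Tibble `(haplotype, chrom, start_cM, end_cM, label)`.
#' @export
panel_to_tracts <- function(panel) {
  grid <- panel_grid(panel)
  counts <- grid_counts(grid)
  lens <- grid_lengths(grid)
  out <- panel %>%
    dplyr::group_by(.data$haplotype, .data$chrom) %>%
    dplyr::reframe({
      r <- rle(.data$label)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      ch <- dplyr::cur_group()$chrom
      width <- lens[[ch]] / counts[[ch]]
      tibble::tibble(start_cM = starts * width, end_cM = ends * width,
                     label = r$values)
    })
  tibble::as_tibble(out)
}
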