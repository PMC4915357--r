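# shared fixtures, built in code at test time

# desk-scale genome, built once per session
desk_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- desk_genome()
    cache
  }
})

# serialize a genetic map in the HapMap 4-column dialect
write_hapmap_map <- function(map, path) {
  df <- tibble::as_tibble(map)
  rate <- rep(1, nrow(df))  # placeholder column; readers ignore it
  readr::write_tsv(
    tibble::tibble(chrom = df$chrom, `position(bp)` = df$pos_bp,
                   `rate(cM/Mb)` = rate, `map(cM)` = df$pos_cM),
    path, progress = FALSE
  )
  path
}

# K=3 two-pulse scenario used across the AHG tests:
# (A,B) founding, later C pulse
sim_k3 <- function(seed, g0 = 60, g1 = 20, m_c = 0.3, n_ind = 25, N = 500) {
  h <- admixture_history(c("A", "B"), g0 = g0, m_founder = 0.5,
                         events = list(admix_pulse(g1, "C", m_c)),
                         N = N, sample_size = 2 * n_ind)
  simulate_history(h, grid = desk_fixture()$grid, seed = seed)
}

# the 4-individual constructed Q table: C layered on an (A,B) mixture with
# construction vectors a (ratio) and c (recent proportion)
fixture_q4 <- function() {
  a <- c(0.2, 0.4, 0.6, 0.8)
  cc <- c(0.3, 0.1, 0.1, 0.3)
  list(a = a, c = cc,
       q = q_matrix(cbind(A = (1 - cc) * a, B = (1 - cc) * (1 - a), C = cc)))
}

# direct-arithmetic sample covariance (the in-test oracle)
oracle_cov <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

# tiny panel on an 8-window, 4 cM single-chromosome grid
tiny_grid <- function(windows = 8, len_cM = 4) {
  map <- uniform_genetic_map(c(chr1 = len_cM))
  build_window_grid(map, c(chr1 = windows))
}

panel_from_labels <- function(label_rows, grid, labels = NULL) {
  # label_rows: list of per-haplotype label vectors (one chromosome)
  calls <- purrr::imap_dfr(label_rows, function(labs, i) {
    tibble::tibble(haplotype = sprintf("hap%03d", i),
                   chrom = tibble::as_tibble(grid)$chrom[1],
                   window = seq_along(labs) - 1L, label = labs,
                   posterior = 1)
  })
  ancestry_panel(calls, grid, labels = labels)
}
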