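test_that("older ancestries merge into population 1", {
  grid <- tiny_grid()
  p <- panel_from_labels(list(c("EUR", "WSIB", "CSIB", "EAS",
                                "EAS", "MASKED", "UNRESOLVED", "CSIB")),
                         grid, labels = c("EUR", "WSIB", "CSIB", "EAS"))
  b <- merge_ancestries(p, older = c("EUR", "WSIB", "CSIB"), recent = "EAS")
  expect_equal(panel_labels(b), c("1", "2"))
  expect_equal(sum(b$label == "1"),
               sum(p$label %in% c("EUR", "WSIB", "CSIB")))
  expect_equal(sum(b$label == "2"), sum(p$label == "EAS"))
  expect_equal(b$label[6:7], c("MASKED", "UNRESOLVED"))

  # already binary: identity
  b2 <- merge_ancestries(b, older = "1", recent = "2")
  expect_equal(tibble::as_tibble(b2), tibble::as_tibble(b))

  # stray label is named in the error
  p2 <- panel_from_labels(list(rep(c("EUR", "X"), 4)), grid,
                          labels = c("EUR", "EAS", "X"))
  expect_error(merge_ancestries(p2, older = "EUR", recent = "EAS"),
               "X")
})

test_that("binary panels encode to +/-1 with masks as zeros", {
  grid <- tiny_grid()
  p_all2 <- panel_from_labels(list(rep("2", 8)), grid, labels = c("1", "2"))
  sig <- encode_signal(p_all2)
  expect_equal(as.vector(sig[[1]]), rep(1, 8))

  p <- panel_from_labels(list(c("1", "1", "MASKED", "MASKED", "2", "2",
                                "1", "2")),
                         grid, labels = c("1", "2"))
  sig2 <- encode_signal(p)
  expect_equal(sum(sig2[[1]] == 0), 2)
  expect_equal(attr(sig2, "callable_fraction"), 0.75)

  p_multi <- panel_from_labels(list(rep(c("A", "B", "C", "A"), 2)), grid,
                               labels = c("A", "B", "C"))
  expect_error(encode_signal(p_multi), "binary")
})

test_that("Haar powers localize block structure at the right scale", {
  coarse <- haar_power(c(1, 1, 1, 1, -1, -1, -1, -1))
  expect_equal(coarse[1:2], c(0, 0))
  expect_gt(coarse[3], 0)
  expect_equal(coarse / sum(coarse), c(0, 0, 1))

  fine <- haar_power(c(1, -1, 1, -1, 1, -1, 1, -1))
  expect_equal(fine / sum(fine), c(1, 0, 0))

  expect_warning(z <- haar_power(rep(1, 8)), "no admixture signal")
  expect_equal(z, c(0, 0, 0))
  expect_error(haar_power(rep(1, 6)), "2\\^n")
})

test_that("Parseval holds: count-weighted power equals signal variance", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(c(3, 5, 8, 10), 1)
    x <- if (i %% 2 == 0) sample(c(-1, 1), 2^n, TRUE) else stats::rnorm(2^n)
    pw <- haar_power(x)
    counts <- 2^(n - seq_len(n))
    pop_var <- mean((x - mean(x))^2)
    expect_equal(sum(pw * counts) / 2^n, pop_var, tolerance = 1e-9)
  }
})

test_that("the pooled center sits at the coarsest level for half/half splits", {
  genome <- desk_fixture()
  half <- c(rep("1", 128), rep("2", 128))
  p <- ancestry_panel(purrr::map_dfr(c("h1", "h2"), function(h) {
    tidyr::expand_grid(chrom = as.character(1:8), window = 0:255) %>%
      dplyr::mutate(haplotype = h,
                    label = half[window + 1], posterior = 1)
  }), genome$grid, labels = c("1", "2"))
  w <- wavelet_center(p)
  expect_equal(w$center, 8)  # all power at the coarsest of 8 scales
  expect_equal(sum(w$levels$p_norm), 1)
  # Parseval on the pooled summary
  expect_equal(w$total_energy / w$total_windows, w$pooled_variance,
               tolerance = 1e-9)
})

test_that("pooling is invariant to duplicating a chromosome", {
  map1 <- uniform_genetic_map(c(`1` = 128))
  grid1 <- build_window_grid(map1, c(`1` = 256))
  labs <- rep(c(rep("1", 16), rep("2", 16)), 8)
  p1 <- panel_from_labels(list(labs), grid1, labels = c("1", "2"))

  map2 <- uniform_genetic_map(c(`1` = 128, `2` = 128))
  grid2 <- build_window_grid(map2, c(`1` = 256, `2` = 256))
  p2 <- ancestry_panel(purrr::map_dfr(c("1", "2"), function(ch) {
    tibble::tibble(haplotype = "hap001", chrom = ch, window = 0:255,
                   label = labs, posterior = 1)
  }), grid2, labels = c("1", "2"))
  expect_equal(wavelet_center(p2)$center, wavelet_center(p1)$center)
})

test_that("older admixture shifts the wavelet center toward finer scales", {
  genome <- desk_fixture()
  center_at <- function(g, seed) {
    h <- admixture_history(c("A", "B"), g0 = g, m_founder = 0.7,
                           N = 300, sample_size = 50)
    s <- simulate_history(h, grid = genome$grid, seed = seed)
    wavelet_center(merge_ancestries(s$panel, "A", "B"))$center
  }
  expect_lt(center_at(100, 13), center_at(20, 13))
})

test_that("block lengths are window runs in cM, split by masks", {
  map <- uniform_genetic_map(c(`1` = 128))
  grid <- build_window_grid(map, c(`1` = 256))
  labs <- rep("A", 256)
  labs[101:110] <- "C"
  p <- panel_from_labels(list(labs), grid, labels = c("A", "C"))
  bl <- block_lengths(p)
  cblocks <- bl$blocks[bl$blocks$ancestry == "C", ]
  expect_equal(nrow(cblocks), 1)
  expect_equal(cblocks$length_cM, 5.0)  # 10 windows x 0.5 cM

  # a mask inside the run splits it in two
  labs2 <- labs
  labs2[105] <- "MASKED"
  p2 <- panel_from_labels(list(labs2), grid, labels = c("A", "C"))
  bl2 <- block_lengths(p2, ancestries = "C")
  expect_equal(sort(bl2$blocks$length_cM), c(2.0, 2.5))

  # an all-masked panel contributes no blocks
  p3 <- panel_from_labels(list(rep("MASKED", 256)), grid,
                          labels = c("A", "C"))
  expect_equal(nrow(block_lengths(p3, ancestries = c("A", "C"))$blocks), 0)
})

test_that("rasterized block lengths track the closed form on a fine grid", {
  # 1024 windows of 0.125 cM keep the quantization bias well under 10%
  lens <- setNames(rep(128, 8), as.character(1:8))
  map <- uniform_genetic_map(lens)
  grid <- build_window_grid(map, setNames(rep(1024, 8), names(lens)))
  h <- admixture_history(c("A", "B"), g0 = 50, m_founder = 0.2,
                         N = 1000, sample_size = 60)
  s <- simulate_history(h, grid = grid, seed = 19)
  bl <- block_lengths(s$panel, ancestries = "A")
  expect_lt(abs(bl$summary$mean_cM - 2.5) / 2.5, 0.10)
})

test_that("masking records positions and accumulates fractions", {
  map <- uniform_genetic_map(c(`1` = 128))
  grid <- build_window_grid(map, c(`1` = 1024))
  labs <- rep("A", 1024)
  labs[1:256] <- "C"
  labs[257:320] <- "B"
  p <- panel_from_labels(list(labs), grid, labels = c("A", "B", "C"))

  mk <- mask_ancestry(p, "C")
  expect_equal(mk$masked_fraction, 0.25)
  expect_equal(nrow(mk$mask), 256)
  expect_equal(panel_labels(mk$panel), c("A", "B"))

  # double masking: fractions are additive over disjoint label sets
  mk2 <- mask_ancestry(mk$panel, "B")
  expect_equal(mk2$masked_fraction, 0.25 + 64 / 1024)

  expect_error(mask_ancestry(mk$panel, "C"), "absent")

  # masking one ancestry leaves the other's block statistics intact here
  # (no run of A is interrupted by the C blocks' positions)
  blA_before <- block_lengths(p, ancestries = "A")$summary
  blA_after <- block_lengths(mk$panel, ancestries = "A")$summary
  expect_equal(blA_after, blA_before)
})
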