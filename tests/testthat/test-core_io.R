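test_that("Q matrices read, renormalize and round-trip", {
  qf <- withr::local_tempfile(fileext = ".Q")
  lf <- withr::local_tempfile(fileext = ".labels")
  writeLines(c("0.2 0.3 0.5",
               "0.1 0.6 0.3",
               "0.3332 0.3333 0.3326",  # sums to 0.9991: renormalized
               "1 0 0"), qf)
  writeLines(paste0("ind", 1:4, "\tpop", c(1, 1, 2, 2)), lf)
  q <- read_q_matrix(qf, lf)
  expect_s3_class(q, "q_matrix")
  expect_equal(nrow(q), 4)
  expect_equal(q_components(q), c("A", "B", "C"))
  expect_equal(unname(rowSums(q_proportions(q))), rep(1, 4))
  expect_equal(q$pop, c("pop1", "pop1", "pop2", "pop2"))

  # write/read round trip preserves proportions exactly
  qf2 <- withr::local_tempfile(); lf2 <- withr::local_tempfile()
  write_q_matrix(q, qf2, lf2)
  q2 <- read_q_matrix(qf2, lf2)
  expect_equal(q_proportions(q2), q_proportions(q))
})

test_that("malformed Q input is rejected with a pointer to the offence", {
  qf <- withr::local_tempfile(); lf <- withr::local_tempfile()
  writeLines(c("0.5 0.5", "0.7 0.2"), qf)   # row 2 sums to 0.9
  writeLines(c("a\tx", "b\tx"), lf)
  expect_error(read_q_matrix(qf, lf), "row 2")

  writeLines(c("0.5 0.5", "0.5 oops"), qf)
  expect_error(read_q_matrix(qf, lf), "non-numeric")

  writeLines(rep("0.5 0.5", 5), qf)
  writeLines(c("a\tx", "b\tx", "c\tx", "d\tx"), lf)
  expect_error(read_q_matrix(qf, lf), "5 rows.*4 rows")
})

test_that("6-column pedigree label files are auto-detected", {
  qf <- withr::local_tempfile(); lf <- withr::local_tempfile()
  writeLines(c("0.5 0.5", "0.4 0.6"), qf)
  writeLines(c("popA\tind1\t0\t0\t1\t-9", "popB\tind2\t0\t0\t2\t-9"), lf)
  q <- read_q_matrix(qf, lf)
  expect_equal(q$id, c("ind1", "ind2"))
  expect_equal(q$pop, c("popA", "popB"))
})

test_that("genetic maps read back, interpolate linearly, reject decreases", {
  mf <- withr::local_tempfile(fileext = ".map")
  writeLines(c("chrom\tpos\trate\tmap",
               "1\t0\t1\t0",
               "1\t1000000\t1\t1.0",
               "1\t2000000\t1.5\t2.5"), mf)
  map <- read_genetic_map(mf)
  expect_equal(unname(chrom_lengths(map)), 2.5)
  expect_equal(interpolate_cM(map, "1", 1.5e6), 1.75)
  expect_error(interpolate_cM(map, "7", 1), "unknown chromosome")

  writeLines(c("chrom\tpos\trate\tmap",
               "1\t0\t1\t0",
               "1\t1000000\t1\t1.0",
               "1\t2000000\t1\t0.8"), mf)
  expect_error(read_genetic_map(mf), "decreases at line 4")
})

test_that("window grids partition chromosomes into 2^n equal windows", {
  map <- uniform_genetic_map(c(`1` = 128))
  grid <- build_window_grid(map, c(`1` = 256))
  expect_equal(nrow(grid), 256)
  expect_equal(unique(grid$end_cM - grid$start_cM), 0.5)
  # exact partition: widths sum to the chromosome length
  expect_equal(sum(grid$end_cM - grid$start_cM), 128, tolerance = 1e-12)
  expect_equal(grid$start_cM[-1], grid$end_cM[-256])

  expect_error(build_window_grid(map, c(`1` = 300)), "powers of two")
  expect_error(build_window_grid(map, c(`2` = 256)), "missing chromosomes")
})

test_that("the human-default scheme reproduces the 1024/512/256 layout", {
  scheme <- human_window_scheme()
  # plausible autosome genetic lengths; only the counts are under test
  lens <- setNames(c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181,
                     158, 174, 126, 120, 141, 134, 128, 117, 107, 108,
                     62, 74), as.character(1:22))
  grid <- build_window_grid(uniform_genetic_map(lens), scheme)
  counts <- grid_counts(grid)
  expect_equal(unname(counts[as.character(1:8)]), rep(1024L, 8))
  expect_equal(unname(counts[as.character(c(9:18, 20))]), rep(512L, 11))
  expect_equal(unname(counts[as.character(c(19, 21, 22))]), rep(256L, 3))
})

test_that("windowed local-ancestry files round-trip losslessly", {
  genome <- desk_fixture()
  h <- admixture_history(c("A", "B"), g0 = 30, m_founder = 0.4,
                         N = 100, sample_size = 20)
  panel <- simulate_history(h, grid = genome$grid, seed = 3)$panel
  panel <- mask_ancestry(panel, "A")$panel  # exercise the MASKED token

  f <- withr::local_tempfile(fileext = ".tsv")
  write_local_ancestry(panel, f)
  back <- read_local_ancestry(f, "windowed_tsv", genome$grid,
                              labels = panel_labels(panel))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(panel))

  # byte-identical re-write of a re-read file (canonical ordering)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_local_ancestry(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("tract files rasterize by window midpoint and reject overlaps", {
  map <- uniform_genetic_map(c(`1` = 128))
  grid <- build_window_grid(map, c(`1` = 256))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t64\th1\tEAS"), f)
  p <- read_local_ancestry(f, "tract_bed", grid, labels = c("EAS", "EUR"))
  expect_equal(sum(p$label == "EAS"), 128)  # first half of 256 windows
  expect_equal(sum(p$label == "UNRESOLVED"), 128)

  writeLines(c("1\t0\t64\th1\tEAS", "1\t60\t128\th1\tEUR"), f)
  expect_error(read_local_ancestry(f, "tract_bed", grid), "overlapping tracts")
})

test_that("low-posterior calls become UNRESOLVED at the threshold", {
  grid <- tiny_grid()
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    haplotype = "h1", chrom = "chr1", window = 0:7,
    label = rep(c("A", "B"), 4),
    posterior = c(1, 1, 0.95, 0.9, 0.89, 0.85, 0.5, 1)
  ), f, progress = FALSE)
  p <- read_local_ancestry(f, "windowed_tsv", grid, posterior_threshold = 0.9)
  expect_equal(sum(p$label == "UNRESOLVED"), 3)  # 0.89, 0.85, 0.5
  p2 <- read_local_ancestry(f, "windowed_tsv", grid, posterior_threshold = 0.5)
  expect_equal(sum(p2$label == "UNRESOLVED"), 0)
  # out-of-range window index
  readr::write_tsv(tibble::tibble(haplotype = "h1", chrom = "chr1",
                                  window = 8L, label = "A", posterior = 1),
                   f, progress = FALSE)
  expect_error(read_local_ancestry(f, "windowed_tsv", grid), "out of range")
})

test_that("an empty panel serializes to a valid header-only file", {
  grid <- tiny_grid()
  empty <- ancestry_panel(tibble::tibble(haplotype = character(),
                                         chrom = character(),
                                         window = integer(),
                                         label = character()),
                          grid, labels = c("A", "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_local_ancestry(empty, f)
  expect_length(readLines(f), 1)  # header only
  back <- read_local_ancestry(f, "windowed_tsv", grid, labels = c("A", "B"))
  expect_equal(nrow(back), 0)
})

test_that("parental selection applies the admixture ceiling", {
  q <- q_matrix(cbind(EAS = c(0.995, 0.92, 0.94, 0.5),
                      EUR = c(0.005, 0.08, 0.06, 0.5)),
                ids = c("i1", "i2", "i3", "i4"))
  expect_equal(select_parentals(q, "EAS", 0.01), "i1")
  expect_setequal(select_parentals(q, "EAS", 0.10), c("i1", "i2", "i3"))
  expect_warning(out <- select_parentals(q, "EUR", 0.01), "raising")
  expect_length(out, 0)
  expect_error(select_parentals(q, "XXX", 0.01), "unknown component")
})
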