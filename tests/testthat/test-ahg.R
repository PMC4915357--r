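test_that("the ancestry ratio is A/(A+B) with degenerate rows excluded", {
  q <- q_matrix(cbind(A = c(0.14, 0, 0), B = c(0.56, 0.7, 0),
                      C = c(0.30, 0.3, 1.0)))
  r <- ancestry_ratio(q, "A", "B")
  expect_equal(r$ratio[1], 0.2)
  expect_equal(r$ratio[2], 0)
  expect_equal(nrow(r), 2)  # third individual has A+B = 0
  expect_equal(attr(r, "excluded"), "ind3")

  q2 <- q_matrix(cbind(A = c(0, 0, 0, 0.5), B = c(0, 0, 0, 0.5),
                       C = c(1, 1, 1, 0)))
  expect_error(ancestry_ratio(q2, "A", "B"), "untestable")
})

test_that("the covariance test recovers the constructed recent component", {
  fx <- fixture_q4()
  ts <- trio_statistics(fx$q, c("A", "B", "C"), min_n = 4)
  tab <- tibble::as_tibble(ts)

  # correct ordering: cov(r, C) = cov(a, c) = 0 by construction
  expect_equal(tab$abs_cov[tab$recent == "C"],
               abs(oracle_cov(fx$a, fx$c)), tolerance = 1e-12)
  expect_lt(tab$abs_cov[tab$recent == "C"], 1e-12)

  # wrong ordering (recent = A): oracle-recomputed nonzero covariance
  r_wrong <- ((1 - fx$c) * (1 - fx$a)) /
    ((1 - fx$c) * (1 - fx$a) + fx$c)
  expected <- abs(oracle_cov(r_wrong, (1 - fx$c) * fx$a))
  expect_equal(tab$abs_cov[tab$recent == "A"], expected, tolerance = 1e-12)
  expect_equal(expected, 0.014192672, tolerance = 1e-6)

  expect_equal(chosen_recent(ts), "C")
  expect_lt(attr(ts, "margin"), 1e-10)
})

test_that("zero-variance candidates are flagged, not silently chosen", {
  q <- q_matrix(cbind(A = c(0.2, 0.4, 0.5, 0.7, 0.3),
                      B = c(0.8, 0.6, 0.5, 0.3, 0.7),
                      C = rep(0, 5)))
  ts <- trio_statistics(q, c("A", "B", "C"), min_n = 5)
  tab <- tibble::as_tibble(ts)
  expect_true(tab$zero_variance[tab$recent == "C"])
  expect_equal(tab$abs_cov[tab$recent == "C"], 0)
  expect_false(chosen_recent(ts) == "C")
})

test_that("permutation support behaves at its rank bounds and is reproducible", {
  # maximal covariance: both vectors sorted together, every permutation is <=
  n <- 12
  a <- seq(0.2, 0.8, length.out = n)
  cc <- seq(0.05, 0.45, length.out = n)
  q <- q_matrix(cbind(A = (1 - cc) * a, B = (1 - cc) * (1 - a), C = cc))
  # r = a and q_C = cc are sorted together, so cov(a, cc) is the maximum
  # over all permutations (rearrangement inequality): every draw counts
  p_max <- permutation_consistency(q, c("A", "B", "C"), recent = "C",
                                   B = 199, seed = 1)
  expect_equal(p_max, 1)

  # exact-zero observed covariance: only the observed arrangement attains it
  set.seed(42)
  cv <- stats::runif(n, 0.1, 0.4)
  cv <- cv - mean(cv)
  av <- a - mean(a)
  cv <- cv - av * sum(av * cv) / sum(av^2)  # project out a: cov(a, cv) = 0
  cv <- cv + 0.25
  q0 <- q_matrix(cbind(A = (1 - cv) * a, B = (1 - cv) * (1 - a), C = cv))
  p0 <- permutation_consistency(q0, c("A", "B", "C"), recent = "C",
                                B = 199, seed = 2)
  expect_equal(p0, 1 / 200)

  p1 <- permutation_consistency(q0, c("A", "B", "C"), recent = "C",
                                B = 999, seed = 7)
  p2 <- permutation_consistency(q0, c("A", "B", "C"), recent = "C",
                                B = 999, seed = 7)
  expect_identical(p1, p2)
  expect_error(permutation_consistency(q0, c("A", "B", "C"), "C", B = 50),
               "at least")
})

test_that("reliability flags fire on low proportions and equal variances", {
  # low-proportion component
  set.seed(3)
  e <- stats::runif(20, -0.1, 0.1)
  q <- q_matrix(cbind(A = 0.5 + e, B = 0.47 - e, C = rep(0.03, 20)))
  flags <- reliability_flags(q)
  expect_true(any(grepl("component C", flags)))
  expect_true(any(grepl("below 5%", flags)))

  # exact-variance fixtures from two orthonormal centered contrasts:
  # x1 = s1 u1, x2 = s2 (rho u1 + sqrt(1-rho^2) u2), x3 = -(x1 + x2)
  u1 <- c(1, 1, -1, -1, 1, -1, 1, -1) / sqrt(8)
  u2 <- c(1, -1, 1, -1, 1, -1, -1, 1) / sqrt(8)
  make_qv <- function(v1, v2, v3) {
    rho <- (v3 - v1 - v2) / (2 * sqrt(v1 * v2))
    x1 <- sqrt(v1 * 7) * u1
    x2 <- sqrt(v2 * 7) * (rho * u1 + sqrt(1 - rho^2) * u2)
    q_matrix(cbind(A = 0.4 + x1, B = 0.3 + x2, C = 0.3 - x1 - x2))
  }

  # near-equal variances (0.010, 0.009, 0.011): max/min 1.22 < 2 -> flag
  qv <- make_qv(0.010, 0.009, 0.011)
  v <- apply(q_proportions(qv), 2, var)
  expect_equal(unname(v), c(0.010, 0.009, 0.011))  # fixture premise
  expect_true(any(grepl("obscured", reliability_flags(qv))))

  # well-separated variances (ratio 4): no equal-variance flag
  qw <- make_qv(0.040, 0.010, 0.014)
  vw <- apply(q_proportions(qw), 2, var)
  expect_gte(max(vw) / min(vw), 2)
  expect_false(any(grepl("obscured", reliability_flags(qw))))
})

test_that("vote-peeling reconstructs a layered four-component history", {
  set.seed(11)
  n <- 200
  av <- stats::runif(n, 0.2, 0.8)
  cv <- stats::runif(n, 0.15, 0.45)
  dv <- stats::runif(n, 0.1, 0.4)
  q4 <- q_matrix(cbind(A = (1 - dv) * (1 - cv) * av,
                       B = (1 - dv) * (1 - cv) * (1 - av),
                       C = (1 - dv) * cv,
                       D = dv))
  g <- infer_graph(q4)
  tab <- g$trio_table
  # every trio containing D picks D; {A,B,C} picks C: 3 votes for D
  expect_equal(tab$chosen_recent[tab$trio == "A,B,C"], "C")
  expect_equal(sum(tab$chosen_recent == "D"), 3)
  expect_equal(g$arrival_order, list(c("A", "B"), "C", "D"))
  expect_equal(format_arrival_order(g$arrival_order), "(A,B) -> C -> D")
})

test_that("low-proportion components are dropped before ordering", {
  set.seed(4)
  n <- 30
  av <- stats::runif(n, 0.2, 0.8)
  cv <- stats::runif(n, 0.15, 0.45)
  ev <- stats::runif(n, 0.01, 0.03)  # mean ~2%
  q <- q_matrix(cbind(A = (1 - ev) * (1 - cv) * av,
                      B = (1 - ev) * (1 - cv) * (1 - av),
                      C = (1 - ev) * cv,
                      E = ev))
  expect_warning(g <- infer_graph(q, min_prop = 0.05), "dropping")
  expect_equal(g$dropped, "E")
  expect_equal(g$components, c("A", "B", "C"))
  q3 <- q_matrix(q_proportions(q)[, 1:3] /
                   rowSums(q_proportions(q)[, 1:3]))
  expect_error(suppressWarnings(infer_graph(q3, min_prop = 0.4)),
               "at least 3")
})

test_that("trio statistics and graphs are invariant to individual order", {
  s <- sim_k3(seed = 77, n_ind = 25)
  q <- s$q
  set.seed(8)
  perm <- sample(nrow(q))
  q_shuf <- q_matrix(q_proportions(q)[perm, ], ids = q$id[perm],
                     components = q_components(q))
  ts1 <- trio_statistics(q, c("A", "B", "C"))
  ts2 <- trio_statistics(q_shuf, c("A", "B", "C"))
  expect_equal(tibble::as_tibble(ts1)[, c("recent", "abs_cov")],
               tibble::as_tibble(ts2)[, c("recent", "abs_cov")])
  expect_equal(infer_graph(q)$arrival_order,
               infer_graph(q_shuf)$arrival_order)
})

test_that("a simulated second pulse is ordered after the founding pair", {
  s <- sim_k3(seed = 123, n_ind = 25)
  g <- infer_graph(s$q, seed = 1)
  expect_equal(g$arrival_order, list(c("A", "B"), "C"))
})

test_that("consensus over replicate runs reports the agreement fraction", {
  s <- sim_k3(seed = 55, n_ind = 25)
  runs <- replicate(10, s$q, simplify = FALSE)
  rc <- run_consistency(runs)
  expect_equal(rc$agreement, 1)
  expect_equal(rc$consensus$arrival_order, list(c("A", "B"), "C"))

  # permuted column order is re-aligned by correlation
  m <- q_proportions(s$q)
  q_perm <- q_matrix(m[, c(3, 1, 2)], ids = s$q$id,
                     components = c("C", "A", "B"))
  rc2 <- run_consistency(list(s$q, q_perm, s$q))
  expect_equal(rc2$agreement, 1)

  # simulator replicates of the same history agree on the graph
  reps <- lapply(1:10, function(i) sim_k3(seed = 300 + i, n_ind = 25)$q)
  rc3 <- run_consistency(reps)
  expect_gte(rc3$agreement, 0.9)
  expect_equal(rc3$consensus$arrival_order, list(c("A", "B"), "C"))

  expect_error(run_consistency(list(s$q)), "at least 2")
})
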