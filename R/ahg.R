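#' Ratio of two older ancestry components
#'
#' The quantity the ordering test is built on: for each individual,
#' `r = q_a / (q_a + q_b)`. If components `a` and `b` predate a later
#' component's arrival, the later gene flow rescales `q_a` and `q_b` by the
#' same factor in every individual, so `r` is unchanged and therefore
#' independent of the later component's proportion. Individuals with
#' `q_a + q_b == 0` carry no information about the ratio and are excluded.
#'
#' @param q A [q_matrix()].
#' @param a,b Distinct component labels.
#' @return Tibble `(id, ratio)`, excluded individuals dropped; the excluded
#'   ids are attached as attribute `"excluded"`.
#' @export
ancestry_ratio <- function(q, a, b) {
  comps <- q_components(q)
  if (!all(c(a, b) %in% comps) || a == b) {
    abort("a and b must be distinct components of q")
  }
  denom <- q[[a]] + q[[b]]
  keep <- denom > 0
  if (mean(keep) < 0.5) {
    abort(paste0("more than 50% of individuals have ", a, " + ", b,
                 " == 0; trio untestable"))
  }
  out <- tibble::tibble(id = q$id[keep], ratio = q[[a]][keep] / denom[keep])
  attr(out, "excluded") <- q$id[!keep]
  out
}

#' Covariance ordering test for one trio of components
#'
#' For each candidate "most recent" component X of the trio, computes the
#' absolute sample covariance (1/(n-1) normalization) between the
#' individuals' proportion of X and the ratio of the two remaining
#' components. Under the correct ordering that covariance is zero in
#' expectation, so the candidate with the smallest `|cov|` is chosen.
#' Correlations are reported for diagnostics only and never used for
#' selection. Candidates with zero variance (in X or in the ratio) are
#' flagged and never chosen silently: they win only if no unflagged
#' candidate exists.
#'
#' @param q A [q_matrix()].
#' @param trio Character vector of three component labels.
#' @param min_n Minimum number of usable individuals per candidate.
#' @return A `trio_statistics` object: tibble with one row per candidate
#'   (`recent`, `abs_cov`, `cor`, `n`, `zero_variance`) plus attributes
#'   `chosen_recent` and `margin` (smallest vs second-smallest `|cov|`
#'   ratio).
#' @export
trio_statistics <- function(q, trio, min_n = 5) {
  comps <- q_components(q)
  if (length(trio) != 3 || !all(trio %in% comps)) {
    abort("trio must be three components of q")
  }
  rows <- purrr::map_dfr(trio, function(x) {
    ab <- setdiff(trio, x)
    r <- ancestry_ratio(q, ab[1], ab[2])
    qx <- q[[x]][match(r$id, q$id)]
    n <- nrow(r)
    if (n < min_n) {
      abort(paste0("fewer than ", min_n, " usable individuals for candidate ",
                   x))
    }
    zv <- sd(qx) == 0 || sd(r$ratio) == 0
    tibble::tibble(
      recent = x,
      abs_cov = abs(cov(r$ratio, qx)),
      cor = if (zv) NA_real_ else cor(r$ratio, qx),
      n = n,
      zero_variance = zv
    )
  })
  eligible <- if (all(rows$zero_variance)) rows else rows[!rows$zero_variance, ]
  chosen <- eligible$recent[which.min(eligible$abs_cov)]
  o <- sort(rows$abs_cov)
  margin <- if (o[2] > 0) o[1] / o[2] else 1
  structure(rows, chosen_recent = chosen, margin = margin,
            trio = trio, class = c("trio_statistics", class(rows)))
}

#' @rdname trio_statistics
#' @param ts A `trio_statistics` object.
#' @export
chosen_recent <- function(ts) attr(ts, "chosen_recent")

#' Permutation support for a trio ordering
#'
#' Permutes the candidate-recent component across individuals `B` times and
#' recomputes `|cov|` against the (fixed) older-pair ratio. The p-value
#' `(1 + #permuted |cov| <= observed) / (B + 1)` is small when the observed
#' covariance is closer to zero than expected by chance, supporting the
#' proposed ordering.
#'
#' @param q A [q_matrix()].
#' @param trio Three component labels.
#' @param recent The candidate most-recent component of the trio.
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return Numeric p-value in (0, 1].
#' @export
permutation_consistency <- function(q, trio, recent, B = 999, seed = 1) {
  if (B < 99) abort("use at least B = 99 permutations")
  if (!recent %in% trio) abort("recent must belong to the trio")
  ab <- setdiff(trio, recent)
  r <- ancestry_ratio(q, ab[1], ab[2])
  qx <- q[[recent]][match(r$id, q$id)]
  obs <- abs(cov(r$ratio, qx))
  set.seed(seed)
  hits <- sum(vapply(seq_len(B), function(i) {
    abs(cov(r$ratio, sample(qx))) <= obs
  }, logical(1)))
  (1 + hits) / (B + 1)
}

#' Reliability diagnostics for an ordering analysis
#'
#' Two known failure modes of the covariance test: components present at
#' very low final proportion (below 5% the accuracy of the ordering
#' decreases), and near-equal variances of all components across
#' individuals, under which any existing covariance is obscured.
#'
#' @param q A [q_matrix()].
#' @param low_prop Mean-proportion threshold for the low-proportion flag.
#' @param var_ratio Minimum max/min component-variance ratio below which the
#'   equal-variance flag is raised.
#' @return Character vector of warnings (possibly empty).
#' @export
reliability_flags <- function(q, low_prop = 0.05, var_ratio = 2) {
  m <- q_proportions(q)
  flags <- character()
  mu <- colMeans(m)
  low <- names(mu)[mu < low_prop]
  if (length(low) > 0) {
    flags <- c(flags, paste0("component ", low, " has mean proportion below ",
                             format(low_prop),
                             "; ordering accuracy decreases below 5%"))
  }
  v <- apply(m, 2, var)
  if (min(v) > 0 && max(v) / min(v) < var_ratio) {
    flags <- c(flags, paste0(
      "component variances are approximately equal (max/min ",
      format(round(max(v) / min(v), 2)), " < ", var_ratio,
      "); covariance may be obscured"))
  }
  flags
}

#' Infer the admixture history graph
#'
#' Evaluates the covariance ordering test on every trio of (retained)
#' components and reconstructs the full arrival order by vote-peeling:
#' among the components still unplaced, the one chosen as most recent by
#' the largest number of trios fully contained in the unplaced set is the
#' latest arrival; ties are broken by the larger mean margin over the trios
#' that chose the candidate, and an exact tie after that is an error. The
#' recursion ends at the founding pair, whose internal order the test
#' cannot resolve.
#'
#' @param q A [q_matrix()].
#' @param min_prop Components with mean proportion below this are dropped
#'   (with a warning) before the analysis.
#' @param seed Integer seed (recorded; the inference itself is
#'   deterministic).
#' @return An `ahg` object: list with `arrival_order` (list whose first
#'   element is the unordered founding pair, followed by later components
#'   oldest to newest), `trio_table`, `warnings`, `components`, `dropped`.
#' @export
infer_graph <- function(q, min_prop = 0.05, seed = 1) {
  comps <- q_components(q)
  mu <- colMeans(q_proportions(q))
  dropped <- comps[mu < min_prop]
  keep <- setdiff(comps, dropped)
  warnings <- reliability_flags(q)
  if (length(dropped) > 0) {
    warn(paste0("dropping low-proportion component(s): ",
                paste(dropped, collapse = ", "),
                " (mean below ", format(min_prop), ")"))
  }
  if (length(keep) < 3) {
    abort("need at least 3 components above min_prop to order events")
  }
  trios <- utils::combn(keep, 3, simplify = FALSE)
  stats_list <- lapply(trios, function(tr) trio_statistics(q, tr))
  trio_table <- purrr::map_dfr(stats_list, function(ts) {
    tibble::tibble(trio = paste(attr(ts, "trio"), collapse = ","),
                   chosen_recent = chosen_recent(ts),
                   margin = attr(ts, "margin"))
  })
  trio_detail <- purrr::map_dfr(stats_list, function(ts) {
    out <- tibble::as_tibble(ts)
    out$trio <- paste(attr(ts, "trio"), collapse = ",")
    out
  })

  remaining <- keep
  order_rev <- character()
  while (length(remaining) > 2) {
    in_set <- vapply(stats_list, function(ts) {
      all(attr(ts, "trio") %in% remaining)
    }, logical(1))
    active <- stats_list[in_set]
    picks <- vapply(active, chosen_recent, character(1))
    margins <- vapply(active, function(ts) attr(ts, "margin"), numeric(1))
    votes <- table(factor(picks, levels = remaining))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mm <- vapply(top, function(x) mean(margins[picks == x]), numeric(1))
      top <- top[mm == min(mm)]
      if (length(top) > 1) {
        abort(paste0("unresolved tie between candidates: ",
                     paste(top, collapse = ", ")))
      }
    }
    order_rev <- c(order_rev, top)
    remaining <- setdiff(remaining, top)
  }
  arrival_order <- c(list(sort(remaining)), as.list(rev(order_rev)))
  structure(list(arrival_order = arrival_order, trio_table = trio_table,
                 trio_detail = trio_detail, warnings = warnings,
                 components = keep, dropped = dropped, seed = seed),
            class = "ahg")
}

#' Compact text rendering of an arrival order
#' @param order An `arrival_order` list (founding pair first).
#' @return Single string, e.g. `"(A,B) -> C -> D"`.
#' @export
format_arrival_order <- function(order) {
  paste(c(paste0("(", paste(order[[1]], collapse = ","), ")"),
          unlist(order[-1])), collapse = " -> ")
}

#' @export
print.ahg <- function(x, ...) {
  cat("Admixture history graph\n")
  cat("  arrival order: ", format_arrival_order(x$arrival_order), "\n", sep = "")
  if (length(x$dropped) > 0) {
    cat("  dropped (low proportion): ", paste(x$dropped, collapse = ", "),
        "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  cat("\n")
  print(x$trio_table)
  invisible(x)
}

#' @export
tidy.ahg <- function(x, ...) x$trio_detail

#' @export
glance.ahg <- function(x, ...) {
  tibble::tibble(
    k = length(x$components),
    n_trios = nrow(x$trio_table),
    arrival_order = format_arrival_order(x$arrival_order),
    n_warnings = length(x$warnings),
    n_dropped = length(x$dropped)
  )
}

#' @export
autoplot.ahg <- function(object, ...) {
  ord <- object$arrival_order
  events <- c(paste(ord[[1]], collapse = " + "), unlist(ord[-1]))
  df <- tibble::tibble(step = seq_along(events), event = events)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = 0)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$step + 0.75, yend = 0),
                          data = df[-nrow(df), ],
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::geom_label(ggplot2::aes(label = .data$event)) +
    ggplot2::scale_x_continuous(breaks = df$step,
                                labels = paste0("event ", df$step)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Inferred arrival order of ancestry components") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  }

#' Consensus graph over replicate clustering runs
#'
#' Aligns the component columns of replicate Q matrices to the first run by
#' greatest column correlation (exhaustive over permutations for K <= 7),
#' infers a graph per run, and reports the modal arrival order together
#' with the fraction of runs agreeing with it. Correlation alignment
#' presumes the runs describe the same individuals; when it fails but the
#' runs carry an identical set of component names (e.g. independent
#' simulation replicates of one scenario), the names are trusted instead.
#'
#' @param runs List of [q_matrix()] objects over the same individuals.
#' @param min_prop,seed Passed to [infer_graph()].
#' @param min_align_cor Minimum worst-pair correlation for accepting an
#'   alignment.
#' @return List with `consensus` (the modal `ahg`), `agreement` (fraction of
#'   runs whose arrival order matches the mode) and `orders` (character
#'   vector of per-run renderings).
#' @export
run_consistency <- function(runs, min_prop = 0.05, seed = 1,
                            min_align_cor = 0.8) {
  if (length(runs) < 2) abort("need at least 2 runs")
  ref <- runs[[1]]
  comps <- q_components(ref)
  k <- length(comps)
  aligned <- lapply(seq_along(runs), function(i) {
    if (i == 1) return(ref)
    m <- q_proportions(runs[[i]])
    if (ncol(m) != k) abort("runs have different numbers of components")
    cm <- suppressWarnings(cor(q_proportions(ref), m))
    cm[is.na(cm)] <- 0
    perms <- perms_of(k)
    scores <- vapply(perms, function(p) min(diag(cm[, p, drop = FALSE])),
                     numeric(1))
    best <- perms[[which.max(scores)]]
    if (max(scores) < min_align_cor) {
      if (setequal(colnames(m), comps)) {
        best <- match(comps, colnames(m))  # trust the shared names
      } else {
        abort(paste0("component sets not alignable (best worst-pair correlation ",
                     format(round(max(scores), 3)), " < ", min_align_cor,
                     ")"))
      }
    }
    q_matrix(m[, best, drop = FALSE], ids = runs[[i]]$id,
             pops = runs[[i]]$pop, components = comps)
  })
  graphs <- lapply(aligned, infer_graph, min_prop = min_prop, seed = seed)
  keys <- vapply(graphs, function(g) format_arrival_order(g$arrival_order),
                 character(1))
  tab <- table(keys)
  modal <- names(tab)[which.max(tab)]
  list(consensus = graphs[[which(keys == modal)[1]]],
       agreement = max(tab) / length(keys),
       orders = keys)
}

perms_of <- function(k) {
  if (k > 7) abort("alignment supports at most 7 components")
  if (k == 1) return(list(1L))
  sub <- perms_of(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}
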