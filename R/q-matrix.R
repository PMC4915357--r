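#' Ancestry proportion (Q) matrices
#'
#' A Q matrix holds, per individual, the estimated proportion of each of K
#' ancestry components, as produced by model-based clustering of genotypes.
#' It is represented as a tibble with columns `id`, `pop` and one numeric
#' column per component; rows sum to 1 exactly after construction.
#'
#' @param proportions Numeric matrix or data frame, individuals x components,
#'   entries in `[0, 1]`.
#' @param ids Character vector of individual identifiers.
#' @param pops Optional character vector of population labels.
#' @param components Optional component names; defaults to the column names
#'   of `proportions` or `A`, `B`, `C`, ...
#' @param tol Maximum tolerated deviation of a row sum from 1 before the row
#'   is rejected; rows within tolerance are renormalized to sum exactly 1.
#' @return A `q_matrix` tibble.
#' @export
q_matrix <- function(proportions, ids = NULL, pops = NULL, components = NULL,
                     tol = 1e-3) {
  m <- as.matrix(proportions)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("a Q matrix needs at least 2 ancestry components")
  if (any(is.na(m))) abort("non-numeric or missing Q entry")
  if (any(m < 0)) abort("Q proportions must be >= 0")
  if (is.null(components)) {
    components <- colnames(m)
    if (is.null(components)) components <- LETTERS[seq_len(k)]
  }
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (length(ids) != n) {
    abort(paste0("Q has ", n, " rows but ", length(ids), " ids"))
  }
  if (is.null(pops)) pops <- rep(NA_character_, n)
  sums <- rowSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off) > 0) {
    abort(paste0("Q row ", off[1], " sums to ", format(sums[off[1]]),
                 " (deviation > ", tol, ")"))
  }
  m <- m / sums
  out <- tibble::tibble(id = as.character(ids), pop = as.character(pops))
  for (j in seq_len(k)) out[[components[j]]] <- m[, j]
  new_q_matrix(out, components)
}

new_q_matrix <- function(x, components) {
  x <- tibble::as_tibble(x)
  attr(x, "components") <- components
  class(x) <- c("q_matrix", class(tibble::tibble()))
  x
}

#' @rdname q_matrix
#' @param q A `q_matrix`.
#' @export
q_components <- function(q) attr(q, "components")

#' @rdname q_matrix
#' @export
q_proportions <- function(q) {
  comps <- q_components(q)
  m <- as.matrix(as.data.frame(q)[, comps, drop = FALSE])
  rownames(m) <- q$id
  m
}

#' Read an ADMIXTURE-style Q matrix with its label file
#'
#' The Q file is a whitespace-delimited numeric table, one row per
#' individual, one column per ancestry component. The label file carries one
#' row per Q row and is auto-detected as either a 2-column ID/population
#' table or a 6-column pedigree file (family, individual, father, mother,
#' sex, phenotype), in which case the individual ID is column 2 and the
#' population label column 1.
#'
#' @param q_path Path to the `.Q` file.
#' @param labels_path Path to the label file.
#' @param components Optional component names (default `A`, `B`, ...).
#' @param tol Row-sum tolerance passed to [q_matrix()].
#' @return A [q_matrix()].
#' @export
read_q_matrix <- function(q_path, labels_path, components = NULL, tol = 1e-3) {
  qtab <- utils::read.table(q_path, header = FALSE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
  m <- suppressWarnings(apply(as.matrix(qtab), 2, as.numeric))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(qtab))
  dimnames(m) <- NULL  # .Q files carry no component names
  if (any(is.na(m))) {
    bad <- which(apply(is.na(m), 1, any))[1]
    abort(paste0("non-numeric Q entry in row ", bad, " of ", q_path))
  }
  lab <- utils::read.table(labels_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) >= 6) {
    ids <- as.character(lab[[2]])
    pops <- as.character(lab[[1]])
  } else if (ncol(lab) >= 2) {
    ids <- as.character(lab[[1]])
    pops <- as.character(lab[[2]])
  } else {
    ids <- as.character(lab[[1]])
    pops <- rep(NA_character_, length(ids))
  }
  if (length(ids) != nrow(m)) {
    abort(paste0("Q file has ", nrow(m), " rows but label file has ",
                 length(ids), " rows"))
  }
  q_matrix(m, ids = ids, pops = pops, components = components, tol = tol)
}

#' Write a Q matrix and its labels
#'
#' Inverse of [read_q_matrix()]: writes the proportions as a
#' space-delimited table (full precision) and the labels as a 2-column TSV.
#'
#' @param q A [q_matrix()].
#' @param q_path,labels_path Output paths.
#' @return Invisibly, `q`.
#' @export
write_q_matrix <- function(q, q_path, labels_path) {
  m <- q_proportions(q)
  lines <- apply(m, 1, function(r) {
    paste(vapply(r, format, character(1), digits = 17), collapse = " ")
  })
  writeLines(lines, q_path)
  writeLines(paste(q$id, ifelse(is.na(q$pop), "-", q$pop), sep = "\t"),
             labels_path)
  invisible(q)
}

#' Select putatively unadmixed parental individuals
#'
#' Returns the individuals usable as a parental reference panel for one
#' ancestry component: those whose total proportion of all *other*
#' components does not exceed `max_admixture`. The conventional cutoff is
#' 1%; for heavily admixed proxy panels it can be relaxed (e.g. to 10%).
#'
#' @param q A [q_matrix()].
#' @param component Component label to select for.
#' @param max_admixture Maximum tolerated admixture fraction, in (0, 1).
#' @return Character vector of individual ids (possibly empty, with a
#'   warning suggesting a higher threshold).
#' @export
select_parentals <- function(q, component, max_admixture = 0.01) {
  comps <- q_components(q)
  if (!component %in% comps) {
    abort(paste0("unknown component ", component))
  }
  if (max_admixture <= 0 || max_admixture >= 1) {
    abort("max_admixture must be in (0, 1)")
  }
  other <- 1 - q[[component]]
  ids <- q$id[other <= max_admixture]
  if (length(ids) == 0) {
    warn(paste0("no individual within ", max_admixture,
                " admixture for component ", component,
                "; consider raising the threshold"))
  }
  ids
}
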