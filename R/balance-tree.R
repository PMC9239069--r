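#' Nearest-balance coordinate tree
#'
#' Greedily builds a full ILR coordinate system (D-1 mutually orthogonal
#' balancing elements forming a sequential binary partition) for a CLR
#' shift: the first element is the nearest balance, and every subsequent
#' element has maximal cosine with the shift among all elements
#' co-realizable in one binary tree with those already chosen. Taxa merged
#' into a branch are represented by their mean CLR component weighted by
#' the branch size, so each step only scans combinations of branch weights.
#'
#' @inheritParams nearest_balance
#' @param max_d Refusal cap on the number of parts (default 30): the
#'   weight-combination scan grows combinatorially with the number of
#'   distinct branch sizes.
#' @return Object of class `balance_tree`: `elements` (list of D-1
#'   [balancing_element()]s in discovery order), `coefficients`
#'   (projections of the shift), `impacts` (`coefficient^2 / ||shift||^2`,
#'   non-increasing, summing to 1), `basis` (the induced
#'   [basis_from_partition()] contrast basis), `tied` (per-step tie flags),
#'   `shift`, `labels`.
#' @examples
#' shift <- clr(closure(c(espresso = 1, milk = 3, syrup = 1)))
#' nearest_balance_tree(shift)
#' @export
nearest_balance_tree <- function(shift, labels = NULL, max_d = 30,
                                 tie_tol = 1e-12) {
  chk <- nb_check_shift(shift, labels)
  v <- chk$v; labels <- chk$labels
  D <- length(v)
  if (D > max_d)
    stop("D = ", D, " exceeds the cap (", max_d, "); the weight-partition ",
         "scan is combinatorial -- raise `max_d` deliberately if needed",
         call. = FALSE)
  vnorm <- sqrt(sum(v^2))
  state <- nb_state(D)
  elements <- vector("list", D - 1L)
  coefficients <- numeric(D - 1L)
  tied <- logical(D - 1L)
  cut_tie <- FALSE
  for (k in seq_len(D - 1L)) {
    win <- nb_search(state, v, labels, tie_tol)
    if (is.null(win)) stop("internal error: tree incomplete at step ", k,
                           call. = FALSE)
    elements[[k]] <- balancing_element(labels[win$num], labels[win$den], labels)
    coefficients[k] <- win$inner
    tied[k] <- win$tied
    cut_tie <- cut_tie || win$cut_tie
    state <- nb_apply_element(state, win$region, win$num_units, win$den_units, k)
  }
  if (cut_tie)
    warning("equal CLR components straddled a group cut during the tree ",
            "search; memberships are not unique", call. = FALSE)
  basis <- basis_from_partition(
    lapply(elements, function(e) list(num = e$num, den = e$den)), labels)
  structure(list(
    elements = elements,
    coefficients = coefficients,
    impacts = coefficients^2 / vnorm^2,
    basis = basis,
    tied = tied,
    any_tied = any(tied),
    shift = stats::setNames(v, labels),
    shift_norm = vnorm,
    labels = labels,
    block_history = state$nodes),
    class = "balance_tree")
}

#' @export
print.balance_tree <- function(x, digits = 4, ...) {
  cat("nearest-balance tree: ", length(x$elements), " balances over ",
      length(x$labels), " parts\n", sep = "")
  for (k in seq_along(x$elements)) {
    e <- x$elements[[k]]
    cat(sprintf("  b%d [impact %.*g]: {%s} | {%s}\n", k, digits, x$impacts[k],
                paste(e$num, collapse = ","), paste(e$den, collapse = ",")))
  }
  if (isTRUE(x$any_tied)) cat("  note: ties occurred during the search\n")
  invisible(x)
}

#' Block subsets of a given total weight with maximal mean sum
#'
#' Enumerates, for a target numerator (or denominator) size `r`, the block
#' subsets whose weights sum exactly to `r`; for each feasible multiset of
#' weights, blocks of equal weight are chosen greedily by descending block
#' mean. Building block of the tree search, exported for inspection.
#'
#' @param blocks List of blocks, each a list with `weight` (positive
#'   integer) and `mean` (mean CLR component over the block's taxa).
#' @param r Target total weight.
#' @return List of integer vectors (indices into `blocks`); empty when no
#'   subset of weights sums to `r`.
#' @export
weight_partitions <- function(blocks, r) {
  w <- vapply(blocks, function(b) as.integer(b$weight), 0L)
  mu <- vapply(blocks, function(b) as.numeric(b$mean), 0)
  if (any(w < 1)) stop("block weights must be positive integers", call. = FALSE)
  weights <- sort(unique(w))
  per_class <- lapply(weights, function(cw) {
    idx <- which(w == cw)
    idx[order(-mu[idx], idx)]
  })
  counts <- lapply(per_class, function(idx) 0:length(idx))
  combos <- expand.grid(counts)
  total <- as.matrix(combos) %*% weights
  combos <- combos[total == r, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- integer(0)
    for (ci in seq_along(weights)) {
      k <- combos[i, ci]
      if (k > 0) sel <- c(sel, per_class[[ci]][seq_len(k)])
    }
    if (length(sel)) out[[length(out) + 1L]] <- sort(sel)
  }
  out
}

#' Newick export of a balance tree
#'
#' Writes the sequential binary partition as a rooted binary newick string
#' with taxa as leaves; each internal node is labelled `b<k>_<impact>`
#' after the balance discovered at step k.
#'
#' @param tree A `balance_tree`.
#' @param digits Digits used for the impact in node labels.
#' @return A newick string (terminated by `;`).
#' @export
to_newick <- function(tree, digits = 4) {
  stopifnot(inherits(tree, "balance_tree"))
  labels <- tree$labels
  supports <- vapply(tree$elements, function(e)
    paste(sort(c(e$num, e$den)), collapse = "\r"), "")
  emit <- function(group) {
    if (length(group) == 1L) return(group)
    k <- match(paste(sort(group), collapse = "\r"), supports)
    if (is.na(k)) stop("incomplete tree: group {",
                       paste(group, collapse = ","), "} has no node",
                       call. = FALSE)
    e <- tree$elements[[k]]
    sprintf("(%s,%s)b%d_%.*g", emit(e$num), emit(e$den), k, digits,
            tree$impacts[k])
  }
  root <- match(paste(sort(labels), collapse = "\r"), supports)
  if (is.na(root)) stop("incomplete tree: no root node", call. = FALSE)
  paste0(emit(labels), ";")
}
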