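#' @keywords internal
"_PACKAGE"

# Numerical tolerance used for orthonormality / zero-sum validation checks.
.ob_tol <- 1e-9

#' Closure of a vector of positive parts
#'
#' Normalizes a vector of strictly positive parts to a fixed total, leaving
#' the ratios between parts (the only information a composition carries)
#' unchanged.
#'
#' @param parts Numeric vector of strictly positive parts, optionally named.
#' @param total Positive total the output should sum to (default 1).
#' @return Named numeric vector summing to `total`.
#' @examples
#' closure(c(espresso = 50, milk = 40, syrup = 10))
#' @export
closure <- function(parts, total = 1) {
  parts <- validate_parts(parts)
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("`total` must be a single positive number", call. = FALSE)
  parts / sum(parts) * total
}

validate_parts <- function(parts) {
  if (!is.numeric(parts) || length(parts) < 2L)
    stop("a composition needs at least two numeric parts", call. = FALSE)
  bad <- which(!is.finite(parts) | parts <= 0)
  if (length(bad))
    stop("parts must be strictly positive; offending index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  parts
}

#' Perturbation between two compositions
#'
#' The compositional difference: the closed component-wise ratio that turns
#' `sample1` into `sample2`. Identical samples yield the uniform (zero-shift)
#' composition.
#'
#' @param sample1,sample2 Positive part vectors over the same labels.
#' @return Composition (closed to 1) of the component-wise fold changes.
#' @export
perturbation_between <- function(sample1, sample2) {
  sample1 <- validate_parts(sample1)
  sample2 <- validate_parts(sample2)
  if (length(sample1) != length(sample2))
    stop("samples have different numbers of parts", call. = FALSE)
  n1 <- names(sample1); n2 <- names(sample2)
  if (!is.null(n1) && !is.null(n2)) {
    if (!setequal(n1, n2)) stop("samples have mismatched labels", call. = FALSE)
    sample2 <- sample2[n1]
  }
  closure(sample2 / sample1)
}

#' Centered log-ratio transform and its inverse
#'
#' `clr()` maps a composition (or a taxa-by-samples matrix of positive
#' values, column-wise) to centered log-ratio coordinates: the log of each
#' part minus the mean log. The result sums to zero. `clr_inv()` maps a
#' zero-sum vector back to a composition closed to 1.
#'
#' @param v Positive parts vector, or a positive matrix (taxa rows, sample
#'   columns) transformed column by column.
#' @param vhat Zero-sum numeric vector (or matrix of zero-sum columns).
#' @param tol Tolerance for the zero-sum check in `clr_inv`.
#' @return Numeric vector/matrix of the same shape.
#' @export
clr <- function(v) {
  if (is.matrix(v)) {
    if (any(!is.finite(v) | v <= 0))
      stop("matrix entries must be strictly positive", call. = FALSE)
    lv <- log(v)
    return(sweep(lv, 2L, colMeans(lv)))
  }
  v <- validate_parts(v)
  lv <- log(v)
  lv - mean(lv)
}

#' @rdname clr
#' @export
clr_inv <- function(vhat, tol = 1e-6) {
  if (is.matrix(vhat)) {
    if (any(abs(colSums(vhat)) > tol))
      stop("clr_inv: columns must sum to zero", call. = FALSE)
    ev <- exp(vhat)
    return(sweep(ev, 2L, colSums(ev), "/"))
  }
  if (abs(sum(vhat)) > tol)
    stop("clr_inv: input must sum to zero (got ", signif(sum(vhat), 3), ")",
         call. = FALSE)
  closure(exp(vhat))
}

#' Balancing element between two groups of parts
#'
#' A balancing element is the unit-norm CLR direction of the log-ratio
#' between the geometric means of two disjoint groups: the numerator
#' (r parts, coordinate `sqrt(rs/(r+s))/r`) and the denominator (s parts,
#' coordinate `-sqrt(rs/(r+s))/s`); all other parts get 0.
#'
#' @param num,den Disjoint character vectors of part labels (or integer
#'   indices into `universe`).
#' @param universe Character vector of all D part labels.
#' @return Object of class `balancing_element` with fields `num`, `den`,
#'   `universe`.
#' @export
balancing_element <- function(num, den, universe) {
  if (is.null(universe) || anyDuplicated(universe))
    stop("`universe` must be unique labels", call. = FALSE)
  universe <- as.character(universe)
  if (is.numeric(num)) num <- universe[num]
  if (is.numeric(den)) den <- universe[den]
  num <- as.character(num); den <- as.character(den)
  if (!length(num) || !length(den))
    stop("numerator and denominator must be non-empty", call. = FALSE)
  if (length(intersect(num, den)))
    stop("numerator and denominator overlap: ",
         paste(intersect(num, den), collapse = ", "), call. = FALSE)
  missing <- setdiff(c(num, den), universe)
  if (length(missing))
    stop("labels outside the universe: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(num = sort(num), den = sort(den), universe = universe),
            class = "balancing_element")
}

#' @export
print.balancing_element <- function(x, ...) {
  cat("balancing element (D = ", length(x$universe), ")\n", sep = "")
  cat("  num (r = ", length(x$num), "): ", paste(x$num, collapse = ", "), "\n",
      sep = "")
  cat("  den (s = ", length(x$den), "): ", paste(x$den, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' CLR coordinates of a balancing element
#'
#' @param element A `balancing_element`.
#' @return Named zero-sum unit vector of length D.
#' @export
element_clr <- function(element) {
  stopifnot(inherits(element, "balancing_element"))
  u <- element$universe
  r <- length(element$num); s <- length(element$den)
  e <- stats::setNames(numeric(length(u)), u)
  e[element$num] <- sqrt(r * s / (r + s)) / r
  e[element$den] <- -sqrt(r * s / (r + s)) / s
  e
}

#' Contrast matrix of a sequential binary partition
#'
#' Builds the (D-1) x D contrast matrix whose rows are the CLR coordinates
#' of the balancing elements defined by the nodes of a binary tree over the
#' parts (a sequential binary partition). Node partitions may be given in
#' any order; they are validated for laminarity and completeness.
#'
#' @param partitions List of D-1 elements, each a list with character (or
#'   integer) `num` and `den` giving the two child groups of a node.
#' @param labels Character vector of all D part labels.
#' @return Object of class `contrast_basis`: list with `psi` (the contrast
#'   matrix, columns named by `labels`) and `partitions` (nodes with sorted
#'   label sets, ordered as given).
#' @export
basis_from_partition <- function(partitions, labels) {
  labels <- as.character(labels)
  D <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  if (length(partitions) != D - 1L)
    stop("need exactly D-1 = ", D - 1L, " node partitions, got ",
         length(partitions), call. = FALSE)
  parts <- lapply(partitions, function(p) {
    num <- p$num; den <- p$den
    if (is.numeric(num)) num <- labels[num]
    if (is.numeric(den)) den <- labels[den]
    list(num = sort(as.character(num)), den = sort(as.character(den)))
  })
  for (p in parts) {
    if (!length(p$num) || !length(p$den) || length(intersect(p$num, p$den)))
      stop("each node needs disjoint non-empty groups", call. = FALSE)
    if (length(setdiff(c(p$num, p$den), labels)))
      stop("node uses labels outside the universe", call. = FALSE)
  }
  supports <- lapply(parts, function(p) sort(c(p$num, p$den)))
  keys <- vapply(supports, paste, "", collapse = "\r")
  if (anyDuplicated(keys)) stop("duplicate nodes in the partition", call. = FALSE)
  # structural validation: exactly one root covering all labels; every
  # non-singleton child group must itself be the support of exactly one node
  root <- which(vapply(supports, length, 0L) == D)
  if (length(root) != 1L)
    stop("partition is not a tree: no unique root node", call. = FALSE)
  for (p in parts) for (side in list(p$num, p$den)) {
    if (length(side) > 1L && !(paste(side, collapse = "\r") %in% keys))
      stop("non-nested or incomplete partition: group {",
           paste(side, collapse = ","), "} is never split", call. = FALSE)
  }
  psi <- t(vapply(parts, function(p)
    element_clr(balancing_element(p$num, p$den, labels)),
    numeric(D)))
  dimnames(psi) <- list(NULL, labels)
  gram <- psi %*% t(psi)
  if (max(abs(gram - diag(D - 1L))) > .ob_tol)
    stop("internal error: contrast rows are not orthonormal", call. = FALSE)
  structure(list(psi = psi, partitions = parts, labels = labels),
            class = "contrast_basis")
}

#' @export
print.contrast_basis <- function(x, ...) {
  cat("contrast basis: ", nrow(x$psi), " balances over ", ncol(x$psi),
      " parts\n", sep = "")
  invisible(x)
}

#' Pivot-style default contrast basis
#'
#' Sequential binary partition where node i separates part i from parts
#' i+1..D. Used as the default ILR basis when none is supplied; analysis
#' results are basis-invariant once transformed back to CLR.
#'
#' @param labels Character vector of part labels.
#' @return A `contrast_basis`.
#' @export
pivot_basis <- function(labels) {
  labels <- as.character(labels)
  D <- length(labels)
  if (D < 2L) stop("need at least two parts", call. = FALSE)
  parts <- lapply(seq_len(D - 1L), function(i)
    list(num = labels[i], den = labels[(i + 1L):D]))
  basis_from_partition(parts, labels)
}

#' Isometric log-ratio coordinates
#'
#' `ilr()` expresses a CLR vector in the coordinates of a contrast basis:
#' `v* = vhat %*% t(psi)`. `ilr_inv()` maps ILR coordinates back to CLR:
#' `vhat = v* %*% psi`. Both preserve norms and inner products.
#'
#' @param vhat Zero-sum numeric vector of length D (or matrix of zero-sum
#'   columns, taxa rows).
#' @param vstar Numeric vector of length D-1 (or a (D-1) x n matrix).
#' @param basis A `contrast_basis`.
#' @return ILR coordinates (length D-1) or CLR coordinates (length D).
#' @export
ilr <- function(vhat, basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  D <- ncol(basis$psi)
  if (is.matrix(vhat)) {
    if (nrow(vhat) != D) stop("dimension mismatch", call. = FALSE)
    return(t(basis$psi %*% vhat))
  }
  if (length(vhat) != D) stop("dimension mismatch", call. = FALSE)
  if (!is.null(names(vhat))) vhat <- vhat[basis$labels]
  drop(basis$psi %*% vhat)
}

#' @rdname ilr
#' @export
ilr_inv <- function(vstar, basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  if (is.matrix(vstar)) {
    if (ncol(vstar) != nrow(basis$psi)) stop("dimension mismatch", call. = FALSE)
    return(vstar %*% basis$psi)
  }
  if (length(vstar) != nrow(basis$psi)) stop("dimension mismatch", call. = FALSE)
  stats::setNames(drop(vstar %*% basis$psi), basis$labels)
}

#' Multiplicative zero replacement
#'
#' Replaces zero counts by a small positive proportion and rescales the
#' non-zero proportions of the same sample multiplicatively so every sample
#' still closes to 1. For count input the imputed proportion is
#' `delta / total reads` of the sample (a `delta` fraction of the detection
#' limit of one read); for proportion input it is `delta` times the smallest
#' positive proportion of the sample.
#'
#' @param counts Non-negative taxa-by-samples matrix (counts or proportions).
#' @param delta Fraction of the detection limit used for imputation
#'   (default 0.65).
#' @return Strictly positive taxa-by-samples proportion matrix (columns sum
#'   to 1).
#' @export
zero_replace <- function(counts, delta = 0.65) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (delta <= 0 || delta >= 1) stop("`delta` must be in (0,1)", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ", paste(which(totals == 0), collapse = ", "),
         call. = FALSE)
  props <- sweep(counts, 2L, totals, "/")
  is_prop <- all(abs(totals - 1) < 1e-6)
  out <- props
  for (j in seq_len(ncol(props))) {
    z <- props[, j] == 0
    if (!any(z)) next
    dl <- if (is_prop) min(props[props[, j] > 0, j]) else 1 / totals[j]
    imput <- delta * dl
    out[z, j] <- imput
    out[!z, j] <- props[!z, j] * (1 - sum(z) * imput)
  }
  out
}

#' Prevalence filter for count tables
#'
#' Keeps the taxa observed with at least `min_reads` reads in at least a
#' `min_fraction` share of the samples.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param min_reads Minimum count for a taxon to be called present in a
#'   sample.
#' @param min_fraction Minimum fraction of samples in which the taxon must
#'   be present.
#' @return The reduced matrix (taxa rows dropped).
#' @export
prevalence_filter <- function(counts, min_reads = 2, min_fraction = 0.5) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must be in [0,1]", call. = FALSE)
  keep <- rowMeans(counts >= min_reads) >= min_fraction
  if (!any(keep))
    stop("prevalence filter removed every taxon; lower `min_reads` or ",
         "`min_fraction`", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Serialize a contrast basis to a signed membership table
#'
#' One row per node, one column per part: +1 numerator, -1 denominator,
#' 0 absent. `basis_from_table()` reverses the encoding.
#'
#' @param basis A `contrast_basis`.
#' @param table Integer matrix of -1/0/+1 with part labels as column names.
#' @return A data.frame (node by part) / a `contrast_basis`.
#' @export
basis_to_table <- function(basis) {
  stopifnot(inherits(basis, "contrast_basis"))
  m <- t(vapply(basis$partitions, function(p) {
    v <- stats::setNames(integer(length(basis$labels)), basis$labels)
    v[p$num] <- 1L; v[p$den] <- -1L
    v
  }, integer(length(basis$labels))))
  data.frame(node = seq_len(nrow(m)), m, check.names = FALSE)
}

#' @rdname basis_to_table
#' @export
basis_from_table <- function(table) {
  m <- as.matrix(table[, setdiff(colnames(table), "node"), drop = FALSE])
  labels <- colnames(m)
  parts <- lapply(seq_len(nrow(m)), function(i)
    list(num = labels[m[i, ] == 1], den = labels[m[i, ] == -1]))
  basis_from_partition(parts, labels)
}
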