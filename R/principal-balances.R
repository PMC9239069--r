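#' Principal component analysis in an ILR space
#'
#' Eigen-decomposition of the sample covariance of centered ILR data.
#' Each component's sign is fixed by making its largest-magnitude loading
#' positive, so downstream balance numerators are reproducible.
#'
#' @param data N x (D-1) ILR matrix (samples in rows).
#' @return List with `directions` ((D-1) x m orthonormal loadings),
#'   `variances` (non-increasing), `scores` and `total_variance`.
#' @export
pca_in_ilr <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("need at least 3 samples", call. = FALSE)
  ctr <- sweep(data, 2L, colMeans(data))
  if (max(abs(ctr)) < 1e-12) stop("constant data: no variation", call. = FALSE)
  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  dirs <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(dirs))) {
    i <- which.max(abs(dirs[, j]))
    if (dirs[i, j] < 0) { dirs[, j] <- -dirs[, j]; scores[, j] <- -scores[, j] }
  }
  list(directions = dirs, variances = pc$sdev^2, scores = scores,
       total_variance = sum(pc$sdev^2))
}

#' Principal balances via the nearest-balance method
#'
#' Interprets the two leading principal components of ILR data by balances:
#' the first balance is the nearest balance to PC1 and the second is the
#' best balance for PC2 among those co-realizable in one binary tree with
#' (hence orthogonal to) the first. The variance explained by a balance is
#' the variance of the data projected on its element divided by the total
#' variance.
#'
#' @param data N x (D-1) ILR matrix (samples in rows), expressed in
#'   `basis`.
#' @param basis The [basis_from_partition()] basis of the columns of
#'   `data`; defaults to the pivot basis.
#' @param labels Taxon labels (length D) when `basis` is not given.
#' @return List with `b1`, `b2` (each a `nearest_balance` result),
#'   `explained` (shares of total variance, one per balance), `pca`.
#' @export
principal_balances <- function(data, basis = NULL, labels = NULL) {
  data <- as.matrix(data)
  D <- ncol(data) + 1L
  if (D < 3L) stop("need at least 3 parts", call. = FALSE)
  if (is.null(labels))
    labels <- if (!is.null(basis)) basis$labels else paste0("t", seq_len(D))
  if (is.null(basis)) basis <- pivot_basis(labels)
  pca <- pca_in_ilr(data)
  pc1_clr <- ilr_inv(pca$directions[, 1L], basis)
  b1 <- nearest_balance(pc1_clr, labels = labels)
  pc2_clr <- ilr_inv(pca$directions[, 2L], basis)
  b2 <- second_balance(b1$element, pc2_clr)
  clr_data <- data %*% basis$psi
  expl <- vapply(list(b1$element, b2$element), function(el)
    stats::var(drop(clr_data %*% element_clr(el))) / pca$total_variance, 0)
  list(b1 = b1, b2 = b2, explained = expl, pca = pca, basis = basis)
}
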