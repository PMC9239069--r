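#' Synthetic log-normal compositional dataset with a clustered basis
#'
#' Generates a taxa-by-samples proportion matrix from independent
#' log-normal components with heterogeneous log-scale variances, and
#' builds an ILR contrast basis by complete-linkage hierarchical clustering
#' of the components on their pairwise log-ratio variation matrix -- a
#' parametric stand-in for a real cohort that reproduces the geometry
#' (dimension and tree structure) relevant to balance recovery.
#'
#' @param D Number of taxa (>= 3).
#' @param N Number of samples (default 150).
#' @param seed Integer seed.
#' @param mu_sd Spread of mean log-abundances across taxa (default 2).
#' @param sd_range Range of per-taxon log-scale standard deviations
#'   (default `c(0.3, 1.5)`).
#' @return List with `proportions` (D x N, columns close to 1), `basis`
#'   (a [basis_from_partition()] basis), `labels`.
#' @export
simulate_base_composition <- function(D, N = 150, seed = NULL, mu_sd = 2,
                                      sd_range = c(0.3, 1.5)) {
  if (D < 3L) stop("need D >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("t%03d", seq_len(D))
  mu <- stats::rnorm(D, 0, mu_sd)
  sds <- stats::runif(D, sd_range[1L], sd_range[2L])
  logx <- mu + sds * matrix(stats::rnorm(D * N), D, N)
  props <- apply(exp(logx), 2L, function(col) col / sum(col))
  rownames(props) <- labels
  list(proportions = props, basis = clustered_basis(props), labels = labels)
}

#' Contrast basis from hierarchical clustering of components
#'
#' Complete-linkage clustering of taxa on the pairwise log-ratio variation
#' matrix `T[i,j] = var(log(x_i / x_j))`; every merge of the dendrogram
#' defines one node of the sequential binary partition.
#'
#' @param proportions Strictly positive taxa-by-samples matrix.
#' @return A [basis_from_partition()] contrast basis.
#' @export
clustered_basis <- function(proportions) {
  lx <- log(proportions)
  D <- nrow(lx)
  labels <- rownames(lx)
  if (is.null(labels)) labels <- sprintf("t%03d", seq_len(D))
  tv <- matrix(0, D, D)
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D)
    tv[i, j] <- tv[j, i] <- stats::var(lx[i, ] - lx[j, ])
  hc <- stats::hclust(stats::as.dist(tv), method = "complete")
  # leaves of each merge node, bottom-up
  node_leaves <- vector("list", D - 1L)
  leafset <- function(idx) {
    if (idx < 0) labels[-idx] else node_leaves[[idx]]
  }
  parts <- vector("list", D - 1L)
  for (k in seq_len(D - 1L)) {
    left <- leafset(hc$merge[k, 1L])
    right <- leafset(hc$merge[k, 2L])
    node_leaves[[k]] <- c(left, right)
    parts[[k]] <- list(num = left, den = right)
  }
  basis_from_partition(parts, labels)
}

#' Balancing elements perturbed by orthogonal noise
#'
#' For every balancing element of a basis and every relative noise length,
#' draws Gaussian noise in the orthogonal complement of the element (within
#' the zero-sum CLR hyperplane), rescales it to exactly `fraction` of the
#' element's (unit) norm, and adds it. The disturbed vectors are the inputs
#' of the noise-stability experiment.
#'
#' @param basis A [basis_from_partition()] contrast basis.
#' @param noise_fractions Relative noise lengths in (0, 1)
#'   (default `c(0.05, 0.10, 0.20, 0.30)`).
#' @param replicates Disturbed copies per element and fraction (default 20).
#' @param seed Integer seed.
#' @return Data-frame-like list of records: for each `element` (node
#'   index), `fraction` and `replicate`, the `disturbed` CLR vector and the
#'   true `balancing_element`.
#' @export
simulate_disturbed_elements <- function(basis,
                                        noise_fractions = c(0.05, 0.1, 0.2, 0.3),
                                        replicates = 20, seed = NULL) {
  stopifnot(inherits(basis, "contrast_basis"))
  if (any(noise_fractions <= 0 | noise_fractions >= 1))
    stop("noise fractions must be in (0, 1)", call. = FALSE)
  if (replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  D <- ncol(basis$psi)
  labels <- basis$labels
  recs <- list()
  for (k in seq_len(nrow(basis$psi))) {
    e <- basis$psi[k, ]
    truth <- balancing_element(basis$partitions[[k]]$num,
                               basis$partitions[[k]]$den, labels)
    for (f in noise_fractions) for (rep_i in seq_len(replicates)) {
      z <- stats::rnorm(D)
      z <- z - mean(z)                 # into the zero-sum hyperplane
      z <- z - sum(z * e) * e          # orthogonal to the element
      z <- z * (f / sqrt(sum(z^2)))    # exact relative length
      recs[[length(recs) + 1L]] <- list(
        element = k, fraction = f, replicate = rep_i,
        disturbed = stats::setNames(e + z, labels), truth = truth)
    }
  }
  recs
}

#' Three-way taxon categorization accuracy
#'
#' Fraction of taxa whose category (numerator / denominator / excluded)
#' matches between two balancing elements, after sign alignment: a global
#' numerator-denominator swap counts as a perfect match.
#'
#' @param true_element,found_element [balancing_element()]s over the same
#'   universe.
#' @return Fraction in `[0, 1]`.
#' @export
taxon_accuracy <- function(true_element, found_element) {
  stopifnot(inherits(true_element, "balancing_element"),
            inherits(found_element, "balancing_element"))
  if (!identical(sort(true_element$universe), sort(found_element$universe)))
    stop("elements live on different taxon universes", call. = FALSE)
  u <- true_element$universe
  cat3 <- function(el) {
    v <- stats::setNames(integer(length(u)), u)
    v[el$num] <- 1L; v[el$den] <- -1L
    v
  }
  a <- cat3(true_element); b <- cat3(found_element)[u]
  max(mean(a == b), mean(a == -b))
}

#' Noise-stability experiment for the nearest-balance search
#'
#' Runs the full recovery experiment: disturb every balancing element of a
#' basis by orthogonal noise of given relative lengths, recover each
#' disturbed vector's nearest balance, and score the three-way taxon
#' categorization against the true element. Also records the distance from
#' the disturbed vector to the recovered balance (never above the noise
#' length).
#'
#' @inheritParams simulate_disturbed_elements
#' @return Data frame with one row per disturbed vector: `element`,
#'   `fraction`, `replicate`, `accuracy`, `distance`, `recovered_true`.
#' @export
noise_recovery_stats <- function(basis,
                                 noise_fractions = c(0.05, 0.1, 0.2, 0.3),
                                 replicates = 20, seed = NULL) {
  recs <- simulate_disturbed_elements(basis, noise_fractions, replicates, seed)
  rows <- lapply(recs, function(rc) {
    nb <- nearest_balance(rc$disturbed)
    data.frame(element = rc$element, fraction = rc$fraction,
               replicate = rc$replicate,
               accuracy = taxon_accuracy(rc$truth, nb$element),
               distance = nb$distance,
               recovered_true = taxon_accuracy(rc$truth, nb$element) == 1)
  })
  do.call(rbind, rows)
}

#' Simulated case-control cohort with a planted single-balance shift
#'
#' Two groups of samples in ILR coordinates: the control group around a
#' fixed baseline, the case group around the baseline shifted by
#' `coefficient` along a planted balancing element, with isotropic Gaussian
#' noise. The per-sample noise standard deviation defaults to the value
#' that makes the regression-estimated shift fluctuate by
#' `noise_fraction` of the planted shift length (the study's noise-to-shift
#' calibration).
#'
#' @param D Number of taxa (default 40).
#' @param n_per_group Samples per group (default 1000).
#' @param num,den Taxon index sets of the planted element (defaults: taxa
#'   1..5 over 6..10).
#' @param coefficient Planted shift length (default 1).
#' @param sigma2 Per-coordinate ILR noise variance; when `NULL`, derived
#'   from `noise_fraction`.
#' @param noise_fraction Target ratio between the sampling standard
#'   deviation of the estimated shift and the shift length (default 0.04).
#' @param seed Integer seed.
#' @return List with `Y` (N x (D-1) ILR matrix), `x` (0/1 group labels),
#'   `element` (the planted [balancing_element()]), `coefficient`,
#'   `sigma2`, `basis`, `labels`.
#' @export
simulate_case_control <- function(D = 40, n_per_group = 1000,
                                  num = 1:5, den = 6:10, coefficient = 1,
                                  sigma2 = NULL, noise_fraction = 0.04,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("t%03d", seq_len(D))
  basis <- pivot_basis(labels)
  el <- balancing_element(num, den, labels)
  e_star <- ilr(element_clr(el), basis)
  N <- 2L * n_per_group
  if (is.null(sigma2)) {
    # sd of the OLS shift estimate is sigma * sqrt(4 (D-1) / N); solve for
    # sigma making that a `noise_fraction` share of the shift length
    sigma2 <- (noise_fraction * abs(coefficient))^2 * N / (4 * (D - 1))
  }
  baseline <- stats::rnorm(D - 1L)
  x <- rep(c(0, 1), each = n_per_group)
  noise <- matrix(stats::rnorm(N * (D - 1L), sd = sqrt(sigma2)), N, D - 1L)
  Y <- matrix(baseline, N, D - 1L, byrow = TRUE) +
    outer(x, coefficient * e_star) + noise
  list(Y = Y, x = x, element = el, coefficient = coefficient,
       sigma2 = sigma2, basis = basis, labels = labels)
}
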