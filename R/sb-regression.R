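#' Regression design in ILR coordinates
#'
#' Bundles an N x (D-1) ILR response matrix, a numeric predictor and
#' optional covariates. The intercept is always implicit: supply `Z`
#' without a constant column.
#'
#' @param Y Numeric N x (D-1) matrix of ILR coordinates (samples in rows),
#'   expressed in `basis`.
#' @param x Numeric predictor of length N (binary group indicators are
#'   given as 0/1).
#' @param Z Optional N x K covariate matrix (no intercept column).
#' @param basis [basis_from_partition()] basis the columns of `Y` refer to;
#'   defaults to the pivot basis over `labels`.
#' @param labels Taxon labels (length D); defaults to `t1..tD`.
#' @return Object of class `sb_design`.
#' @export
sb_design <- function(Y, x, Z = NULL, basis = NULL, labels = NULL) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (length(x) != N) stop("`x` length must match nrow(Y)", call. = FALSE)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != N) stop("`Z` rows must match nrow(Y)", call. = FALSE)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  }
  D <- ncol(Y) + 1L
  if (is.null(labels)) {
    labels <- if (!is.null(basis)) basis$labels else paste0("t", seq_len(D))
  }
  if (is.null(basis)) basis <- pivot_basis(labels)
  if (nrow(basis$psi) != ncol(Y))
    stop("basis dimension does not match ncol(Y)", call. = FALSE)
  const_x <- stats::sd(x) == 0
  if (const_x && !is.null(Z))
    stop("covariates are not identifiable with a constant predictor",
         call. = FALSE)
  # constant x (the mean-shift case) absorbs the intercept itself
  Zfull <- if (const_x) NULL else cbind(`(Intercept)` = rep(1, N), Z)
  M <- cbind(x = x, Zfull)
  if (N <= ncol(M))
    stop("need more samples than coefficients", call. = FALSE)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    drop_cols <- colnames(M)[qr_m$pivot[(qr_m$rank + 1L):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  structure(list(Y = Y, x = as.numeric(x), Z = Z, Zfull = Zfull,
                 basis = basis, labels = labels, N = N, D = D,
                 const_x = const_x),
            class = "sb_design")
}

#' Unconstrained multivariate OLS in ILR coordinates
#'
#' Fits `y*_i = x_i v* + A z_i + noise` by ordinary least squares; the
#' predictor coefficient `v*` is the (D-1)-vector of ILR shifts per unit of
#' `x`. With a constant predictor and no covariates the coefficient equals
#' the sample mean.
#'
#' @param design An [sb_design()].
#' @return Object of class `sb_ols`: `v_star`, `A` (covariate coefficients,
#'   intercept first), `sigma2` (residual variance per coordinate), `rss`,
#'   `r_squared` (training), `fitted`.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "sb_design"))
  M <- cbind(x = design$x, design$Zfull)
  fit <- stats::lm.fit(M, design$Y)
  B <- fit$coefficients
  v_star <- B["x", ]
  A <- if (design$const_x) NULL else B[-1L, , drop = FALSE]
  res <- design$Y - M %*% B
  rss <- sum(res^2)
  dfree <- (design$N - ncol(M)) * ncol(design$Y)
  out <- list(v_star = v_star, A = A, sigma2 = rss / max(dfree, 1L), rss = rss,
              fitted = M %*% B, design = design)
  out$r_squared <- 1 - mean(rowSums(res^2)) /
    mean(rowSums(sweep(design$Y, 2L, colMeans(design$Y))^2))
  structure(out, class = "sb_ols")
}

#' Single-balance linear regression
#'
#' Least-squares fit of the regression model whose predictor coefficient is
#' constrained to be a balance: the unconstrained OLS coefficient is
#' projected onto its nearest balancing element and the covariate
#' coefficients are re-estimated against the constrained predictor term,
#' which yields the global least-squares solution of the constrained model.
#'
#' @inheritParams fit_ols
#' @param tie_tol Tie tolerance passed to [nearest_balance()].
#' @return Object of class `single_balance_fit`: `balance` (the
#'   `nearest_balance` of the OLS coefficient), `beta_star` (ILR
#'   coordinates of the fitted balance), `A` (re-estimated covariate
#'   coefficients, intercept first), `sigma2`, `rss`, `r_squared`,
#'   `impact` (share of the predictor-associated shift captured by the
#'   balance), `tied`.
#' @export
fit_single_balance <- function(design, tie_tol = 1e-12) {
  stopifnot(inherits(design, "sb_design"))
  ols <- fit_ols(design)
  if (sqrt(sum(ols$v_star^2)) <= 1e-12)
    stop("no predictor-associated shift (zero OLS coefficient)", call. = FALSE)
  vhat <- ilr_inv(ols$v_star, design$basis)
  nb <- nearest_balance(vhat, labels = design$labels, tie_tol = tie_tol)
  e_star <- ilr(element_clr(nb$element), design$basis)
  beta_star <- nb$coefficient * e_star
  # covariate coefficients re-estimated per the constrained least squares
  if (design$const_x) {
    A <- NULL
    fitted <- design$x %*% t(beta_star)
  } else {
    R <- design$Y - design$x %*% t(beta_star)
    A <- solve(crossprod(design$Zfull), crossprod(design$Zfull, R))
    fitted <- design$x %*% t(beta_star) + design$Zfull %*% A
  }
  res <- design$Y - fitted
  rss <- sum(res^2)
  p <- 1L + if (design$const_x) 0L else ncol(design$Zfull)
  dfree <- (design$N - p) * ncol(design$Y)
  structure(list(
    balance = nb,
    element = nb$element,
    e_star = e_star,
    beta_star = beta_star,
    coefficient = nb$coefficient,
    A = A,
    sigma2 = rss / max(dfree, 1L),
    rss = rss,
    fitted = fitted,
    impact = nb$impact,
    v_star = ols$v_star,
    ols = ols,
    tied = nb$tied,
    design = design,
    r_squared = 1 - mean(rowSums(res^2)) /
      mean(rowSums(sweep(design$Y, 2L, colMeans(design$Y))^2))),
    class = "single_balance_fit")
}

#' @export
print.single_balance_fit <- function(x, digits = 4, ...) {
  cat("single-balance regression fit\n")
  print(x$element)
  cat(sprintf("  coefficient %.*g, impact %.*g, R-squared %.*g\n",
              digits, x$coefficient, digits, x$impact, digits, x$r_squared))
  invisible(x)
}

sb_predict <- function(fit, x, Z = NULL, N = length(x)) {
  Zfull <- cbind(rep(1, N), Z)
  coefs <- if (inherits(fit, "single_balance_fit")) fit$beta_star
           else if (inherits(fit, "sb_ols")) fit$v_star
           else stop("unsupported fit object", call. = FALSE)
  pred <- x %*% t(coefs)
  if (!is.null(fit$A)) pred <- pred + Zfull %*% fit$A
  pred
}

#' Proportion of variance explained
#'
#' `1 - MSE / total variance`, computed on the supplied (possibly held-out)
#' data; may be negative out of sample. The total variance is taken about
#' the mean of the evaluated responses.
#'
#' @param fit A `single_balance_fit` or `sb_ols`.
#' @param Y N x (D-1) ILR response matrix to score.
#' @param x,Z Predictor and covariates matching `Y`.
#' @param recenter If `TRUE`, predictions are shifted so their mean matches
#'   the mean of `Y` before scoring, correcting for a systematic location
#'   shift between datasets.
#' @return A scalar.
#' @export
r_squared <- function(fit, Y, x, Z = NULL, recenter = FALSE) {
  Y <- as.matrix(Y)
  pred <- sb_predict(fit, x, Z, nrow(Y))
  if (recenter)
    pred <- sweep(pred, 2L, colMeans(pred) - colMeans(Y))
  tot <- mean(rowSums(sweep(Y, 2L, colMeans(Y))^2))
  if (tot <= 0) stop("zero total variance in the responses", call. = FALSE)
  1 - mean(rowSums((Y - pred)^2)) / tot
}

#' Share of the predictor shift captured by the fitted balance
#'
#' `||beta||^2 / ||v*_ls||^2`: the impact of the single balance on the
#' unconstrained predictor-associated shift (identical to the A1 impact of
#' the OLS coefficient).
#'
#' @param fit A `single_balance_fit`.
#' @return A scalar in `[0, 1]`.
#' @export
balance_impact <- function(fit) {
  stopifnot(inherits(fit, "single_balance_fit"))
  fit$impact
}

#' Permutation test on the orthogonal complement of the fitted balance
#'
#' Tests whether the predictor is associated with variation outside the
#' fitted single balance: the ILR data are projected onto the
#' (D-2)-dimensional orthogonal complement of the fitted balancing element
#' and a permutation pseudo-F test (PERMANOVA on Euclidean distances, via
#' \code{vegan::adonis2}) is run for the predictor, with covariates as
#' additional terms. A high p-value means the single balance captures the
#' whole predictor-associated difference.
#'
#' @param design An [sb_design()].
#' @param fit The `single_balance_fit` for that design.
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return List with `p_value`, `statistic` (pseudo-F), `table` (the
#'   full permutation-test table), `n_permutations`.
#' @export
orthogonal_complement_test <- function(design, fit, n_permutations = 999,
                                       seed = NULL) {
  stopifnot(inherits(design, "sb_design"),
            inherits(fit, "single_balance_fit"))
  if (n_permutations < 99)
    stop("use at least 99 permutations", call. = FALSE)
  ux <- unique(design$x)
  if (length(ux) == 2L && min(table(design$x)) < 3L)
    stop("too few samples per group for a permutation test", call. = FALSE)
  D <- design$D
  if (D < 3L) stop("no orthogonal complement exists for D < 3", call. = FALSE)
  ehat <- element_clr(fit$element)
  M <- design$basis$psi - (design$basis$psi %*% ehat) %*% t(ehat)
  sv <- svd(M)
  V <- sv$v[, sv$d > 1e-8, drop = FALSE]        # D x (D-2), orthonormal
  scores <- (design$Y %*% design$basis$psi) %*% V
  df <- data.frame(x = design$x)
  rhs <- "x"
  if (!is.null(design$Z)) {
    df <- cbind(df, as.data.frame(design$Z))
    rhs <- paste(c(colnames(design$Z), "x"), collapse = " + ")
  }
  if (!is.null(seed)) set.seed(seed)
  tab <- vegan::adonis2(stats::as.formula(paste("scores ~", rhs)),
                        data = df, permutations = n_permutations,
                        method = "euclidean", by = "margin")
  row <- match("x", rownames(tab))
  list(p_value = tab[["Pr(>F)"]][row], statistic = tab[["F"]][row],
       table = tab, n_permutations = n_permutations)
}

#' Classification scores along the fitted balance
#'
#' Scores samples by their projection onto the fitted balancing element;
#' for a binary training predictor the AUC is computed from the rank
#' statistic of the scores against the true labels.
#'
#' @param fit A `single_balance_fit`.
#' @param new_ilr N x (D-1) ILR matrix of samples to score (same basis as
#'   the training design).
#' @param truth Optional binary labels (0/1) for AUC computation.
#' @return List with `scores` and (when `truth` is supplied) `auc`.
#' @export
classify_by_balance <- function(fit, new_ilr, truth = NULL) {
  stopifnot(inherits(fit, "single_balance_fit"))
  new_ilr <- as.matrix(new_ilr)
  scores <- drop(new_ilr %*% fit$e_star)
  out <- list(scores = scores)
  if (!is.null(truth)) {
    g <- unique(truth)
    if (length(g) != 2L)
      stop("need exactly two classes to compute an AUC", call. = FALSE)
    out$auc <- rank_auc(scores, truth == max(truth))
  }
  out
}

# Mann-Whitney AUC from ranks.
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
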