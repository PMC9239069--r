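make_cohort <- function(D = 8, n = 30, coef = 1, sigma = 0.05, seed = 1,
                        num = 1:2, den = 3:5, Z = NULL, A = NULL) {
  set.seed(seed)
  labels <- paste0("t", 1:D)
  basis <- pivot_basis(labels)
  el <- balancing_element(num, den, labels)
  e_star <- ilr(element_clr(el), basis)
  x <- rep(c(0, 1), length.out = 2 * n)
  N <- 2 * n
  Y <- outer(x, coef * e_star) +
    matrix(rnorm(N * (D - 1), sd = sigma), N, D - 1)
  if (!is.null(Z)) Y <- Y + Z %*% A
  list(Y = Y, x = x, basis = basis, labels = labels, element = el,
       e_star = e_star)
}

test_that("a constant predictor reduces to the mean-shift approximation", {
  set.seed(141)
  Y <- matrix(rnorm(60), 20, 3)
  d <- sb_design(Y, x = rep(1, 20))
  ols <- fit_ols(d)
  expect_equal(unname(ols$v_star), unname(colMeans(Y)), tolerance = 1e-12)
  fit <- fit_single_balance(d)
  # fitted balance equals A1 applied to the CLR image of the sample mean
  nb <- nearest_balance(ilr_inv(colMeans(Y), d$basis))
  expect_same_element(fit$element, nb$element)
  expect_equal(fit$coefficient, nb$coefficient, tolerance = 1e-12)
})

test_that("noiseless single-balance data are recovered exactly", {
  ch <- make_cohort(sigma = 0, seed = 3)
  d <- sb_design(ch$Y, ch$x, basis = ch$basis)
  ols <- fit_ols(d)
  expect_equal(unname(ols$v_star), unname(ch$e_star), tolerance = 1e-9)
  fit <- fit_single_balance(d)
  expect_same_element(fit$element, ch$element)
  expect_equal(fit$r_squared, ols$r_squared, tolerance = 1e-9)
  expect_equal(fit$impact, 1, tolerance = 1e-9)
})

test_that("unconstrained OLS agrees with the normal-equation oracle", {
  set.seed(151)
  for (i in 1:10) {
    N <- 25; D <- 6; K <- 2
    Y <- matrix(rnorm(N * (D - 1)), N, D - 1)
    x <- rnorm(N)
    Z <- matrix(rnorm(N * K), N, K)
    d <- sb_design(Y, x, Z)
    ols <- fit_ols(d)
    M <- cbind(x, 1, Z)
    B <- solve(crossprod(M), crossprod(M, Y))
    expect_equal(unname(ols$v_star), unname(B[1, ]), tolerance = 1e-9)
  }
  expect_error(sb_design(matrix(rnorm(30), 10, 3), rnorm(10),
                         Z = matrix(rep(1, 10))), "collinear")
})

test_that("the constrained fit attains minimal RSS over every balance", {
  # independent oracle: for each element, residualize on the covariates
  # (Frisch-Waugh), fit the per-element coefficient, and compare RSS
  set.seed(161)
  for (i in 1:10) {
    D <- sample(4:6, 1); N <- sample(15:30, 1); K <- sample(0:2, 1)
    Y <- matrix(rnorm(N * (D - 1)), N, D - 1)
    x <- rnorm(N)
    Z <- if (K > 0) matrix(rnorm(N * K), N, K) else NULL
    d <- sb_design(Y, x, Z)
    fit <- fit_single_balance(d)
    Zf <- cbind(rep(1, N), Z)
    H <- Zf %*% solve(crossprod(Zf), t(Zf))
    xt <- x - H %*% x
    Yt <- Y - H %*% Y
    best <- Inf
    for (e in oracle_elements(D)) {
      ec <- oracle_element_clr(e$num, e$den, D)
      estar <- drop(d$basis$psi %*% ec)
      c0 <- sum((Yt %*% estar) * xt) / sum(xt^2)
      rss_e <- sum((Yt - xt %*% t(c0 * estar))^2)
      best <- min(best, rss_e)
    }
    expect_equal(fit$rss, best, tolerance = 1e-8)
    # and never better than the unconstrained OLS
    expect_gte(fit$rss, fit$ols$rss - 1e-9)
    expect_lte(fit$r_squared, fit$ols$r_squared + 1e-12)
  }
})

test_that("covariate coefficients follow the constrained least squares", {
  set.seed(171)
  N <- 40; D <- 6
  Z <- matrix(rnorm(N * 2), N, 2)
  A_true <- matrix(rnorm(2 * (D - 1)), 2, D - 1)
  ch <- make_cohort(D = D, n = N / 2, sigma = 0.1, seed = 5, Z = Z, A = A_true)
  d <- sb_design(ch$Y, ch$x, Z, basis = ch$basis)
  fit <- fit_single_balance(d)
  # closed form: A = (Zf' Zf)^-1 Zf' (Y - x beta')
  Zf <- d$Zfull
  A_hat <- solve(crossprod(Zf), crossprod(Zf, ch$Y - ch$x %*% t(fit$beta_star)))
  expect_equal(fit$A, A_hat, tolerance = 1e-9)
  expect_equal(unname(fit$A[-1, ]), unname(A_true), tolerance = 0.15)
  # single-predictor intercept identity: a = mean(y) - mean(x) beta
  d1 <- sb_design(ch$Y - Z %*% A_true, ch$x, basis = ch$basis)
  f1 <- fit_single_balance(d1)
  expect_equal(unname(f1$A["(Intercept)", ]),
               unname(colMeans(d1$Y) - mean(ch$x) * f1$beta_star),
               tolerance = 1e-9)
})

test_that("balance membership recovery improves as noise vanishes", {
  accs <- vapply(c(0.6, 0.15, 0.01), function(sig) {
    mean(vapply(1:8, function(s) {
      ch <- make_cohort(D = 8, n = 25, sigma = sig, seed = 200 + s)
      fit <- fit_single_balance(sb_design(ch$Y, ch$x, basis = ch$basis))
      taxon_accuracy(ch$element, fit$element)
    }, 0))
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1, tolerance = 1e-12)
})

test_that("r_squared behaves at its anchor points and out of sample", {
  ch <- make_cohort(sigma = 0, seed = 7)
  d <- sb_design(ch$Y, ch$x, basis = ch$basis)
  fit <- fit_single_balance(d)
  expect_equal(r_squared(fit, ch$Y, ch$x), 1, tolerance = 1e-9)
  # intercept-only prediction of the training mean scores exactly zero
  set.seed(181)
  Y <- matrix(rnorm(60), 20, 3)
  dm <- sb_design(Y, rep(1, 20))
  expect_equal(r_squared(fit_ols(dm), Y, rep(1, 20)), 0, tolerance = 1e-12)
  # train R2 >= test R2 in expectation over seeded splits
  deltas <- vapply(1:20, function(s) {
    ch <- make_cohort(D = 6, n = 40, sigma = 0.4, seed = 300 + s,
                      num = 1:2, den = 3:4)
    idx <- seq_len(40)
    d_tr <- sb_design(ch$Y[idx, ], ch$x[idx], basis = ch$basis)
    fit <- fit_single_balance(d_tr)
    r_squared(fit, ch$Y[idx, ], ch$x[idx]) -
      r_squared(fit, ch$Y[-idx, ], ch$x[-idx])
  }, 0)
  expect_gt(mean(deltas), 0)
  expect_error(r_squared(fit, ch$Y * 0, ch$x), "zero total variance")
})

test_that("impact equals the A1 impact and decays with noise", {
  ch <- make_cohort(sigma = 0.2, seed = 9)
  fit <- fit_single_balance(sb_design(ch$Y, ch$x, basis = ch$basis))
  nb <- nearest_balance(ilr_inv(fit$v_star, ch$basis))
  expect_equal(balance_impact(fit), nb$impact, tolerance = 1e-12)
  imps <- vapply(c(0.05, 0.4, 1.2), function(sig)
    mean(vapply(1:6, function(s) {
      ch <- make_cohort(D = 8, n = 25, sigma = sig, seed = 400 + s)
      fit_single_balance(sb_design(ch$Y, ch$x, basis = ch$basis))$impact
    }, 0)), 0)
  expect_true(all(diff(imps) < 0))
})

test_that("fits are invariant to the choice of ILR basis", {
  set.seed(191)
  ch <- make_cohort(D = 7, n = 20, sigma = 0.3, seed = 11)
  labs <- ch$labels
  basis2 <- basis_from_partition(random_sbp(labs), labs)
  Y2 <- ilr(t(ch$Y %*% ch$basis$psi), basis2)   # re-express in the new basis
  f1 <- fit_single_balance(sb_design(ch$Y, ch$x, basis = ch$basis))
  f2 <- fit_single_balance(sb_design(Y2, ch$x, basis = basis2))
  expect_same_element(f1$element, f2$element)
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-8)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
})

test_that("the orthogonal-complement permutation test is seeded and calibrated", {
  ch <- make_cohort(D = 6, n = 25, sigma = 0.3, seed = 13)
  d <- sb_design(ch$Y, ch$x, basis = ch$basis)
  fit <- fit_single_balance(d)
  p1 <- orthogonal_complement_test(d, fit, n_permutations = 99, seed = 42)
  p2 <- orthogonal_complement_test(d, fit, n_permutations = 99, seed = 42)
  expect_identical(p1$p_value, p2$p_value)
  expect_error(orthogonal_complement_test(d, fit, n_permutations = 9),
               "at least 99")
  # type-I calibration: difference confined to the fitted balance
  pvals <- vapply(1:60, function(s) {
    ch <- make_cohort(D = 5, n = 20, sigma = 0.25, seed = 500 + s)
    d <- sb_design(ch$Y, ch$x, basis = ch$basis)
    fit <- fit_single_balance(d)
    orthogonal_complement_test(d, fit, n_permutations = 99,
                               seed = s)$p_value
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.18)       # ~0.05 nominal, binomial slack at 60 runs
  # power: an orthogonal component no single balance can absorb must be
  # detected (two disjoint pairwise shifts with unequal coefficients)
  set.seed(201)
  labs <- paste0("t", 1:6)
  basis <- pivot_basis(labs)
  e1 <- ilr(element_clr(balancing_element(1, 2, labs)), basis)
  e2 <- ilr(element_clr(balancing_element(3, 4, labs)), basis)
  x <- rep(c(0, 1), each = 100)
  Y <- outer(x, e1 + 0.6 * e2) + matrix(rnorm(200 * 5, sd = 0.2), 200, 5)
  d2 <- sb_design(Y, x, basis = basis)
  fit2 <- fit_single_balance(d2)
  p <- orthogonal_complement_test(d2, fit2, n_permutations = 199, seed = 1)
  expect_lt(p$p_value, 0.05)
})

test_that("classification by the fitted balance scores and ranks correctly", {
  ch <- make_cohort(D = 6, n = 30, sigma = 0.05, seed = 15)
  fit <- fit_single_balance(sb_design(ch$Y, ch$x, basis = ch$basis))
  cl <- classify_by_balance(fit, ch$Y, truth = ch$x)
  expect_equal(cl$auc, 1)
  # labels independent of scores give AUC near 1/2
  aucs <- vapply(1:20, function(s) {
    set.seed(600 + s)
    classify_by_balance(fit, ch$Y, truth = sample(ch$x))$auc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
  expect_error(classify_by_balance(fit, ch$Y, truth = rep(1, 60)),
               "two classes")
})
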