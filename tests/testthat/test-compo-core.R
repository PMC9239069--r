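test_that("closure rescales to the requested total and keeps ratios", {
  expect_equal(closure(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(closure(c(espresso = 50, milk = 40, syrup = 10)),
               c(espresso = 0.5, milk = 0.4, syrup = 0.1))
  expect_equal(closure(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(closure(c(1, 3), total = 100), c(25, 75))
  expect_error(closure(c(1, 0, 2)), "offending index: 2")
  expect_error(closure(c(1, -1, 2, -3)), "2, 4")
})

test_that("perturbation is the closed fold change between samples", {
  cup1 <- c(espresso = 50, milk = 40, syrup = 10)
  cup2 <- c(espresso = 50, milk = 120, syrup = 10)
  expect_equal(perturbation_between(cup1, cup2),
               c(espresso = 0.2, milk = 0.6, syrup = 0.2))
  expect_equal(perturbation_between(cup1, cup1),
               c(espresso = 1, milk = 1, syrup = 1) / 3)
  expect_equal(perturbation_between(c(1, 1), c(2, 8)), c(0.2, 0.8))
  expect_error(perturbation_between(c(a = 1, b = 2), c(a = 1, c = 2)),
               "mismatched labels")
  # perturbing sample1 by the result recovers sample2 up to closure
  set.seed(1)
  s1 <- closure(runif(6) + 0.1); s2 <- closure(runif(6) + 0.1)
  p <- perturbation_between(s1, s2)
  expect_equal(closure(s1 * p), closure(s2))
})

test_that("clr matches the closed form and round-trips", {
  expect_equal(clr(rep(1 / 4, 4)), rep(0, 4))
  expect_equal(clr(closure(c(1, 3, 1))),
               c(-log(3) / 3, 2 * log(3) / 3, -log(3) / 3))
  set.seed(7)
  for (i in 1:20) {
    x <- closure(runif(sample(3:10, 1)) + 0.05)
    expect_equal(clr_inv(clr(x)), x, tolerance = 1e-9)
  }
  expect_error(clr_inv(c(1, 2, 3)), "sum to zero")
  # matrix form works column-wise
  m <- matrix(runif(12) + 0.1, 4, 3)
  expect_equal(clr(m)[, 2], clr(m[, 2]), ignore_attr = TRUE)
})

test_that("balancing element CLR has the closed-form coordinates", {
  u <- paste0("t", 1:7)
  set.seed(3)
  for (i in 1:25) {
    r <- sample(1:3, 1); s <- sample(1:3, 1)
    taxa <- sample(u, r + s)
    el <- balancing_element(taxa[1:r], taxa[(r + 1):(r + s)], u)
    e <- element_clr(el)
    expect_equal(sum(e), 0, tolerance = 1e-12)
    expect_equal(sum(e^2), 1, tolerance = 1e-12)
    ap <- sqrt(r * s / (r + s)) / r
    am <- -sqrt(r * s / (r + s)) / s
    expect_equal(unname(e[el$num]), rep(ap, r))
    expect_equal(unname(e[el$den]), rep(am, s))
    # closed-form identities r*a+ + s*a- = 0 and r*a+^2 + s*a-^2 = 1
    expect_equal(r * ap + s * am, 0)
    expect_equal(r * ap^2 + s * am^2, 1)
  }
  expect_error(balancing_element("a", "a", c("a", "b")), "overlap")
  expect_error(balancing_element("a", "z", c("a", "b")), "outside the universe")
})

test_that("contrast basis of the coffee tree has the printed entries", {
  cb <- coffee_basis()
  expect_equal(unname(cb$psi[1, ]),
               c(-sqrt(1 / 6), sqrt(2 / 3), -sqrt(1 / 6)), tolerance = 1e-9)
  expect_equal(unname(cb$psi[2, ]), c(sqrt(1 / 2), 0, -sqrt(1 / 2)),
               tolerance = 1e-9)
})

test_that("contrast bases are orthonormal for random trees, in any node order", {
  expect_equal(unname(pivot_basis(c("a", "b"))$psi), rbind(c(1, -1) / sqrt(2)))
  set.seed(11)
  for (i in 1:15) {
    labs <- paste0("x", seq_len(sample(3:9, 1)))
    parts <- random_sbp(labs)
    parts <- parts[sample(length(parts))]
    cb <- basis_from_partition(parts, labs)
    D <- length(labs)
    expect_equal(cb$psi %*% t(cb$psi), diag(D - 1), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(rowSums(cb$psi), rep(0, D - 1), tolerance = 1e-9)
    # swapping num and den of a node only flips the row sign
    parts2 <- parts
    parts2[[1]] <- list(num = parts[[1]]$den, den = parts[[1]]$num)
    cb2 <- basis_from_partition(parts2, labs)
    expect_equal(abs(cb2$psi), abs(cb$psi), tolerance = 1e-12)
  }
})

test_that("invalid partitions are rejected", {
  labs <- c("a", "b", "c", "d")
  expect_error(basis_from_partition(list(list(num = "a", den = "b")), labs),
               "D-1")
  # non-nested: {a,b} vs {b,c} overlap without containment
  expect_error(basis_from_partition(list(
    list(num = c("a", "b"), den = c("c", "d")),
    list(num = "b", den = "c"),
    list(num = "a", den = "d")), labs), "no unique root|never split")
  # incomplete: group {c,d} never split
  expect_error(basis_from_partition(list(
    list(num = c("a", "b"), den = c("c", "d")),
    list(num = "a", den = "b"),
    list(num = "a", den = c("b", "c"))), labs), "never split|unique root")
})

test_that("ilr is an isometry and inverts exactly", {
  cb <- coffee_basis()
  expect_equal(ilr(c(0, 0, 0), cb), c(0, 0))
  shift <- clr(closure(c(espresso = 1, milk = 3, syrup = 1)))
  vstar <- ilr(shift, cb)
  expect_equal(vstar[2], 0, tolerance = 1e-12)      # second balance constant
  expect_equal(abs(vstar[1]), sqrt(sum(shift^2)), tolerance = 1e-9)
  set.seed(5)
  for (i in 1:15) {
    labs <- paste0("x", seq_len(sample(3:9, 1)))
    cb2 <- basis_from_partition(random_sbp(labs), labs)
    v <- rand_clr(length(labs)); w <- rand_clr(length(labs))
    expect_equal(sqrt(sum(ilr(v, cb2)^2)), sqrt(sum(v^2)), tolerance = 1e-9)
    expect_equal(sum(ilr(v, cb2) * ilr(w, cb2)), sum(v * w), tolerance = 1e-9)
    expect_equal(unname(ilr_inv(ilr(v, cb2), cb2)), v, tolerance = 1e-9)
  }
  expect_error(ilr(c(0, 0), cb), "dimension mismatch")
  expect_error(ilr_inv(c(0, 0, 0), cb), "dimension mismatch")
})

test_that("zero replacement is multiplicative and closure-preserving", {
  m <- matrix(c(2, 3, 5, 1, 4, 5), 3, 2)
  expect_equal(zero_replace(m), sweep(m, 2, colSums(m), "/"))
  m2 <- matrix(c(0, 5, 5), 3, 1)
  out <- zero_replace(m2, delta = 0.65)
  expect_equal(out[1, 1], 0.65 * (1 / 10))
  expect_equal(out[2:3, 1], rep(0.5 * (1 - 0.065), 2), ignore_attr = TRUE)
  expect_equal(colSums(out), 1, ignore_attr = TRUE)
  set.seed(9)
  m3 <- matrix(rpois(60, 2), 6, 10)
  m3[1, colSums(m3[-1, , drop = FALSE]) == 0] <- 1    # avoid all-zero samples
  out3 <- zero_replace(m3)
  expect_true(all(out3 > 0))
  expect_equal(colSums(out3), rep(1, 10), tolerance = 1e-12)
  # imputed values stay below the smallest observed proportion per sample
  for (j in which(colSums(m3 == 0) > 0)) {
    pj <- m3[, j] / sum(m3[, j])
    expect_true(all(out3[m3[, j] == 0, j] < min(pj[pj > 0])))
  }
  expect_error(zero_replace(matrix(c(0, 0, 1, 2), 2, 2)), "all-zero")
})

test_that("prevalence filter keeps taxa by count threshold and fraction", {
  m <- rbind(a = c(5, 6, 7, 8), b = c(0, 0, 0, 9), c = c(2, 2, 0, 0),
             d = c(1, 1, 1, 1))
  expect_equal(prevalence_filter(m, min_reads = 1, min_fraction = 0), m)
  kept <- prevalence_filter(m, min_reads = 2, min_fraction = 0.5)
  expect_setequal(rownames(kept), c("a", "c"))
  # taxon b present (>=2 reads) in 1 of 4 samples only
  expect_false("b" %in% rownames(prevalence_filter(m, 2, 0.5)))
  # monotone: raising the fraction never adds taxa
  set.seed(2)
  sparse <- matrix(rpois(200, 1), 10, 20)
  prev <- NULL
  for (f in c(0.05, 0.2, 0.5)) {
    kept_f <- tryCatch(rownames(prevalence_filter(sparse, 2, f)),
                       error = function(e) character(0))
    if (!is.null(prev)) expect_true(all(kept_f %in% prev))
    prev <- kept_f
  }
  expect_error(prevalence_filter(m, min_reads = 100, min_fraction = 1),
               "lower")
})

test_that("basis serialization round-trips through the signed table", {
  set.seed(13)
  labs <- paste0("x", 1:6)
  cb <- basis_from_partition(random_sbp(labs), labs)
  tab <- basis_to_table(cb)
  cb2 <- basis_from_table(tab)
  expect_equal(cb2$psi, cb$psi, tolerance = 1e-12)
})
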