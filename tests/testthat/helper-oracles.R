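# Independent oracle machinery used across the suite. Everything here is
# deliberately naive (full enumeration, closed forms evaluated directly)
# and never calls into the package's search code.

rand_clr <- function(D) {
  v <- stats::rnorm(D)
  v - mean(v)
}

# every (num, den) assignment as index sets, sign pairs included
oracle_elements <- function(D) {
  asg <- as.matrix(expand.grid(rep(list(0:2), D)))
  asg <- asg[rowSums(asg == 1) > 0 & rowSums(asg == 2) > 0, , drop = FALSE]
  lapply(seq_len(nrow(asg)), function(i)
    list(num = which(asg[i, ] == 1), den = which(asg[i, ] == 2)))
}

oracle_element_clr <- function(num, den, D) {
  r <- length(num); s <- length(den)
  e <- numeric(D)
  e[num] <- sqrt(r * s / (r + s)) / r
  e[den] <- -sqrt(r * s / (r + s)) / s
  e
}

# largest |projection| over all elements
oracle_best_inner <- function(v, elements = oracle_elements(length(v))) {
  max(vapply(elements, function(e)
    abs(sum(v * oracle_element_clr(e$num, e$den, length(v)))), 0))
}

# can two elements appear in one binary tree?
oracle_compatible <- function(a, b) {
  sa <- c(a$num, a$den); sb <- c(b$num, b$den)
  all(sb %in% a$num) || all(sb %in% a$den) ||
    all(sa %in% b$num) || all(sa %in% b$den) ||
    length(intersect(sa, sb)) == 0
}

element_as_sets <- function(el) {
  labs <- el$universe
  list(num = match(el$num, labs), den = match(el$den, labs))
}

# random sequential binary partition over given labels
random_sbp <- function(labels) {
  parts <- list()
  split_group <- function(group) {
    if (length(group) < 2) return(invisible(NULL))
    k <- sample(seq_len(length(group) - 1), 1)
    idx <- sample(length(group))
    num <- group[idx[seq_len(k)]]
    den <- group[idx[(k + 1):length(group)]]
    parts[[length(parts) + 1]] <<- list(num = num, den = den)
    split_group(num)
    split_group(den)
  }
  split_group(labels)
  parts
}

expect_same_element <- function(a, b) {
  expect_true(
    (setequal(a$num, b$num) && setequal(a$den, b$den)) ||
      (setequal(a$num, b$den) && setequal(a$den, b$num)),
    label = sprintf("{%s|%s} vs {%s|%s}",
                    paste(a$num, collapse = ","), paste(a$den, collapse = ","),
                    paste(b$num, collapse = ","), paste(b$den, collapse = ",")))
}

coffee_labels <- c("espresso", "milk", "syrup")

coffee_basis <- function() {
  basis_from_partition(list(
    list(num = "milk", den = c("espresso", "syrup")),
    list(num = "espresso", den = "syrup")), coffee_labels)
}

# the worked 8-taxon shift used throughout (brute-force-confirmed optimum)
worked_shift <- c(-0.1, -0.8, -0.1, -0.3, 0.1, 0.9, -0.6, 0.9)
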