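#' Nearest balance to a compositional shift
#'
#' Finds the balancing element with maximal cosine to an arbitrary CLR shift
#' vector, and the nearest balance: the orthogonal projection of the shift
#' onto that element. Because the optimal numerator must collect the r
#' largest CLR components and the optimal denominator the s smallest, only
#' the group sizes (r, s) need to be scanned after one descending sort.
#'
#' @param shift Zero-sum numeric vector (CLR coordinates of the shift),
#'   optionally named by taxon.
#' @param labels Optional taxon labels (defaults to `names(shift)` or
#'   `t1..tD`).
#' @param tie_tol Cosines within this tolerance of the maximum are treated
#'   as tied; the reported winner then has the smallest r+s, then the
#'   smallest r, then the lexicographically smallest label sets.
#' @return Object of class `nearest_balance`: list with `element`
#'   (a [balancing_element()]), `coefficient` (the signed projection
#'   length), `cosine`, `impact` (`cosine^2`, the captured share of the
#'   squared shift norm), `distance` (`||shift - balance||`),
#'   `candidate_table` (best cosine per (r, s)), `tied`, `tie_elements`.
#' @examples
#' shift <- clr(closure(c(espresso = 1, milk = 3, syrup = 1)))
#' nearest_balance(shift)
#' @export
nearest_balance <- function(shift, labels = NULL, tie_tol = 1e-12) {
  chk <- nb_check_shift(shift, labels)
  v <- chk$v; labels <- chk$labels
  state <- nb_state(length(v))
  win <- nb_search(state, v, labels, tie_tol)
  res <- nb_result(win, v, labels)
  if (win$cut_tie)
    warning("equal CLR components straddle the group cut; ",
            "balance membership is not unique", call. = FALSE)
  res
}

nb_result <- function(win, v, labels) {
  vnorm <- sqrt(sum(v^2))
  el <- balancing_element(labels[win$num], labels[win$den], labels)
  coef <- win$inner
  structure(list(
    element = el,
    coefficient = coef,
    cosine = win$cosine,
    impact = win$cosine^2,
    distance = sqrt(max(0, vnorm^2 - coef^2)),
    shift_norm = vnorm,
    candidate_table = win$candidates,
    tied = win$tied,
    tie_elements = win$tie_elements),
    class = "nearest_balance")
}

#' @export
print.nearest_balance <- function(x, digits = 4, ...) {
  cat("nearest balance (D = ", length(x$element$universe), ")\n", sep = "")
  cat("  num: ", paste(x$element$num, collapse = ", "), "\n", sep = "")
  cat("  den: ", paste(x$element$den, collapse = ", "), "\n", sep = "")
  cat(sprintf("  coefficient %.*g, cosine %.*g, impact %.*g, distance %.*g\n",
              digits, x$coefficient, digits, x$cosine, digits, x$impact,
              digits, x$distance))
  if (isTRUE(x$tied))
    cat("  note: ", length(x$tie_elements), " elements tied at the optimum\n",
        sep = "")
  invisible(x)
}

#' Best cosine achievable at fixed group sizes
#'
#' For a descendingly sorted CLR vector, the best cosine with any element
#' having r numerator and s denominator parts is
#' `sqrt(rs/(r+s)) * (mean of top r - mean of bottom s) / ||v||`.
#'
#' @param sorted_shift CLR vector sorted in decreasing order.
#' @param r,s Numerator and denominator sizes (`r, s >= 1`, `r + s <= D`).
#' @return The cosine (a scalar).
#' @export
cosine_for_sizes <- function(sorted_shift, r, s) {
  D <- length(sorted_shift)
  if (is.unsorted(rev(sorted_shift)))
    stop("`sorted_shift` must be in decreasing order", call. = FALSE)
  if (r < 1 || s < 1 || r + s > D)
    stop("need r >= 1, s >= 1 and r + s <= D", call. = FALSE)
  vnorm <- sqrt(sum(sorted_shift^2))
  if (vnorm == 0) stop("zero-norm shift", call. = FALSE)
  sqrt(r * s / (r + s)) *
    (sum(sorted_shift[seq_len(r)]) / r -
       sum(sorted_shift[(D - s + 1):D]) / s) / vnorm
}

#' Exhaustive nearest-balance search (testing oracle)
#'
#' Enumerates every assignment of the D taxa to numerator, denominator or
#' excluded (non-empty numerator and denominator; sign-symmetric pairs
#' deduplicated) and returns the global cosine maximizer. Intended as an
#' independent oracle for [nearest_balance()] at small D.
#'
#' @inheritParams nearest_balance
#' @param max_d Enumeration guard (default 12; `3^D` assignments are
#'   scanned).
#' @return A `nearest_balance` object (without the per-(r,s) candidate
#'   table).
#' @export
brute_force_nearest <- function(shift, labels = NULL, max_d = 12,
                                tie_tol = 1e-12) {
  chk <- nb_check_shift(shift, labels)
  v <- chk$v; labels <- chk$labels
  D <- length(v)
  if (D > max_d)
    stop("D = ", D, " too large for exhaustive enumeration (guard at ",
         max_d, "); use nearest_balance()", call. = FALSE)
  asg <- enumerate_elements(D)
  r <- rowSums(asg == 1L); s <- rowSums(asg == 2L)
  SN <- drop((asg == 1L) %*% v); SD <- drop((asg == 2L) %*% v)
  inner <- sqrt(r * s / (r + s)) * (SN / r - SD / s)
  flip <- inner < 0
  if (any(flip)) {   # orient every element so its projection is non-negative
    tmp <- asg[flip, , drop = FALSE]
    asg[flip, ] <- c(0L, 2L, 1L)[tmp + 1L]
    inner[flip] <- -inner[flip]
    tmp2 <- r[flip]; r[flip] <- s[flip]; s[flip] <- tmp2
  }
  vnorm <- sqrt(sum(v^2))
  best <- max(inner)
  hit <- which(inner >= best - tie_tol * vnorm)
  keys <- apply(asg[hit, , drop = FALSE], 1L, paste, collapse = "")
  hit <- hit[!duplicated(keys)]
  ord <- order(r[hit] + s[hit], r[hit],
               vapply(hit, function(i)
                 paste(formatC(labels[asg[i, ] == 1L], width = 12),
                       collapse = ""), ""),
               vapply(hit, function(i)
                 paste(formatC(labels[asg[i, ] == 2L], width = 12),
                       collapse = ""), ""))
  w <- hit[ord[1L]]
  win <- list(num = which(asg[w, ] == 1L), den = which(asg[w, ] == 2L),
              r = r[w], s = s[w], inner = inner[w],
              cosine = inner[w] / vnorm,
              tied = length(hit) > 1L,
              tie_elements = if (length(hit) > 1L) lapply(hit, function(i)
                list(num = labels[asg[i, ] == 1L],
                     den = labels[asg[i, ] == 2L],
                     cosine = inner[i] / vnorm)) else list(),
              candidates = NULL)
  nb_result(win, v, labels)
}

# All 3^D assignments with non-empty numerator (1) and denominator (2);
# 0 marks excluded taxa. Sign-symmetric duplicates are kept and handled by
# orientation in the caller.
enumerate_elements <- function(D) {
  asg <- as.matrix(expand.grid(rep(list(c(0L, 1L, 2L)), D),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(asg) <- NULL
  asg[rowSums(asg == 1L) > 0 & rowSums(asg == 2L) > 0, , drop = FALSE]
}

#' JSON report for a balance search result
#'
#' @param x A `nearest_balance` object.
#' @param ... Extra fields appended to the report.
#' @return A JSON string.
#' @export
balance_report <- function(x, ...) {
  stopifnot(inherits(x, "nearest_balance"))
  rep <- list(numerator = x$element$num,
              denominator = x$element$den,
              coefficient = x$coefficient,
              cosine = x$cosine,
              impact = x$impact,
              distance = x$distance,
              ties = lapply(x$tie_elements, function(t)
                list(numerator = t$num, denominator = t$den)))
  extra <- list(...)
  if (!is.null(x$case)) rep$case <- x$case
  rep[names(extra)] <- extra
  jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
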