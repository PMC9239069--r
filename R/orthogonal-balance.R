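#' Best second balance orthogonal to a given one
#'
#' Finds the balancing element nearest (by cosine) to a second CLR vector
#' `w` among all elements that can appear in one binary tree together with
#' a given first element -- and are therefore orthogonal to it. The
#' tree-compatible candidates fall into three cases: the new node sits
#' inside the first element's numerator or denominator branch (case A), the
#' first element's full taxon set enters the new numerator or denominator
#' as a block (case B), or the two nodes share no taxa (case C).
#'
#' @param first A [balancing_element()].
#' @param w Zero-sum numeric CLR vector over the same universe.
#' @param tie_tol Tie tolerance on cosines (see [nearest_balance()]).
#' @return A `nearest_balance` object with an extra `case` field
#'   (`"A"`, `"B"` or `"C"`) and an `orthogonal_direction` flag set when
#'   `w` carries no component along any feasible element (coefficient 0).
#' @export
second_balance <- function(first, w, tie_tol = 1e-12) {
  stopifnot(inherits(first, "balancing_element"))
  labels <- first$universe
  D <- length(labels)
  if (D < 3L)
    stop("no second balance exists for D < 3", call. = FALSE)
  chk <- nb_check_shift(w, labels)
  v <- chk$v
  state <- nb_state(D)
  state <- nb_apply_element(state,
                            "root",
                            match(first$num, labels),
                            match(first$den, labels),
                            step = 1L)
  win <- nb_search(state, v, labels, tie_tol)
  if (is.null(win)) stop("no tree-compatible second element exists", call. = FALSE)
  res <- nb_result(win, v, labels)
  block_unit <- D + 1L  # the unit created by merging first's taxa
  res$case <- if (win$region %in% c("s1.num", "s1.den")) "A"
    else if (block_unit %in% c(win$num_units, win$den_units)) "B"
    else "C"
  res$orthogonal_direction <- abs(res$coefficient) < 1e-12
  if (res$orthogonal_direction) res$coefficient <- 0
  e1 <- element_clr(first); e2 <- element_clr(res$element)
  if (abs(sum(e1 * e2)) > .ob_tol)
    stop("internal error: second element not orthogonal to the first",
         call. = FALSE)
  res
}

#' Case-B candidate: first balance forced into one side as a block
#'
#' Best element whose `side` (numerator or denominator) contains the whole
#' taxon set of `first` as a block, completed greedily from the decreasingly
#' sorted remaining components of `w`.
#'
#' @inheritParams second_balance
#' @param side `"num"` or `"den"`: which side absorbs the first balance.
#' @return List with `element`, `inner` (projection of `w`), `cosine`, or
#'   `NULL` when no taxa remain outside `first`.
#' @export
case_b_search <- function(first, w, side = c("num", "den")) {
  side <- match.arg(side)
  stopifnot(inherits(first, "balancing_element"))
  labels <- first$universe
  chk <- nb_check_shift(w, labels)
  v <- stats::setNames(chk$v, labels)
  block <- c(first$num, first$den)
  outside <- setdiff(labels, block)
  if (!length(outside)) return(NULL)
  m <- length(block)
  Tblock <- sum(v[block])
  wo <- sort(v[outside], decreasing = TRUE)
  n_out <- length(wo)
  top <- c(0, cumsum(wo))           # prefix sums of the largest components
  bot <- c(0, cumsum(rev(wo)))      # prefix sums of the smallest components
  best <- NULL
  for (extra in 0:(n_out - 1L)) {   # outside taxa joining the block's side
    for (other in 1:(n_out - extra)) {
      if (side == "num") {
        r <- m + extra; s <- other
        SN <- Tblock + top[extra + 1L]; SD <- bot[other + 1L]
      } else {
        s <- m + extra; r <- other
        SD <- Tblock + bot[extra + 1L]; SN <- top[other + 1L]
      }
      inner <- unname(sqrt(r * s / (r + s)) * (SN / r - SD / s))
      if (is.null(best) || inner > best$inner)
        best <- list(extra = extra, other = other, r = r, s = s, inner = inner)
    }
  }
  if (side == "num") {
    num <- c(block, names(wo)[seq_len(best$extra)])
    den <- names(rev(wo))[seq_len(best$other)]
  } else {
    den <- c(block, names(rev(wo))[seq_len(best$extra)])
    num <- names(wo)[seq_len(best$other)]
  }
  el <- balancing_element(num, den, labels)
  list(element = el, inner = best$inner,
       cosine = best$inner / sqrt(sum(chk$v^2)))
}
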