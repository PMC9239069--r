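# Internal search machinery shared by the nearest-balance search (A1), the
# orthogonal second balance (A2) and the nearest-balance tree (A3).
#
# The state of a partially built sequential binary partition is a forest:
# `units` are groups of taxa already known to form a branch of the final
# tree (initially the D singletons); `regions` are sets of units among
# which a new node may still be placed (the root region, plus the two child
# sides of every placed node). A new balancing element picks disjoint
# non-empty unit subsets of one region for its numerator and denominator;
# this generates exactly the elements co-realizable in one binary tree with
# all previously placed elements, hence orthogonal to them.

nb_state <- function(D) {
  list(units = as.list(seq_len(D)),
       regions = list(root = seq_len(D)),
       nodes = list())
}

nb_apply_element <- function(state, region_id, num_units, den_units, step) {
  new_id <- length(state$units) + 1L
  taxa <- sort(unlist(state$units[c(num_units, den_units)], use.names = FALSE))
  state$units[[new_id]] <- taxa
  state$regions[[region_id]] <-
    c(setdiff(state$regions[[region_id]], c(num_units, den_units)), new_id)
  if (length(num_units) >= 2L)
    state$regions[[paste0("s", step, ".num")]] <- num_units
  if (length(den_units) >= 2L)
    state$regions[[paste0("s", step, ".den")]] <- den_units
  state$nodes[[step]] <- list(
    num = sort(unlist(state$units[num_units], use.names = FALSE)),
    den = sort(unlist(state$units[den_units], use.names = FALSE)),
    region = region_id)
  state
}

# All candidate elements within one region, for a fixed CLR target vector v.
# Units are grouped into weight classes; within a class (sorted by unit sum,
# descending) the numerator always takes units from the top and the
# denominator from the bottom, which is optimal for any class usage counts.
# All per-class usage-count combinations are enumerated jointly, covering
# every feasible (r, s) size pair.
nb_region_candidates <- function(state, region_id, v, max_combos = 2e6) {
  unit_ids <- state$regions[[region_id]]
  m <- length(unit_ids)
  if (m < 2L) return(NULL)
  w <- vapply(state$units[unit_ids], length, 0L)
  tsum <- vapply(state$units[unit_ids], function(tx) sum(v[tx]), 0)
  first_tax <- vapply(state$units[unit_ids], min, 0L)

  classes <- list()
  for (cw in sort(unique(w))) {
    idx <- which(w == cw)
    ord <- idx[order(-tsum[idx], first_tax[idx])]
    ts <- tsum[ord]
    classes[[length(classes) + 1L]] <- list(
      weight = cw,
      units = unit_ids[ord],          # region units, best mean first
      top = c(0, cumsum(ts)),         # prefix sums from the top
      bot = c(0, cumsum(rev(ts))),    # prefix sums from the bottom
      tsorted = ts,
      n = length(idx))
  }

  pair_list <- lapply(classes, function(cl) {
    p <- expand.grid(kN = 0:cl$n, kD = 0:cl$n)
    p[p$kN + p$kD <= cl$n, , drop = FALSE]
  })
  n_combos <- prod(vapply(pair_list, nrow, 0L))
  if (n_combos > max_combos)
    stop("candidate enumeration too large (", format(n_combos, big.mark = ","),
         " combinations); reduce the number of parts", call. = FALSE)
  combo <- expand.grid(lapply(pair_list, function(p) seq_len(nrow(p))))

  r <- s <- SN <- SD <- numeric(nrow(combo))
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    kN <- pair_list[[ci]]$kN[combo[[ci]]]
    kD <- pair_list[[ci]]$kD[combo[[ci]]]
    r <- r + cl$weight * kN
    s <- s + cl$weight * kD
    SN <- SN + cl$top[kN + 1L]
    SD <- SD + cl$bot[kD + 1L]
  }
  ok <- r >= 1 & s >= 1
  if (!any(ok)) return(NULL)
  inner <- sqrt(r * s / (r + s)) * (SN / r - SD / s)
  list(region = region_id, classes = classes, pair_list = pair_list,
       combo = combo[ok, , drop = FALSE],
       r = r[ok], s = s[ok], inner = inner[ok])
}

# Materialize the num/den unit sets (and taxa) of candidate row i.
nb_candidate_sets <- function(cand, i, state) {
  num_units <- integer(0); den_units <- integer(0)
  for (ci in seq_along(cand$classes)) {
    cl <- cand$classes[[ci]]
    p <- cand$pair_list[[ci]][cand$combo[i, ci], ]
    if (p$kN > 0) num_units <- c(num_units, cl$units[seq_len(p$kN)])
    if (p$kD > 0) den_units <- c(den_units, cl$units[cl$n - seq_len(p$kD) + 1L])
  }
  list(num_units = num_units, den_units = den_units,
       num = sort(unlist(state$units[num_units], use.names = FALSE)),
       den = sort(unlist(state$units[den_units], use.names = FALSE)))
}

# Whether candidate i sits on a within-class tie (equal unit sums straddling
# the numerator or denominator cut), making set membership non-unique.
nb_candidate_cut_tie <- function(cand, i, tol = 1e-12) {
  for (ci in seq_along(cand$classes)) {
    cl <- cand$classes[[ci]]
    p <- cand$pair_list[[ci]][cand$combo[i, ci], ]
    ts <- cl$tsorted
    if (p$kN > 0 && p$kN < cl$n - p$kD &&
        abs(ts[p$kN] - ts[p$kN + 1L]) <= tol) return(TRUE)
    if (p$kD > 0 && cl$n - p$kD > p$kN &&
        abs(ts[cl$n - p$kD + 1L] - ts[cl$n - p$kD]) <= tol) return(TRUE)
  }
  FALSE
}

# Search every open region of `state` for the element with maximal cosine to
# the CLR vector v. Ties within `tie_tol` of the maximum cosine are broken by
# smaller r+s, then smaller r, then lexicographically smaller numerator and
# denominator label sets. Returns NULL when no region is open.
nb_search <- function(state, v, labels, tie_tol = 1e-12) {
  vnorm <- sqrt(sum(v^2))
  cands <- list()
  for (rid in names(state$regions)) {
    cd <- nb_region_candidates(state, rid, v)
    if (!is.null(cd)) cands[[rid]] <- cd
  }
  if (!length(cands)) return(NULL)
  best <- max(unlist(lapply(cands, `[[`, "inner")))
  # collect contenders within the tie tolerance (cosine scale)
  contenders <- list()
  for (cd in cands) {
    hit <- which(cd$inner >= best - tie_tol * vnorm)
    for (i in hit) {
      sets <- nb_candidate_sets(cd, i, state)
      contenders[[length(contenders) + 1L]] <- list(
        region = cd$region, sets = sets, r = cd$r[i], s = cd$s[i],
        inner = cd$inner[i], cand = cd, idx = i,
        key = paste(paste(sets$num, collapse = ","),
                    paste(sets$den, collapse = ","), sep = "|"))
    }
  }
  keys <- vapply(contenders, `[[`, "", "key")
  contenders <- contenders[!duplicated(keys)]
  ord <- order(
    vapply(contenders, function(ct) ct$r + ct$s, 0),
    vapply(contenders, function(ct) ct$r, 0),
    vapply(contenders, function(ct)
      paste(formatC(labels[ct$sets$num], width = 12), collapse = ""), ""),
    vapply(contenders, function(ct)
      paste(formatC(labels[ct$sets$den], width = 12), collapse = ""), ""))
  win <- contenders[[ord[1L]]]
  list(region = win$region,
       num_units = win$sets$num_units, den_units = win$sets$den_units,
       num = win$sets$num, den = win$sets$den,
       r = win$r, s = win$s, inner = win$inner,
       cosine = if (vnorm > 0) win$inner / vnorm else 0,
       tied = length(contenders) > 1L,
       tie_elements = if (length(contenders) > 1L) lapply(contenders, function(ct)
         list(num = labels[ct$sets$num], den = labels[ct$sets$den],
              cosine = if (vnorm > 0) ct$inner / vnorm else 0)) else list(),
       cut_tie = nb_candidate_cut_tie(win$cand, win$idx),
       candidates = nb_candidate_table(cands, vnorm))
}

# Diagnostic: best cosine per (r, s) over all open regions.
nb_candidate_table <- function(cands, vnorm) {
  df <- do.call(rbind, lapply(cands, function(cd)
    data.frame(r = cd$r, s = cd$s, inner = cd$inner)))
  agg <- stats::aggregate(inner ~ r + s, data = df, FUN = max)
  agg$cosine <- if (vnorm > 0) agg$inner / vnorm else 0
  agg[order(-agg$cosine), c("r", "s", "cosine")]
}

# Normalize a user-facing CLR shift argument: accepts a named/plain numeric
# zero-sum vector; returns list(v, labels).
nb_check_shift <- function(shift, labels = NULL, min_norm = 1e-12) {
  if (!is.numeric(shift)) stop("`shift` must be a numeric CLR vector", call. = FALSE)
  if (is.null(labels)) labels <- names(shift)
  if (is.null(labels)) labels <- paste0("t", seq_along(shift))
  if (length(labels) != length(shift)) stop("labels/shift length mismatch", call. = FALSE)
  if (abs(sum(shift)) > 1e-6)
    stop("`shift` must be a CLR vector (sum zero); got sum ",
         signif(sum(shift), 3), call. = FALSE)
  if (sqrt(sum(shift^2)) <= min_norm)
    stop("zero-norm shift: no direction to approximate", call. = FALSE)
  list(v = unname(shift), labels = as.character(labels))
}
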