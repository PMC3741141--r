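#' Pairwise lane weights from a connection set
#'
#' Sums connection weights between each pair of phenotypes over everything
#' in the current view (all times and lags present in `connections`),
#' direction-blind. This symmetric matrix is the input to the lane-ordering
#' objective: total weight between adjacent lanes.
#'
#' @param connections a [connection_set].
#' @param phenotypes phenotype universe defining matrix order.
#' @return symmetric non-negative matrix with zero diagonal, dimnames
#'   `phenotypes`.
#' @export
lane_weights <- function(connections, phenotypes) {
  stopifnot(inherits(connections, "connection_set"))
  W <- matrix(0, length(phenotypes), length(phenotypes),
              dimnames = list(phenotypes, phenotypes))
  for (r in seq_len(nrow(connections))) {
    p <- connections$source[r]; q <- connections$target[r]
    if (p == q) next
    if (!(p %in% phenotypes) || !(q %in% phenotypes))
      abort_key(sprintf("connection endpoint '%s' not in phenotype list",
                        if (p %in% phenotypes) q else p))
    W[p, q] <- W[p, q] + connections$weight[r]
    W[q, p] <- W[q, p] + connections$weight[r]
  }
  W
}

#' Total connection weight between adjacent lanes of an ordering
#'
#' @param ordering character vector, a permutation of the phenotypes of
#'   `weights`.
#' @param weights symmetric lane-weight matrix from [lane_weights()].
#' @return sum of `weights[o[i], o[i + 1]]` over consecutive lanes.
#' @export
adjacent_score <- function(ordering, weights) {
  if (!setequal(ordering, rownames(weights)) ||
      length(ordering) != nrow(weights))
    abort_key("ordering is not a permutation of the weight matrix phenotypes")
  if (length(ordering) < 2L) return(0)
  sum(weights[cbind(ordering[-length(ordering)], ordering[-1L])])
}

#' Reorder phenotype lanes to maximize adjacent connection weight
#'
#' Greedy agglomerative chain merging: every lane starts as a singleton
#' chain; the two chains with the largest total between-chain weight are
#' merged, concatenated in whichever of the four end-to-end orientations
#' puts the most weight across the new junction; the final chain, polished
#' by a deterministic 2-opt segment-reversal pass, is the ordering. The
#' result is guaranteed never to score below the input order
#' (fallback), and ties are broken lexicographically by chain label so the
#' output is deterministic.
#'
#' @param weights symmetric lane-weight matrix from [lane_weights()].
#' @param tie_seed accepted for interface stability; ties are resolved
#'   lexicographically, so the value has no effect.
#' @return character vector: the lane ordering (class `lane_ordering`).
#' @export
order_lanes <- function(weights, tie_seed = NULL) {
  phen <- rownames(weights)
  stopifnot(!is.null(phen), nrow(weights) == ncol(weights))
  if (length(phen) <= 2L)
    return(structure(phen, class = c("lane_ordering", "character")))
  chains <- lapply(phen, identity)
  # label = lexicographically smallest member; stable tie-break key
  chain_label <- function(ch) min(ch)
  while (length(chains) > 1L) {
    best <- NULL; best_w <- -Inf
    ord <- order(vapply(chains, chain_label, character(1)))
    for (ii in seq_along(ord)) for (jj in seq_along(ord)) {
      if (jj <= ii) next
      i <- ord[ii]; j <- ord[jj]
      w <- sum(weights[chains[[i]], chains[[j]]])
      if (w > best_w) { best_w <- w; best <- c(i, j) }
    }
    a <- chains[[best[1L]]]; b <- chains[[best[2L]]]
    # four end-to-end orientations; junction weight decides
    cand <- list(c(a, b), c(a, rev(b)), c(rev(a), b), c(rev(a), rev(b)))
    jw <- vapply(cand, function(ch)
      weights[ch[length(a)], ch[length(a) + 1L]], numeric(1))
    merged <- cand[[which.max(jw)]]
    chains <- c(chains[-best], list(merged))
  }
  out <- refine_ordering(chains[[1L]], weights)
  if (adjacent_score(out, weights) < adjacent_score(phen, weights))
    out <- phen
  structure(out, class = c("lane_ordering", "character"))
}

# 2-opt refinement: reverse contiguous segments while that raises the
# adjacent score; deterministic sweep order, first-improvement
refine_ordering <- function(o, weights) {
  n <- length(o)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      cand <- o
      cand[i:j] <- rev(cand[i:j])
      if (adjacent_score(cand, weights) >
          adjacent_score(o, weights) + 1e-12) {
        o <- cand
        improved <- TRUE
      }
    }
  }
  o
}
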