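#' Maximum-weight matching heuristic
#'
#' Interprets a symmetric median matrix as a weighted graph on the
#' extremities: an edge `{i, j}` carries weight `2 |m[i,j]|` and a potential
#' telomere at `i` carries weight `|m[i,i]|`; weights below `eps` are
#' discarded as numerically insignificant. A maximum-weight matching of this
#' graph (telomeres modelled as matched self-states) is returned as a genome.
#' The matching is solved exactly per connected component by dynamic
#' programming over vertex subsets for components of at most `max_component`
#' vertices, and greedily above that size.
#'
#' @param m Square symmetric numeric matrix.
#' @param eps Weight threshold (default `1e-6`).
#' @param max_component Largest component size solved exactly (default 16).
#' @return A [genome()].
#' @export
matching_heuristic <- function(m, eps = 1e-6, max_component = 16L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  w <- 2 * abs(m)
  diag(w) <- 0
  w[w <= eps] <- 0
  loops <- abs(diag(m))
  loops[loops <= eps] <- 0
  pairing <- seq_len(n)
  for (comp in weight_components(w)) {
    k <- length(comp)
    if (k == 1L) next
    sub <- w[comp, comp, drop = FALSE]
    lp <- loops[comp]
    sel <- if (k <= max_component) matching_exact(sub, lp)
           else matching_greedy(sub, lp)
    pairing[comp] <- comp[sel]
  }
  genome(pairing, warn_odd = FALSE)
}

# connected components of the thresholded weight graph, ordered by smallest
# vertex
weight_components <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i
    seen[i] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- which(w[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# exact maximum-weight matching with telomere gains, by subset DP;
# returns the pairing as indices into 1..k (self for telomere)
matching_exact <- function(w, loops) {
  k <- nrow(w)
  nmask <- bitwShiftL(1L, k)
  dp <- numeric(nmask)
  choice <- integer(nmask)  # 0 = telomere for the lowest vertex, else partner
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (mask in seq_len(nmask - 1L)) {
    v <- which(bitwAnd(mask, bits) != 0L)[1L]
    rest <- bitwAnd(mask, bitwNot(bits[v]))
    best <- dp[rest + 1L] + loops[v]
    pick <- 0L
    others <- which(bitwAnd(rest, bits) != 0L)
    for (u in others) {
      if (w[v, u] > 0) {
        cand <- dp[bitwAnd(rest, bitwNot(bits[u])) + 1L] + w[v, u]
        if (cand > best + 1e-12) {
          best <- cand
          pick <- u
        }
      }
    }
    dp[mask + 1L] <- best
    choice[mask + 1L] <- pick
  }
  sel <- seq_len(k)
  mask <- nmask - 1L
  while (mask > 0L) {
    v <- which(bitwAnd(mask, bits) != 0L)[1L]
    u <- choice[mask + 1L]
    mask <- bitwAnd(mask, bitwNot(bits[v]))
    if (u > 0L) {
      sel[v] <- u
      sel[u] <- v
      mask <- bitwAnd(mask, bitwNot(bits[u]))
    }
  }
  sel
}

# deterministic greedy fallback for oversized components
matching_greedy <- function(w, loops) {
  k <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ord <- order(-w[idx], idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  sel <- seq_len(k)
  free <- rep(TRUE, k)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (free[i] && free[j]) {
      sel[i] <- j
      sel[j] <- i
      free[c(i, j)] <- FALSE
    }
  }
  sel
}

#' Rows of a median with fractional entries
#'
#' For a symmetric orthogonal median, the rows (equivalently columns) holding
#' at least one non-integer entry form the index set `R`; the matrix is
#' binary outside of the rows and columns of `R` (asserted). An entry near -1
#' cannot occur in such a median and raises an internal error.
#'
#' @param m Symmetric numeric matrix.
#' @param tol Distance-to-integer tolerance (default `1e-6`).
#' @return Sorted integer vector of 1-based row indices (possibly empty).
#' @export
fractional_rows <- function(m, tol = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(abs(m + 1) < tol))
    stop("internal error: -1 entry in a median matrix")
  frac <- abs(m - round(m)) > tol
  r <- sort(which(rowSums(frac) > 0))
  if (length(r) < nrow(m)) {
    rest <- setdiff(seq_len(nrow(m)), r)
    stopifnot("non-binary entry outside fractional rows" =
                !any(frac[rest, rest]))
  }
  r
}

#' Count and enumerate involutions
#'
#' The number of genomes (involutions, telomeres allowed) on `k` extremities
#' obeys `I(k) = I(k-1) + (k-1) I(k-2)`. `enumerate_involutions()` lists them
#' all in a deterministic order: the smallest unplaced extremity is first a
#' telomere, then paired with each larger available extremity in increasing
#' order.
#'
#' @param k Number of extremities.
#' @return `count_involutions()`: a number (exact while below 2^53).
#'   `enumerate_involutions()`: a `k x I(k)` integer matrix whose columns are
#'   pairing vectors.
#' @examples
#' count_involutions(6)             # 76
#' ncol(enumerate_involutions(4))   # 10
#' @export
count_involutions <- function(k) {
  stopifnot(k >= 0L)
  if (k < 2L) return(1)
  i2 <- 1; i1 <- 1
  for (j in 2:k) {
    cur <- i1 + (j - 1) * i2
    i2 <- i1
    i1 <- cur
  }
  i1
}

#' @rdname count_involutions
#' @export
enumerate_involutions <- function(k) {
  stopifnot(k >= 0L, k <= 16L)
  total <- count_involutions(k)
  out <- matrix(0L, nrow = max(k, 1L), ncol = total)
  if (k == 0L) return(matrix(0L, 0L, 1L))
  col <- 0L
  pairing <- integer(k)
  recurse <- function(avail) {
    if (length(avail) == 0L) {
      col <<- col + 1L
      out[, col] <<- pairing
      return(invisible())
    }
    x <- avail[1L]
    pairing[x] <<- x
    recurse(avail[-1L])
    for (j in seq_along(avail)[-1L]) {
      y <- avail[j]
      pairing[x] <<- y
      pairing[y] <<- x
      recurse(avail[-c(1L, j)])
    }
    invisible()
  }
  recurse(seq_len(k))
  out
}

#' Closest-genome heuristic
#'
#' Replaces the fractional block of a symmetric orthogonal median by the
#' genomic matrix nearest to it in rank distance. The fractional rows `R`
#' split into connected components (an edge wherever `|M^R[i,j]| > tol`);
#' the search is restricted to block-diagonal genomes over those components,
#' solved exhaustively per component (each must have at most `max_block`
#' vertices). Ties among equally close blocks are broken by the lower median
#' score of the assembled genome against the inputs, then by enumeration
#' order.
#'
#' @param m Symmetric orthogonal median matrix for `(a, b, c)`.
#' @param a,b,c The input [genome()] objects.
#' @param max_block Largest component searched exhaustively (default 10).
#' @param tol Entry tolerance (default `1e-6`).
#' @param rank_tol Relative rank tolerance for block distances.
#' @return A list of class `"recovery_outcome"`: `genome`, `score`,
#'   `gap` (score minus `beta`), `method = "closest"`, `blocks` (component
#'   sizes), `block_min_dist` and `block_n_closest` (per-component minimum
#'   rank distance and number of genomes attaining it).
#' @export
closest_genome_heuristic <- function(m, a, b, c, max_block = 10L,
                                     tol = 1e-6, rank_tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) == a$n)
  inv <- median_invariants(a, b, c)
  r_set <- fractional_rows(m, tol)
  if (length(r_set) == 0L) {
    g <- matrix_to_genome(m, tol)
    s <- median_score(g, a, b, c)
    return(structure(list(genome = g, score = s, gap = s - inv$beta,
                          method = "closest", blocks = integer(0),
                          block_min_dist = integer(0),
                          block_n_closest = integer(0)),
                     class = "recovery_outcome"))
  }
  mr <- m[r_set, r_set, drop = FALSE]
  adj <- abs(mr) > tol
  diag(adj) <- FALSE
  comps <- weight_components(adj * 1)
  sizes <- lengths(comps)
  if (any(sizes > max_block))
    stop("component too large for exhaustive search (size ",
         max(sizes), " > max_block = ", max_block, ")")
  block_sets <- list()   # per component: matrix of argmin pairings
  block_dist <- integer(length(comps))
  block_ncl <- integer(length(comps))
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    blk <- mr[comp, comp, drop = FALSE]
    cands <- enumerate_involutions(length(comp))
    dists <- apply(cands, 2L, function(pr) {
      gm <- matrix(0, length(comp), length(comp))
      gm[cbind(seq_along(comp), pr)] <- 1
      matrix_rank(gm - blk, rank_tol)
    })
    dmin <- min(dists)
    hit <- which(dists == dmin)
    block_sets[[ci]] <- cands[, hit, drop = FALSE]
    block_dist[ci] <- dmin
    block_ncl[ci] <- length(hit)
  }
  # integer part of the median outside R is itself a partial genome
  base_pairing <- apply(round(m), 1L, which.max)
  assemble <- function(choice) {
    pairing <- base_pairing
    for (ci in seq_along(comps)) {
      orig <- r_set[comps[[ci]]]
      pairing[orig] <- orig[block_sets[[ci]][, choice[ci]]]
    }
    genome(as.integer(pairing), warn_odd = FALSE)
  }
  n_comb <- prod(block_ncl)
  if (n_comb > 64) {
    choices <- matrix(1L, 1L, length(comps))
  } else {
    choices <- as.matrix(expand.grid(lapply(block_ncl, seq_len)))
  }
  best <- NULL
  best_score <- Inf
  for (r in seq_len(nrow(choices))) {
    g <- assemble(choices[r, ])
    s <- median_score(g, a, b, c)
    if (s < best_score) {
      best <- g
      best_score <- s
    }
  }
  structure(list(genome = best, score = best_score,
                 gap = best_score - inv$beta, method = "closest",
                 blocks = sizes, block_min_dist = block_dist,
                 block_n_closest = block_ncl),
            class = "recovery_outcome")
}

#' @export
print.recovery_outcome <- function(x, ...) {
  cat("recovered genome (", x$method, "): ", format_cycles(x$genome),
      "\n  score = ", x$score, " (gap over beta: ", x$gap, ")\n", sep = "")
  if (length(x$blocks))
    cat("  blocks:", paste(x$blocks, collapse = " "),
        "; per-block min rank distance:",
        paste(x$block_min_dist, collapse = " "), "\n")
  invisible(x)
}

#' Exhaustive search for the best-scoring genomes
#'
#' Enumerates every involution on `n` extremities and returns the minimum
#' median score together with all genomes attaining it, in enumeration order.
#' Only feasible for small `n` (guard: `n <= 12`).
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return A list with `best_score` (integer) and `genomes` (list of
#'   [genome()] objects).
#' @export
brute_force_best_genomes <- function(a, b, c) {
  stopifnot(is_genome(a))
  n <- a$n
  if (n > 12L) stop("n = ", n, " too large for exhaustive search (max 12)")
  cands <- enumerate_involutions(n)
  scores <- integer(ncol(cands))
  pa <- a$pairing; pb <- b$pairing; pc <- c$pairing
  for (k in seq_len(ncol(cands))) {
    pr <- cands[, k]
    scores[k] <- 3L * n - cycle_count(pr[pa]) - cycle_count(pr[pb]) -
      cycle_count(pr[pc])
  }
  best <- min(scores)
  list(best_score = best,
       genomes = lapply(which(scores == best),
                        function(k) genome(cands[, k], warn_odd = FALSE)))
}
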