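#' Number of cycles of a permutation
#'
#' Counts the cycles (including fixed points) of a permutation given as a
#' total map, i.e. an integer vector `p` with `p[i]` the image of `i`.
#'
#' @param p Integer vector; must be a bijection on `1..length(p)`.
#' @return Integer cycle count.
#' @export
cycle_count <- function(p) {
  p <- as.integer(p)
  n <- length(p)
  if (n == 0L) return(0L)
  if (anyNA(p) || any(p < 1L) || any(p > n) || anyDuplicated(p))
    stop("not a bijection on 1..", n)
  seen <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      k <- k + 1L
      j <- i
      while (!seen[j]) {
        seen[j] <- TRUE
        j <- p[j]
      }
    }
  }
  k
}

# cycles of a permutation, each sorted internally by traversal from its
# smallest element; cycles ordered by smallest element
permutation_cycles <- function(p) {
  n <- length(p)
  seen <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (!seen[i]) {
      cyc <- i
      seen[i] <- TRUE
      j <- p[i]
      while (!seen[j]) {
        cyc <- c(cyc, j)
        seen[j] <- TRUE
        j <- p[j]
      }
      out[[length(out) + 1L]] <- cyc
    }
  }
  out
}

# composition: (a * b)(i) = a(b(i)) -- matches the juxtaposition AB used for
# products of genomes, where B is applied first
compose_permutations <- function(a, b) a[b]

#' Rank distance between two genomes
#'
#' The rank distance is `d(A, B) = rank(A - B)` on genomic matrices. For
#' involutions it equals `n - c(AB)`, where `c` counts cycles (with fixed
#' points) of the product permutation, so it is computed exactly in integers.
#'
#' @param a,b [genome()] objects on the same extremity set.
#' @return Integer distance.
#' @examples
#' a <- parse_cycles("(2 4)(3 9)(6 8)(10 11)", 12)
#' b <- parse_cycles("(2 7)(3 8)(4 5)(6 9)(10 11)", 12)
#' rank_distance(a, b)  # 5
#' @export
rank_distance <- function(a, b) {
  stopifnot(is_genome(a), is_genome(b))
  if (a$n != b$n) stop("genomes have different extremity counts")
  a$n - cycle_count(compose_permutations(a$pairing, b$pairing))
}

#' Rank distance between two matrices
#'
#' Numerical rank of `x - y`: the number of singular values exceeding
#' `tol * max(1, largest singular value)`.
#'
#' @param x,y Numeric matrices of equal shape.
#' @param tol Relative singular-value tolerance (default `1e-9`).
#' @return Integer rank.
#' @export
rank_distance_matrices <- function(x, y, tol = 1e-9) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!all(dim(x) == dim(y))) stop("matrices have different shapes")
  matrix_rank(x - y, tol = tol)
}

matrix_rank <- function(m, tol = 1e-9) {
  if (length(m) == 0L) return(0L)
  s <- svd(m, nu = 0L, nv = 0L)$d
  sum(s > tol * max(1, s[1L]))
}

#' The three median invariants
#'
#' For genomes A, B, C: `beta` is half the sum of the pairwise rank distances
#' (the lower bound on any median score), `alpha` the dimension of the triple
#' agreement subspace `{x : Ax = Bx = Cx}` (the number of weakly connected
#' components of the union of the graphs of the products AB and BC), and
#' `delta = alpha + beta - n` the deficiency. For genomic inputs `beta` is an
#' integer and `delta >= 0`; both are asserted.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return A list of class `"median_invariants"` with integer fields `alpha`,
#'   `beta`, `delta`, `n` and the pairwise distances `d_ab`, `d_bc`, `d_ca`.
#' @examples
#' tr <- lapply(c("(2 4)(3 9)(6 8)(10 11)",
#'                "(2 7)(3 8)(4 5)(6 9)(10 11)",
#'                "(2 3)(4 5)(6 7)(8 9)(10 11)"), parse_cycles, n = 12)
#' median_invariants(tr[[1]], tr[[2]], tr[[3]])  # alpha 5, beta 8, delta 1
#' @export
median_invariants <- function(a, b, c) {
  stopifnot(is_genome(a), is_genome(b), is_genome(c))
  if (a$n != b$n || b$n != c$n) stop("genomes have different extremity counts")
  n <- a$n
  d_ab <- rank_distance(a, b)
  d_bc <- rank_distance(b, c)
  d_ca <- rank_distance(c, a)
  two_beta <- d_ab + d_bc + d_ca
  stopifnot("pairwise distance sum must be even for genomes" = two_beta %% 2L == 0L)
  beta <- two_beta %/% 2L
  alpha <- length(union_components(a, b, c))
  delta <- alpha + beta - n
  stopifnot("deficiency must be non-negative for genomes" = delta >= 0L)
  structure(list(alpha = alpha, beta = beta, delta = delta, n = n,
                 d_ab = d_ab, d_bc = d_bc, d_ca = d_ca),
            class = "median_invariants")
}

#' @export
print.median_invariants <- function(x, ...) {
  cat("median invariants (n = ", x$n, "): alpha = ", x$alpha,
      ", beta = ", x$beta, ", delta = ", x$delta,
      "  [d(A,B) = ", x$d_ab, ", d(B,C) = ", x$d_bc,
      ", d(C,A) = ", x$d_ca, "]\n", sep = "")
  invisible(x)
}

# weakly connected components of the union of the graph representations of
# the products AB and BC; these support the indicator basis of the triple
# agreement subspace V1
union_components <- function(a, b, c) {
  n <- a$n
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  ab <- compose_permutations(a$pairing, b$pairing)
  bc <- compose_permutations(b$pairing, c$pairing)
  for (i in seq_len(n)) {
    link(i, ab[i])
    link(i, bc[i])
  }
  roots <- vapply(seq_len(n), find, 0L)
  split(seq_len(n), roots)  # ordered by smallest element (root is minimum)
}

#' Median score of a candidate
#'
#' The score of a candidate median `m` against genomes A, B, C is
#' `d(A, m) + d(B, m) + d(C, m)`. When `m` is a genome the three distances are
#' computed exactly by cycle counting; when it is a matrix, by numerical rank
#' of the differences. The score never falls below `beta(A, B, C)` (asserted).
#'
#' @param m A [genome()] or an `n x n` numeric matrix.
#' @param a,b,c [genome()] objects.
#' @param tol Rank tolerance for the matrix case.
#' @return Integer score.
#' @export
median_score <- function(m, a, b, c, tol = 1e-9) {
  inv <- median_invariants(a, b, c)
  s <- if (is_genome(m)) {
    rank_distance(m, a) + rank_distance(m, b) + rank_distance(m, c)
  } else {
    stopifnot(is.matrix(m), all(dim(m) == a$n))
    rank_distance_matrices(m, genome_to_matrix(a), tol) +
      rank_distance_matrices(m, genome_to_matrix(b), tol) +
      rank_distance_matrices(m, genome_to_matrix(c), tol)
  }
  stopifnot("score fell below the beta lower bound" = s >= inv$beta)
  as.integer(s)
}
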