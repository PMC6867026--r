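#' Standard basis of the triple agreement subspace
#'
#' The triple agreement subspace `V1 = {x : Ax = Bx = Cx}` is spanned by the
#' indicator vectors of the weakly connected components of the union of the
#' graph representations of the products AB and BC. Components (and hence
#' columns) are ordered by smallest element.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return An `n x alpha` numeric matrix of 0/1 indicator columns.
#' @export
triple_agreement_basis <- function(a, b, c) {
  stopifnot(is_genome(a), is_genome(b), is_genome(c))
  if (a$n != b$n || b$n != c$n) stop("genomes have different extremity counts")
  comps <- union_components(a, b, c)
  m <- matrix(0, a$n, length(comps))
  for (k in seq_along(comps)) m[comps[[k]], k] <- 1
  m
}

#' Standard basis of a pairwise agreement subspace
#'
#' For a product permutation `p` (AB for V2, BC for V3, CA for V4), the
#' subspace of vectors on which the two factors agree but which are orthogonal
#' to V1 is spanned by the cycle indicator vectors of `p` minus their
#' orthogonal projections onto the triple-agreement basis. Every cycle of `p`
#' lies inside one triple-agreement component, and within each component the
#' projected indicators sum to zero; one vector per component is therefore
#' dropped (the largest cycle, ties broken by dropping the later one in
#' smallest-element-first order), leaving `c(p) - alpha` independent columns.
#'
#' @param p Integer permutation vector (a product of two genome involutions).
#' @param b1 Triple-agreement basis matrix from [triple_agreement_basis()].
#' @return An `n x (c(p) - alpha)` numeric matrix (possibly with 0 columns).
#' @export
pairwise_basis <- function(p, b1) {
  p <- as.integer(p)
  n <- length(p)
  stopifnot(is.matrix(b1), nrow(b1) == n)
  cycles <- permutation_cycles(p)
  # component index of each extremity (columns of b1 are disjoint indicators)
  comp_of <- as.integer(b1 %*% seq_len(ncol(b1)))
  sizes <- colSums(b1)
  cols <- list()
  cyc_comp <- integer(0)
  cyc_len <- integer(0)
  for (cyc in cycles) {
    comp <- comp_of[cyc[1L]]
    if (any(comp_of[cyc] != comp))
      stop("internal error: product cycle crosses triple-agreement components")
    v <- numeric(n)
    v[cyc] <- 1
    v[b1[, comp] > 0] <- v[b1[, comp] > 0] - length(cyc) / sizes[comp]
    cols[[length(cols) + 1L]] <- v
    cyc_comp <- c(cyc_comp, comp)
    cyc_len <- c(cyc_len, length(cyc))
  }
  # drop one (dependent) vector per component: the largest cycle, later wins ties
  drop <- logical(length(cols))
  for (comp in unique(cyc_comp)) {
    idx <- which(cyc_comp == comp)
    drop[idx[max(which(cyc_len[idx] == max(cyc_len[idx])))]] <- TRUE
  }
  kept <- cols[!drop]
  if (length(kept) == 0L) return(matrix(0, n, 0L))
  do.call(cbind, kept)
}

#' Dimensions of the five subspaces
#'
#' The inputs split `R^n` into a direct sum of five subspaces: the triple
#' agreement subspace V1 (dimension `alpha`), the pairwise agreement
#' subspaces V2, V3, V4 (dimensions `c(AB) - alpha`, `c(BC) - alpha`,
#' `c(CA) - alpha`), and the disagreement subspace V5 (dimension `2 delta`).
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return Integer vector of five dimensions summing to `n`.
#' @examples
#' tr <- lapply(c("(2 4)(3 9)(6 8)(10 11)",
#'                "(2 7)(3 8)(4 5)(6 9)(10 11)",
#'                "(2 3)(4 5)(6 7)(8 9)(10 11)"), parse_cycles, n = 12)
#' subspace_dims(tr[[1]], tr[[2]], tr[[3]])  # 5 2 3 0 2
#' @export
subspace_dims <- function(a, b, c) {
  inv <- median_invariants(a, b, c)
  n <- inv$n
  c_ab <- n - inv$d_ab
  c_bc <- n - inv$d_bc
  c_ca <- n - inv$d_ca
  dims <- c(inv$alpha, c_ab - inv$alpha, c_bc - inv$alpha, c_ca - inv$alpha,
            2L * inv$delta)
  stopifnot("subspace dimensions must sum to n" = sum(dims) == n)
  dims
}

#' Standard bases B1..B4 of the agreement subspaces
#'
#' Builds the four agreement-subspace bases used by the median formula. The
#' disagreement subspace V5 is never given an explicit basis; the median
#' formula bypasses it.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return A list of class `"subspace_bases"` with fields `b1`..`b4` (numeric
#'   matrices with `n` rows), `dims` (the five dimensions), and `n`.
#' @export
subspace_bases <- function(a, b, c) {
  dims <- subspace_dims(a, b, c)
  b1 <- triple_agreement_basis(a, b, c)
  b2 <- pairwise_basis(compose_permutations(a$pairing, b$pairing), b1)
  b3 <- pairwise_basis(compose_permutations(b$pairing, c$pairing), b1)
  b4 <- pairwise_basis(compose_permutations(c$pairing, a$pairing), b1)
  got <- c(ncol(b1), ncol(b2), ncol(b3), ncol(b4))
  stopifnot("basis column counts disagree with subspace dimensions" =
              all(got == dims[1:4]))
  structure(list(b1 = b1, b2 = b2, b3 = b3, b4 = b4, dims = dims, n = a$n),
            class = "subspace_bases")
}

#' @export
print.subspace_bases <- function(x, ...) {
  cat("subspace bases on n =", x$n, "; dim(V1..V5) =",
      paste(x$dims, collapse = " "), "\n")
  invisible(x)
}
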