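#' Generalized rank-distance median of three genomes
#'
#' Computes the generalized median `M_I`: the matrix that acts as A on the
#' triple agreement subspace V1 and the pairwise agreement subspace V2, as B
#' on V3, as C on V4, and as the identity on the disagreement subspace V5.
#' With `B14 = [B1, B2, B3, B4]` the concatenated agreement bases, it is
#' evaluated in one shot as
#' `M_I = I + ([A B1, A B2, B B3, C B4] - B14) (B14' B14)^{-1} B14'`,
#' which never needs a basis of V5. `M_I` is always symmetric, orthogonal,
#' has unit row sums, attains the lower-bound score `beta`, and contains
#' every adjacency or telomere shared by at least two inputs; all of these
#' guarantees are verified on the returned object.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @param exact If `TRUE`, solve the normal equations in integer arithmetic
#'   (fraction-free Gauss-Jordan elimination on integer-scaled bases) and
#'   attach the exact rational form of the median.
#' @param tol Entry tolerance used for the genomicity and conservation checks.
#' @param rank_tol Relative tolerance for numerical ranks.
#' @return An object of class `"rank_median"`: a list with fields
#'   `m` (the median matrix), `invariants` ([median_invariants()]),
#'   `dims` (five subspace dimensions), `score` (equal to `beta`),
#'   `is_genomic`, `genome` (the median as a [genome()] when genomic),
#'   `conserved` (data frame from [check_conservation()]),
#'   `diagnostics` (the three optimality dimensions, all equal to `delta`),
#'   and in exact mode `m_num`/`m_den` with `m = m_num / m_den` exactly.
#' @examples
#' tr <- lapply(c("(1 3)(2 8)(5 7)", "(1 6)(2 7)(3 4)(5 8)",
#'                "(1 2)(3 4)(5 6)(7 8)"), parse_cycles, n = 8)
#' med <- compute_median(tr[[1]], tr[[2]], tr[[3]])
#' med$score        # 8, the beta lower bound
#' med$is_genomic   # FALSE: entries with denominator 6 remain
#' @export
compute_median <- function(a, b, c, exact = FALSE, tol = 1e-6,
                           rank_tol = 1e-9) {
  inv <- median_invariants(a, b, c)
  n <- inv$n
  if (n == 0L) stop("cannot compute a median on zero extremities")
  bases <- subspace_bases(a, b, c)
  ma <- genome_to_matrix(a)
  mb <- genome_to_matrix(b)
  mc_ <- genome_to_matrix(c)
  b14 <- cbind(bases$b1, bases$b2, bases$b3, bases$b4)
  f <- cbind(ma %*% bases$b1, ma %*% bases$b2,
             mb %*% bases$b3, mc_ %*% bases$b4)
  exact_form <- NULL
  if (exact) {
    exact_form <- median_exact(b14, f, ma, mb, mc_)
    m <- exact_form$m
  } else {
    # (B14'B14)^{-1} applied through a linear solve, never an explicit inverse
    m <- diag(n) + (f - b14) %*% solve(crossprod(b14), t(b14))
  }
  # guaranteed structural properties
  stopifnot("median is not symmetric" = max(abs(m - t(m))) < tol,
            "median is not orthogonal" = max(abs(crossprod(m) - diag(n))) < tol,
            "median row sums differ from 1" = max(abs(rowSums(m) - 1)) < tol,
            "median does not map B14 to the majority images" =
              max(abs(m %*% b14 - f)) < tol)
  score <- median_score(m, a, b, c, tol = rank_tol)
  stopifnot("median score does not attain the beta lower bound" =
              score == inv$beta)
  diagnostics <- optimality_diagnostics(a, b, c, bases = bases,
                                        rank_tol = rank_tol)
  stopifnot("optimality diagnostics differ from delta" =
              all(diagnostics == inv$delta))
  conserved <- check_conservation(a, b, c, m, tol = tol)
  stopifnot("a 2-of-3 feature is missing from the median" =
              all(conserved$present))
  g <- tryCatch(matrix_to_genome(m, tol = tol), error = function(e) NULL)
  structure(list(m = m, invariants = inv, dims = bases$dims, score = score,
                 is_genomic = !is.null(g), genome = g, conserved = conserved,
                 diagnostics = diagnostics,
                 m_num = exact_form$num_int, m_den = exact_form$den),
            class = "rank_median")
}

#' @export
print.rank_median <- function(x, ...) {
  inv <- x$invariants
  cat("generalized rank median on n =", inv$n, "\n")
  cat("  alpha =", inv$alpha, " beta =", inv$beta, " delta =", inv$delta,
      " dims(V1..V5) =", paste(x$dims, collapse = " "), "\n")
  cat("  score =", x$score, " genomic:", x$is_genomic, "\n")
  if (x$is_genomic) cat("  genome:", format_cycles(x$genome), "\n")
  invisible(x)
}

# exact rational median via integer-scaled bases and fraction-free
# (Bareiss) Gauss-Jordan elimination; num/den kept in doubles, which are
# exact for integers below 2^53 (guarded)
median_exact <- function(b14, f, ma, mb, mc_) {
  n <- nrow(b14)
  k <- ncol(b14)
  if (k == 0L) stop("internal error: empty agreement basis")
  # scale each column to integers: entries are 1 - l/s and -l/s with s the
  # number of nonzeros in the column (the component size), l the cycle length
  scale <- apply(b14, 2L, function(v) {
    nz <- sum(abs(v) > 1e-12)
    if (nz == 0L) 1 else nz
  })
  bi <- round(sweep(b14, 2L, scale, `*`))
  fi <- round(sweep(f, 2L, scale, `*`))
  if (max(abs(sweep(b14, 2L, scale, `*`) - bi)) > 1e-6)
    stop("internal error: basis column does not scale to integers")
  s <- round(crossprod(bi))                      # k x k integer, SPD
  aug <- cbind(s, t(bi))                         # solve S X = Bi'
  prev <- 1
  for (p in seq_len(k)) {
    piv <- aug[p, p]
    if (piv == 0) stop("internal error: zero pivot in exact elimination")
    for (i in seq_len(k)) {
      if (i == p) next
      row <- (piv * aug[i, ] - aug[i, p] * aug[p, ]) / prev
      if (max(abs(row)) > 2^52)
        stop("exact mode overflow: instance too large for exact arithmetic")
      if (max(abs(row - round(row))) > 1e-6)
        stop("internal error: inexact division in Bareiss elimination")
      aug[i, ] <- round(row)
    }
    prev <- piv
  }
  dens <- diag(aug)[seq_len(k)]
  l <- abs(dens[1L])
  for (d in dens[-1L]) l <- l / num_gcd(l, abs(d)) * abs(d)
  if (l > 2^52) stop("exact mode overflow: common denominator too large")
  x_int <- aug[, k + seq_len(n), drop = FALSE] * (l / dens)
  num <- l * diag(n) + (fi - bi) %*% x_int
  if (max(abs(num)) > 2^52) stop("exact mode overflow in numerator matrix")
  g <- l
  for (v in num) g <- num_gcd(g, abs(v))
  if (g == 0) g <- 1
  list(m = num / l, num_int = num / g, den = l / g)
}

num_gcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b > 0.5) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

#' Remove features shared by all three genomes
#'
#' Adjacencies and telomeres present in all three inputs can be assumed
#' present in a median, so they are removed and the remaining extremities
#' renumbered `1..n'` in increasing order. [restore_genome()] and
#' [restore_matrix()] invert the reduction.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @return A list with the reduced genomes `a`, `b`, `c`, the `kept` original
#'   extremity labels (in order, so reduced label `i` is original `kept[i]`),
#'   `fixed` (list of removed features, each an integer vector of length 1 for
#'   a telomere or 2 for an adjacency), and `n_original`.
#' @export
reduce_unanimous <- function(a, b, c) {
  stopifnot(is_genome(a), is_genome(b), is_genome(c))
  if (a$n != b$n || b$n != c$n) stop("genomes have different extremity counts")
  n <- a$n
  same <- a$pairing == b$pairing & b$pairing == c$pairing
  drop <- same  # extremities whose (identical) pairing is unanimous
  fixed <- list()
  for (i in which(same)) {
    j <- a$pairing[i]
    if (j == i) fixed[[length(fixed) + 1L]] <- i
    else if (i < j) fixed[[length(fixed) + 1L]] <- c(i, j)
  }
  kept <- which(!drop)
  relabel <- integer(n)
  relabel[kept] <- seq_along(kept)
  shrink <- function(g) {
    genome(relabel[g$pairing[kept]], name = g$name, warn_odd = FALSE)
  }
  list(a = shrink(a), b = shrink(b), c = shrink(c),
       kept = kept, fixed = fixed, n_original = n)
}

#' Restore a reduced genome or matrix to the original extremity set
#'
#' @param g A [genome()] on the reduced extremity set.
#' @param kept,fixed,n_original Reduction map as returned by
#'   [reduce_unanimous()].
#' @return `restore_genome()`: a [genome()] on `n_original` extremities with
#'   the fixed features reinstated. `restore_matrix()`: an
#'   `n_original x n_original` matrix embedding `m` on the kept rows/columns
#'   and the fixed features as exact 0/1 entries.
#' @export
restore_genome <- function(g, kept, fixed, n_original) {
  stopifnot(is_genome(g), g$n == length(kept))
  pairing <- rep(NA_integer_, n_original)
  pairing[kept] <- kept[g$pairing]
  for (ft in fixed) {
    if (any(!is.na(pairing[ft]))) stop("label collision restoring feature")
    if (length(ft) == 1L) pairing[ft] <- ft
    else pairing[ft] <- rev(ft)
  }
  if (anyNA(pairing)) stop("restore map does not cover every extremity")
  genome(pairing, name = g$name, warn_odd = FALSE)
}

#' @rdname restore_genome
#' @param m A numeric matrix on the reduced extremity set.
#' @export
restore_matrix <- function(m, kept, fixed, n_original) {
  stopifnot(is.matrix(m), nrow(m) == length(kept))
  out <- matrix(0, n_original, n_original)
  out[kept, kept] <- m
  for (ft in fixed) {
    if (length(ft) == 1L) out[ft, ft] <- 1
    else {
      out[ft[1L], ft[2L]] <- 1
      out[ft[2L], ft[1L]] <- 1
    }
  }
  out
}

#' Optimality diagnostics of the identity-action median
#'
#' A median candidate that acts as the majority on V1..V4 and as the identity
#' on V5 attains the `beta` lower bound if and only if the three subspaces
#' `V_I^A = {x + y : x in V3, y in V5, A(x+y) = Bx + y}` (and the analogues
#' for B over V4 and C over V2) all have dimension `delta`. Each dimension is
#' computed as the nullity of the corresponding linear map on coefficient
#' space, with V5 realized as the orthogonal complement of the concatenated
#' agreement bases.
#'
#' @param a,b,c [genome()] objects on the same extremity set.
#' @param bases Optionally, precomputed [subspace_bases()].
#' @param rank_tol Relative rank tolerance.
#' @return Integer vector `(dim V_I^A, dim V_I^B, dim V_I^C)`.
#' @export
optimality_diagnostics <- function(a, b, c, bases = NULL, rank_tol = 1e-9) {
  if (is.null(bases)) bases <- subspace_bases(a, b, c)
  n <- bases$n
  ma <- genome_to_matrix(a)
  mb <- genome_to_matrix(b)
  mc_ <- genome_to_matrix(c)
  b14 <- cbind(bases$b1, bases$b2, bases$b3, bases$b4)
  n5 <- null_space_basis(t(b14), rank_tol)  # basis of V5
  nullity <- function(mx, my, pair_basis) {
    coef <- cbind((mx - my) %*% pair_basis, (mx - diag(n)) %*% n5)
    ncol(coef) - matrix_rank(coef, rank_tol)
  }
  c(nullity(ma, mb, bases$b3),
    nullity(mb, mc_, bases$b4),
    nullity(mc_, ma, bases$b2))
}

# orthonormal basis of {x : m x = 0} (full LAPACK SVD supplies the
# null-space completion of V)
null_space_basis <- function(m, tol = 1e-9) {
  p <- ncol(m)
  if (p == 0L) return(matrix(0, 0L, 0L))
  sv <- svd(m, nu = 0L, nv = p)
  r <- sum(sv$d > tol * max(1, sv$d[1L]))
  if (r == p) matrix(0, p, 0L) else sv$v[, (r + 1L):p, drop = FALSE]
}

#' Conservation of 2-of-3 adjacencies and telomeres
#'
#' Every adjacency or telomere shared by at least two of the three input
#' genomes is guaranteed to be present in any orthogonal median. A feature is
#' present in a matrix when its entries are 1 and the rest of the involved
#' rows and columns are 0.
#'
#' @param a,b,c [genome()] objects.
#' @param m The median matrix to check.
#' @param tol Entry tolerance.
#' @return A data frame with one row per shared feature: columns `i`, `j`
#'   (equal for a telomere), `support` (2 or 3 input genomes) and `present`.
#' @export
check_conservation <- function(a, b, c, m, tol = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == a$n)
  n <- a$n
  votes <- cbind(a$pairing, b$pairing, c$pairing)
  feats <- list()
  for (i in seq_len(n)) {
    tab <- table(votes[i, ])
    j <- as.integer(names(tab)[tab >= 2L])
    for (jj in j) {
      if (jj >= i) {
        feats[[length(feats) + 1L]] <-
          c(i = i, j = jj, support = max(tab[as.character(jj)]))
      }
    }
  }
  if (length(feats) == 0L)
    return(data.frame(i = integer(0), j = integer(0), support = integer(0),
                      present = logical(0)))
  df <- as.data.frame(do.call(rbind, feats))
  zmax <- function(v) if (length(v)) max(abs(v)) else 0
  df$present <- vapply(seq_len(nrow(df)), function(k) {
    i <- df$i[k]; j <- df$j[k]
    abs(m[i, j] - 1) < tol && abs(m[j, i] - 1) < tol &&
      zmax(m[i, -j]) < tol && zmax(m[-j, i]) < tol &&
      zmax(m[j, -i]) < tol && zmax(m[-i, j]) < tol
  }, TRUE)
  df
}
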