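# shared fixtures: the 12-extremity example triple, its reduction, and the
# known 8x8 median, plus small independent oracles used across tests

example_triple <- function() {
  list(a = parse_cycles("(2 4)(3 9)(6 8)(10 11)", 12, "A"),
       b = parse_cycles("(2 7)(3 8)(4 5)(6 9)(10 11)", 12, "B"),
       c = parse_cycles("(2 3)(4 5)(6 7)(8 9)(10 11)", 12, "C"))
}

reduced_triple <- function() {
  list(a = parse_cycles("(1 3)(2 8)(5 7)", 8, "A'"),
       b = parse_cycles("(1 6)(2 7)(3 4)(5 8)", 8, "B'"),
       c = parse_cycles("(1 2)(3 4)(5 6)(7 8)", 8, "C'"))
}

# the known median of the reduced triple, as 6 * M_I
known_median_6x <- function() {
  matrix(c(
     4,  2, 0, 0, -2,  2, -2,  2,
     2,  1, 0, 0, -1, -2,  5,  1,
     0,  0, 0, 6,  0,  0,  0,  0,
     0,  0, 6, 0,  0,  0,  0,  0,
    -2, -1, 0, 0,  1,  2,  1,  5,
     2, -2, 0, 0,  2,  4,  2, -2,
    -2,  5, 0, 0,  1,  2,  1, -1,
     2,  1, 0, 0,  5, -2, -1,  1), 8, 8, byrow = TRUE)
}

# independent involution sampler (not the package's recursive-law sampler):
# shuffle the extremities and pair successive ones with probability 1/2
rand_involution <- function(n) {
  ord <- sample.int(n)
  pairing <- seq_len(n)
  i <- 1L
  while (i < n) {
    if (stats::runif(1) < 0.5) {
      pairing[ord[i]] <- ord[i + 1L]
      pairing[ord[i + 1L]] <- ord[i]
      i <- i + 2L
    } else i <- i + 1L
  }
  suppressWarnings(genome(pairing))  # odd n is fine for these algebra tests
}

# independent rank oracle via QR decomposition (the package uses SVD)
qr_rank <- function(m) if (length(m) == 0) 0L else qr(m, tol = 1e-9)$rank

# exhaustive maximum-weight matching oracle: enumerate every matching on the
# support graph of a symmetric matrix m (edges 2|m_ij| > eps, loops |m_ii|)
brute_matching_weight <- function(m, eps = 1e-6) {
  n <- nrow(m)
  best <- -Inf
  recurse <- function(free, acc) {
    if (length(free) == 0L) {
      best <<- max(best, acc)
      return(invisible())
    }
    v <- free[1L]
    loop <- abs(m[v, v])
    recurse(free[-1L], acc + if (loop > eps) loop else 0)
    for (u in free[-1L]) {
      w <- 2 * abs(m[v, u])
      if (w > eps) recurse(setdiff(free, c(v, u)), acc + w)
    }
    invisible()
  }
  recurse(seq_len(n), 0)
  best
}

# weight of the matching encoded by a genome under the heuristic's weights
matching_weight_of <- function(g, m, eps = 1e-6) {
  w <- 0
  adj <- adjacencies(g)
  if (nrow(adj)) for (r in seq_len(nrow(adj))) {
    e <- 2 * abs(m[adj[r, 1L], adj[r, 2L]])
    if (e > eps) w <- w + e
  }
  for (t in telomeres(g)) {
    l <- abs(m[t, t])
    if (l > eps) w <- w + l
  }
  w
}
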