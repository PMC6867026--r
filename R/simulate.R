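#' Sample a genome uniformly at random
#'
#' Draws a uniformly random involution on `n` extremities by the standard
#' recursive construction: the largest remaining extremity is a telomere with
#' probability `I(n-1)/I(n)` (computed through the involution-count ratio
#' recurrence, stable for large `n`) and otherwise pairs with a uniformly
#' chosen remaining extremity. Uses R's global random number generator;
#' seed with [set.seed()] for reproducibility.
#'
#' @param n Number of extremities.
#' @param name Optional label.
#' @return A [genome()].
#' @export
random_genome <- function(n, name = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (n == 0L) return(genome(integer(0), name = name))
  # ratios r_k = I(k)/I(k-1): r_1 = 1, r_k = 1 + (k-1)/r_{k-1}
  ratio <- numeric(n)
  ratio[1L] <- 1
  if (n > 1L) for (k in 2:n) ratio[k] <- 1 + (k - 1) / ratio[k - 1L]
  pairing <- integer(n)
  avail <- seq_len(n)
  while (length(avail) > 0L) {
    m <- length(avail)
    x <- avail[m]
    if (m == 1L || stats::runif(1) < 1 / ratio[m]) {
      pairing[x] <- x
      avail <- avail[-m]
    } else {
      y <- avail[sample.int(m - 1L, 1L)]
      pairing[x] <- y
      pairing[y] <- x
      avail <- setdiff(avail, c(x, y))
    }
  }
  genome(pairing, name = name)
}

#' Apply one random SCJ operation
#'
#' A single cut-or-join: one operation drawn uniformly from the union of all
#' possible cuts (break one adjacency into two telomeres) and all possible
#' joins (glue two telomeres into an adjacency). The result is always at rank
#' distance exactly 1 from the input.
#'
#' @param g A [genome()].
#' @return A [genome()].
#' @export
apply_scj <- function(g) {
  stopifnot(is_genome(g))
  adj <- adjacencies(g)
  tel <- telomeres(g)
  n_cut <- nrow(adj)
  n_join <- length(tel) * (length(tel) - 1L) / 2L
  if (n_cut + n_join == 0L)
    stop("no SCJ operation possible on this genome")
  pairing <- g$pairing
  pick <- sample.int(n_cut + n_join, 1L)
  if (pick <= n_cut) {
    pairing[adj[pick, ]] <- adj[pick, ]
  } else {
    pair <- pair_from_index(pick - n_cut, length(tel))
    i <- tel[pair[1L]]; j <- tel[pair[2L]]
    pairing[i] <- j
    pairing[j] <- i
  }
  genome(pairing, name = g$name, warn_odd = FALSE)
}

# k-th unordered pair {i, j}, i < j, of 1..m in lexicographic order
pair_from_index <- function(k, m) {
  i <- 1L
  while (k > m - i) {
    k <- k - (m - i)
    i <- i + 1L
  }
  c(i, i + k)
}

#' Apply one random DCJ operation
#'
#' A double cut-and-join drawn uniformly over all (element pair, rewiring)
#' outcomes: two distinct elements among the adjacencies and telomeres are
#' picked and their extremities rewired. Two adjacencies `{a,b}`, `{c,d}`
#' yield the double swaps `{a,c},{b,d}` or `{a,d},{b,c}`; an adjacency
#' `{a,b}` and a telomere `t` yield `{a,t}` (b freed) or `{b,t}` (a freed);
#' two telomeres are joined. The result is at rank distance 1 (join) or 2
#' (other outcomes) from the input.
#'
#' @param g A [genome()].
#' @return A [genome()].
#' @export
apply_dcj <- function(g) {
  stopifnot(is_genome(g))
  adj <- adjacencies(g)
  tel <- telomeres(g)
  na <- nrow(adj)
  nt <- length(tel)
  w_aa <- na * (na - 1L)            # 2 outcomes per adjacency pair
  w_at <- 2L * na * nt              # 2 outcomes per adjacency-telomere pair
  w_tt <- nt * (nt - 1L) / 2L       # 1 outcome per telomere pair
  if (w_aa + w_at + w_tt == 0L)
    stop("no DCJ operation possible on this genome")
  pairing <- g$pairing
  pick <- sample.int(w_aa + w_at + w_tt, 1L)
  if (pick <= w_aa) {
    variant <- (pick - 1L) %% 2L
    pair <- pair_from_index((pick - 1L) %/% 2L + 1L, na)
    a <- adj[pair[1L], 1L]; b <- adj[pair[1L], 2L]
    c_ <- adj[pair[2L], 1L]; d <- adj[pair[2L], 2L]
    if (variant == 0L) {
      pairing[c(a, c_)] <- c(c_, a)
      pairing[c(b, d)] <- c(d, b)
    } else {
      pairing[c(a, d)] <- c(d, a)
      pairing[c(b, c_)] <- c(c_, b)
    }
  } else if (pick <= w_aa + w_at) {
    k <- pick - w_aa - 1L
    variant <- k %% 2L
    k <- k %/% 2L
    ai <- k %/% nt + 1L
    t <- tel[k %% nt + 1L]
    keep <- adj[ai, variant + 1L]       # extremity staying with the telomere
    free <- adj[ai, 2L - variant]
    pairing[c(keep, t)] <- c(t, keep)
    pairing[free] <- free
  } else {
    pair <- pair_from_index(pick - w_aa - w_at, nt)
    i <- tel[pair[1L]]; j <- tel[pair[2L]]
    pairing[i] <- j
    pairing[j] <- i
  }
  genome(pairing, name = g$name, warn_odd = FALSE)
}

#' Simulate a rearrangement triple
#'
#' Draws a uniformly random ancestor genome on `2 * n_genes` extremities and
#' derives three descendants by applying `round(r * n_genes)` independent
#' random SCJ or DCJ operations to three copies of it.
#'
#' @param n_genes Number of genes (so `2 * n_genes` extremities).
#' @param r Rearrangement rate; each descendant receives
#'   `round(r * n_genes)` operations.
#' @param model `"SCJ"` or `"DCJ"`.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A list of class `"rearrangement_triple"` with genomes `a`, `b`,
#'   `c`, the `ancestor`, and fields `n`, `r`, `model`, `ops_applied`, `seed`.
#' @examples
#' tr <- generate_triple(10, 0.2, "DCJ", seed = 1)
#' median_invariants(tr$a, tr$b, tr$c)
#' @export
generate_triple <- function(n_genes, r, model = c("SCJ", "DCJ"), seed = NULL) {
  model <- match.arg(toupper(model), c("SCJ", "DCJ"))
  stopifnot(n_genes >= 1L, r >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * as.integer(n_genes)
  ops <- as.integer(round(r * n_genes))
  ancestor <- random_genome(n, name = "ancestor")
  evolve <- function(nm) {
    g <- ancestor
    if (ops > 0L) for (k in seq_len(ops)) {
      g <- if (model == "SCJ") apply_scj(g) else apply_dcj(g)
    }
    g$name <- nm
    g
  }
  structure(list(a = evolve("A"), b = evolve("B"), c = evolve("C"),
                 ancestor = ancestor, n = n, r = r, model = model,
                 ops_applied = ops, seed = seed),
            class = "rearrangement_triple")
}

#' @export
print.rearrangement_triple <- function(x, ...) {
  cat("simulated", x$model, "triple: n =", x$n, "extremities,",
      x$ops_applied, "ops/genome (rate", x$r, ")\n")
  invisible(x)
}
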