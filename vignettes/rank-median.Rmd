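---
title: "Rank-distance medians of three genomes: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-distance medians of three genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankmedian)
```

## The model

A genome on `n` gene extremities is an involution of `{1..n}`: a 2-cycle
`(i j)` is an adjacency (the extremities are glued), a fixed point is a
telomere. Its genomic matrix `M` (the permutation matrix of the involution)
is binary, symmetric and orthogonal, and the rank distance

$$ d(A, B) = \operatorname{rank}(A - B) = n - c(AB) $$

counts, in the cycle form, how far apart two genomes are; `c` is the number
of cycles of the product permutation, fixed points included. This distance
assigns weight 1 to single cuts and joins and weight 2 to double swaps, so
it behaves like a DCJ-type distance while remaining a genuine matrix metric.

Given three genomes, write $\beta = \tfrac12[d(A,B)+d(B,C)+d(C,A)]$ (an
integer for genomic inputs), $\alpha$ for the dimension of the triple
agreement subspace $V_1 = \{x : Ax = Bx = Cx\}$, and
$\delta = \alpha + \beta - n \ge 0$ for the deficiency. $\beta$ is a lower
bound on the score $d(A,M)+d(B,M)+d(C,M)$ of every matrix $M$. The inputs
decompose $\mathbb R^n$ as
$V_1 \oplus V_2 \oplus V_3 \oplus V_4 \oplus V_5$ with
$\dim V_2 = c(AB)-\alpha$, $\dim V_3 = c(BC)-\alpha$,
$\dim V_4 = c(CA)-\alpha$ and $\dim V_5 = 2\delta$. The generalized median
computed by `compute_median()` acts as $A$ on $V_1$ and $V_2$, as $B$ on
$V_3$, as $C$ on $V_4$, and as the identity on the disagreement space
$V_5$. It always attains the $\beta$ bound, is symmetric and orthogonal
with unit row sums, and conserves every adjacency and telomere shared by
at least two inputs. These are theorems about the construction; the package
treats them as run-time assertions so that a violation is an implementation
bug, never a silent wrong answer. The price of generality is that the
median may have fractional (rational) entries, i.e. fail to be a genome.

## Computing the median

`subspace_bases()` builds standard bases without ever touching $V_5$:

* $B_1$: indicator vectors of the weakly connected components of the union
  of the graphs of the products $AB$ and $BC$. These have disjoint supports
  and are therefore orthogonal.
* $B_2, B_3, B_4$: for each cycle of the relevant product ($AB$, $BC$,
  $CA$), the indicator vector minus its orthogonal projection onto $B_1$.
  Within each $V_1$-component the projected indicators sum to zero, so one
  of them is redundant even when none is numerically zero. We drop exactly
  one vector per component — the largest cycle, breaking ties toward the
  later cycle in smallest-element-first order. The resulting counts are
  exactly $c(\cdot) - \alpha$. The median itself is invariant under the
  choice of which dependent vector is dropped (any spanning set per
  subspace yields the same projector); the rule only pins down the
  *printed* bases deterministically.

With $B_{14} = [B_1, B_2, B_3, B_4]$ the median is evaluated as
$$ M_I = I + ([A B_1, A B_2, B B_3, C B_4] - B_{14})
          (B_{14}^{\mathsf T} B_{14})^{-1} B_{14}^{\mathsf T}, $$
applied through a linear solve (never an explicit inverse). On $V_5$,
$B_{14}^{\mathsf T} x = 0$, so the formula silently acts as the identity
there — no basis of $V_5$ is ever needed.

Optimality is certified through the three diagnostic subspaces: the median
attains $\beta$ exactly when
$\dim V_I^A = \dim V_I^B = \dim V_I^C = \delta$, where, e.g.,
$V_I^A = \{x + y : x \in V_3,\ y \in V_5,\ A(x+y) = Bx + y\}$. Each
dimension is the nullity of a small coefficient-space map, with $V_5$
realized as the orthogonal complement of the column span of $B_{14}$.

### Reduction by unanimous features

Adjacencies and telomeres carried by all three inputs can be assumed present
in a median, so `reduce_unanimous()` removes them and renumbers the
remaining extremities in increasing order before the median is computed;
`restore_genome()`/`restore_matrix()` re-embed results. Only 3-of-3 features
are pre-fixed: a 2-of-3 feature would perturb the dissenting genome's
distances if forced, and conservation of such features is a guarantee we
*verify* on the output rather than an assumption we bake into the input.

## Numerical choices

* **Two tolerance regimes.** Entry-level decisions (is this entry 0 or 1,
  is this feature present, is this matching weight significant) use
  `1e-6`; rank decisions use a relative singular-value cutoff of `1e-9`
  (`sigma > 1e-9 * max(1, sigma_max)`). Genome–genome distances never touch
  floating point at all: they are computed by integer cycle counting.
* **Exact mode.** `compute_median(exact = TRUE)` scales each basis column to
  integers (multiplying by its component size) and solves the normal
  equations by fraction-free (Bareiss) Gauss-Jordan elimination, in which
  every intermediate division is exact. The result is an integer numerator
  matrix with a single common denominator, reduced by their gcd. All values
  are held in doubles, exact below $2^{53}$; a guard aborts well before
  that. This makes small instances bit-exact (the bundled 8-extremity
  example has denominator 6) without requiring a big-integer dependency.
* **Degenerate inputs.** Three identical genomes reduce to an empty
  instance; the pipeline short-circuits to the common genome with score 0.
  Odd extremity counts are accepted with a one-time warning (the algebra is
  parity-agnostic; whole-gene genomes have even `n`).
* **Determinism.** Component and cycle orderings are smallest-element-first
  throughout, so bases, enumeration orders and tie-breaks are reproducible
  across runs and platforms.

## Recovering a genome from a fractional median

**Maximum-weight matching.** The median's entries are read as a weighted
graph: edge `{i,j}` with weight `2|M_ij|`, potential telomere `i` with
weight `|M_ii|`, both thresholded at `1e-6`. The genome returned is a
maximum-weight matching. Because the graph decomposes into connected
components — and binary rows of an orthogonal median form isolated edges or
loops — an exact subset-DP per component suffices: components of up to 16
vertices (default) are solved optimally in $O(2^k k)$, larger ones by a
deterministic greedy pass. We chose subset DP over a blossom implementation
because the components that arise from orthogonal, unit-row-sum medians
are small in practice, and an exact small-component solver is easy to
verify against exhaustive enumeration.

**Closest genome by rank distance.** The fractional rows `R` of the median
are split into connected components of the nonzero pattern of `M[R,R]`
(which is block-diagonal across components, so rank distance decomposes as
a sum over blocks). For each component of size at most `max_block = 10`,
every involution on the block (9496 at size 10) is scored by the numerical
rank of its difference to the block, and the minimizers are kept. The
search is restricted to block-diagonal candidates — a heuristic, not a
theorem; the test suite cross-checks it against unrestricted brute force on
the bundled example. Ties across blocks are resolved by the lower median
score of the assembled genome, then by enumeration order. The integer part
of the median outside `R` is kept verbatim, as any closest genome must
agree with it there.

On the bundled 12-extremity example the matching heuristic scores
$\beta + 2$ and the closest-genome heuristic $\beta + 1$, which exhaustive
search confirms is optimal among genomes — both facts are reproduced by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## What the simulator emulates

`generate_triple(n_genes, r, model)` draws a uniformly random involution on
`2 * n_genes` extremities (by the telephone-number recurrence
`I(k) = I(k-1) + (k-1) I(k-2)`, with ratios iterated in floating point so
large `n` cannot overflow) and applies `round(r * n_genes)` operations
independently to three copies:

* **SCJ**: one operation uniform over all cuts (one per adjacency) and all
  joins (one per telomere pair); always rank distance 1.
* **DCJ**: one operation uniform over all (element pair, rewiring)
  outcomes on two distinct adjacencies/telomeres: two adjacencies admit the
  two double swaps, an adjacency and a telomere the two exchanges, two
  telomeres a join; rank distance 1 or 2. Under this pairing scheme a pure
  cut never occurs as a DCJ outcome; this is a documented package choice
  for the operation pool, made once and kept.

The defaults mirror the regime the method is intended for: rates
`r` between 0.05 and 0.3 on tens to hundreds of genes, where SCJ triples
are overwhelmingly deficiency-zero (hence genomic medians) while DCJ
triples frequently have $\delta > 0$ and fractional medians. The test
sweep uses 200 triples with up to 200 extremities — sizes chosen so the
whole suite exercises every guarantee (symmetry, orthogonality, score
$= \beta$, diagnostics $= \delta$, 2-of-3 conservation, cycle-count vs
SVD-rank agreement) at desk scale.

What the simulator does **not** emulate: gene content evolution
(duplication, gain/loss), chromosome-count constraints, operation-rate
heterogeneity along the genome, or any correlation between the three
lineages beyond their shared ancestor. Passing tests therefore demonstrate
the algebraic guarantees and the heuristics' behaviour under a clean
uniform-operations model, not calibration to any particular biological
data set.

## Known limitations

* The closest-genome heuristic fails (by design, with an informative error)
  when a fractional component exceeds `max_block`; the pipeline then falls
  back to the matching heuristic under `method = "auto"`.
* `brute_force_best_genomes()` is capped at `n = 12` (140,152 candidates).
* Exact mode is intended for small-to-moderate instances; it aborts if
  intermediate integers approach $2^{52}$ rather than silently losing
  precision.
* The package finds *one* generalized median with guaranteed properties;
  enumerating all medians, and the genomic-median decision problem itself,
  are outside its scope.
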