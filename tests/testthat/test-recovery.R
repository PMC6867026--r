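test_that("the matching heuristic recovers the known genome from the median", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  g <- matching_heuristic(med$m)
  expect_true(g == parse_cycles("(3 4)(2 7)(5 8)", 8))
  expect_equal(median_score(g, red$a, red$b, red$c), 10L)
})

test_that("the matching heuristic is exact on a genomic matrix", {
  set.seed(51)
  for (k in 1:10) {
    g <- rand_involution(sample(2:12, 1))
    expect_true(matching_heuristic(genome_to_matrix(g)) == g)
  }
})

test_that("matching weight matches the exhaustive matching oracle", {
  set.seed(52)
  found <- 0L
  tries <- 0L
  while (found < 6L && tries < 200L) {
    tries <- tries + 1L
    tr <- generate_triple(4, 0.5, "DCJ")
    med <- compute_median(tr$a, tr$b, tr$c)
    if (med$is_genomic) next
    found <- found + 1L
    g <- matching_heuristic(med$m)
    expect_equal(matching_weight_of(g, med$m),
                 brute_matching_weight(med$m), tolerance = 1e-9)
    expect_gte(median_score(g, tr$a, tr$b, tr$c), med$invariants$beta)
  }
  expect_gte(found, 3L)  # fractional medians do arise in this regime
})

test_that("fractional rows are identified and the complement is binary", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  expect_equal(fractional_rows(med$m), c(1L, 2L, 5L, 6L, 7L, 8L))
  expect_equal(fractional_rows(genome_to_matrix(red$b)), integer(0))
  neg <- diag(4); neg[1, 1] <- -1
  expect_error(fractional_rows(neg), "-1")
})

test_that("involution counts follow the telephone-number recurrence", {
  expect_equal(count_involutions(1), 1)
  expect_equal(count_involutions(6), 76)
  expect_equal(count_involutions(10), 9496)
  expect_gt(count_involutions(12), 140000)
  expect_equal(ncol(enumerate_involutions(6)), 76)
  expect_equal(ncol(enumerate_involutions(1)), 1)
  for (k in 4:8)
    expect_equal(count_involutions(k),
                 count_involutions(k - 1) + (k - 1) * count_involutions(k - 2))
  # enumeration is duplicate-free and every column is an involution
  inv5 <- enumerate_involutions(5)
  expect_equal(nrow(unique(t(inv5))), ncol(inv5))
  expect_true(all(apply(inv5, 2, function(p) all(p[p] == 1:5))))
})

test_that("the closest-genome heuristic recovers the known genomic median", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  out <- closest_genome_heuristic(med$m, red$a, red$b, red$c)
  expect_true(out$genome == parse_cycles("(1 6)(2 7)(3 4)(5 8)", 8))
  expect_equal(out$score, 9L)
  expect_equal(out$gap, 1L)
  expect_equal(out$blocks, 6L)
  expect_equal(out$block_min_dist, 1L)
  expect_equal(out$block_n_closest, 1L)  # unique closest genome on 6 extremities
})

test_that("closest-genome heuristic is the identity on genomic medians", {
  g <- parse_cycles("(1 2)(3 6)", 6)
  out <- closest_genome_heuristic(genome_to_matrix(g), g, g, g)
  expect_true(out$genome == g)
  expect_equal(out$gap, 0L)
  expect_equal(out$blocks, integer(0))
})

test_that("oversized components are refused with a size message", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  expect_error(closest_genome_heuristic(med$m, red$a, red$b, red$c,
                                        max_block = 4L),
               "component too large.*6")
})

test_that("block search matches the unrestricted brute force over involutions", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  r_set <- fractional_rows(med$m)
  mr <- med$m[r_set, r_set]
  cands <- enumerate_involutions(length(r_set))
  dists <- apply(cands, 2, function(pr) {
    gm <- matrix(0, length(r_set), length(r_set))
    gm[cbind(seq_along(r_set), pr)] <- 1
    qr_rank(gm - mr)
  })
  out <- closest_genome_heuristic(med$m, red$a, red$b, red$c)
  expect_equal(min(dists), out$block_min_dist)
  expect_equal(sum(dists == min(dists)), out$block_n_closest)
})

test_that("exhaustive search finds the three best-scoring genomes", {
  red <- reduced_triple()
  bf <- brute_force_best_genomes(red$a, red$b, red$c)
  expect_equal(bf$best_score, 9L)
  expect_length(bf$genomes, 3L)
  want <- lapply(c("(1 6)(2 7)(3 4)(5 8)", "(1 6)(2 8)(3 4)(5 7)",
                   "(1 6)(2 5)(3 4)(7 8)"), parse_cycles, n = 8)
  for (w in want)
    expect_true(any(vapply(bf$genomes, function(g) g == w, TRUE)))

  g <- rand_involution(6)
  bfg <- brute_force_best_genomes(g, g, g)
  expect_equal(bfg$best_score, 0L)
  expect_length(bfg$genomes, 1L)
  expect_true(bfg$genomes[[1]] == g)
  expect_error(brute_force_best_genomes(genome(1:14), genome(1:14),
                                        genome(1:14)), "too large")
})

test_that("best score never beats beta; equality iff a genomic median exists", {
  set.seed(53)
  for (k in 1:8) {
    tr <- generate_triple(sample(3:5, 1), runif(1, 0.2, 0.5),
                          sample(c("SCJ", "DCJ"), 1))
    inv <- median_invariants(tr$a, tr$b, tr$c)
    bf <- brute_force_best_genomes(tr$a, tr$b, tr$c)
    expect_gte(bf$best_score, inv$beta)
  }
})

test_that("min-score genomes also minimize rank distance to the median", {
  # spot check of the closest-genome conjecture; mismatches are reported,
  # not raised, as the claim is a conjecture
  set.seed(54)
  checked <- 0L
  mismatches <- 0L
  for (k in 1:10) {
    tr <- generate_triple(sample(3:5, 1), runif(1, 0.2, 0.5), "DCJ")
    med <- compute_median(tr$a, tr$b, tr$c)
    bf <- brute_force_best_genomes(tr$a, tr$b, tr$c)
    dist_to_m <- function(g)
      rank_distance_matrices(genome_to_matrix(g), med$m)
    all_d <- apply(enumerate_involutions(tr$n), 2, function(pr)
      dist_to_m(genome(pr)))
    dmin <- min(all_d)
    for (g in bf$genomes) {
      checked <- checked + 1L
      if (dist_to_m(g) != dmin) mismatches <- mismatches + 1L
    }
  }
  expect_gte(checked, 10L)
  if (mismatches > 0L)
    message(mismatches, " of ", checked,
            " best-scoring genomes were not closest to the median")
  succeed()
})
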