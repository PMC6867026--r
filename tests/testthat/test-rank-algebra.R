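test_that("cycle counting handles products, identities and long cycles", {
  expect_equal(cycle_count(1:5), 5L)
  expect_equal(cycle_count(c(2L, 3L, 4L, 5L, 1L)), 1L)
  ex <- example_triple()
  # product AB = (2 7 4 5)(3 6)(8 9) with fixed points 1, 10, 11, 12
  ab <- ex$a$pairing[ex$b$pairing]
  expect_equal(cycle_count(ab), 7L)
  expect_error(cycle_count(c(1L, 1L, 3L)), "bijection")
})

test_that("pairwise rank distances of the example triple match by both routes", {
  ex <- example_triple()
  expect_equal(rank_distance(ex$a, ex$b), 5L)
  expect_equal(rank_distance(ex$b, ex$c), 4L)
  expect_equal(rank_distance(ex$c, ex$a), 7L)
  expect_equal(rank_distance(ex$a, ex$a), 0L)
  expect_equal(rank_distance_matrices(genome_to_matrix(ex$c),
                                      genome_to_matrix(ex$a)), 7L)
  expect_error(rank_distance(ex$a, genome(1:4)), "different extremity counts")
})

test_that("cycle-count distance equals numerical rank of the matrix difference", {
  set.seed(21)
  for (k in 1:25) {
    n <- sample(2:40, 1)
    g1 <- rand_involution(n)
    g2 <- rand_involution(n)
    d <- rank_distance(g1, g2)
    diff <- genome_to_matrix(g1) - genome_to_matrix(g2)
    expect_equal(rank_distance_matrices(genome_to_matrix(g1),
                                        genome_to_matrix(g2)), d)
    expect_equal(qr_rank(diff), d)  # independent QR oracle
    expect_equal(rank_distance(g2, g1), d)
  }
})

test_that("rank distance is a metric on random involution triples", {
  set.seed(22)
  for (k in 1:25) {
    n <- sample(3:25, 1)
    x <- rand_involution(n); y <- rand_involution(n); z <- rand_involution(n)
    expect_lte(rank_distance(x, z),
               rank_distance(x, y) + rank_distance(y, z))
    expect_equal(rank_distance(x, y) == 0L, x == y)
  }
})

test_that("invariants alpha, beta, delta are exact on the example instances", {
  ex <- example_triple()
  inv <- median_invariants(ex$a, ex$b, ex$c)
  expect_equal(inv$alpha, 5L)
  expect_equal(inv$beta, 8L)
  expect_equal(inv$delta, 1L)

  red <- reduced_triple()
  invr <- median_invariants(red$a, red$b, red$c)
  expect_equal(invr$alpha, 1L)
  expect_equal(invr$beta, 8L)
  expect_equal(invr$delta, 1L)

  g <- rand_involution(9)
  invg <- median_invariants(g, g, g)
  expect_equal(invg$alpha, 9L)
  expect_equal(invg$beta, 0L)
  expect_equal(invg$delta, 0L)
})

test_that("beta is integral and delta non-negative on random triples", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(4:30, 1)
    inv <- median_invariants(rand_involution(n), rand_involution(n),
                             rand_involution(n))
    expect_equal((inv$d_ab + inv$d_bc + inv$d_ca) %% 2L, 0L)
    expect_gte(inv$delta, 0L)
  }
})

test_that("median scores of known candidates match", {
  red <- reduced_triple()
  expect_equal(median_score(red$b, red$a, red$b, red$c), 9L)
  m_match <- parse_cycles("(3 4)(2 7)(5 8)", 8)
  expect_equal(median_score(m_match, red$a, red$b, red$c), 10L)
  g <- rand_involution(6)
  expect_equal(median_score(g, g, g, g), 0L)
  # matrix route agrees with the genome route
  expect_equal(median_score(genome_to_matrix(red$b), red$a, red$b, red$c), 9L)
})

test_that("single operations move the rank distance by their weight", {
  set.seed(24)
  for (k in 1:20) {
    g <- rand_involution(sample(4:20, 1))
    expect_equal(rank_distance(g, apply_scj(g)), 1L)
    expect_true(rank_distance(g, apply_dcj(g)) %in% c(1L, 2L))
  }
})
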