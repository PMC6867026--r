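test_that("the median of the reduced triple equals the known 8x8 matrix", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c)
  expect_lt(max(abs(6 * med$m - known_median_6x())), 1e-9)
  expect_equal(med$score, 8L)
  expect_false(med$is_genomic)
  expect_equal(med$diagnostics, c(1L, 1L, 1L))
  expect_equal(med$dims, c(1L, 2L, 3L, 0L, 2L))
  # the adjacency (3,4) shared by B' and C' is present
  expect_true(all(med$conserved$present))
  expect_true(any(med$conserved$i == 3 & med$conserved$j == 4))
})

test_that("exact mode reproduces the median in integer arithmetic", {
  red <- reduced_triple()
  med <- compute_median(red$a, red$b, red$c, exact = TRUE)
  expect_identical(med$m_den, 6)
  expect_identical(med$m_num, known_median_6x())
  expect_identical(med$m * 6, known_median_6x())  # bit-exact
})

test_that("identical inputs give back the input with score zero", {
  g <- parse_cycles("(1 4)(2 3)", 6)
  med <- compute_median(g, g, g)
  expect_equal(med$m, genome_to_matrix(g))
  expect_equal(med$score, 0L)
  expect_true(med$is_genomic)
  expect_true(med$genome == g)
})

test_that("unanimous reduction yields the printed reduced instance", {
  ex <- example_triple()
  red <- reduce_unanimous(ex$a, ex$b, ex$c)
  expect_equal(red$a$n, 8L)
  known <- reduced_triple()
  expect_true(red$a == known$a)
  expect_true(red$b == known$b)
  expect_true(red$c == known$c)
  expect_equal(red$kept, 2:9)
  expect_setequal(vapply(red$fixed, paste, collapse = ",", FUN.VALUE = ""),
                  c("1", "12", "10,11"))

  g <- rand_involution(6)
  redg <- reduce_unanimous(g, g, g)
  expect_equal(redg$a$n, 0L)
  expect_length(redg$fixed, length(telomeres(g)) + nrow(adjacencies(g)))
})

test_that("restoration inverts reduction and reinstates fixed features", {
  # recovery (1 4)(2 5)(3 6) on kept extremities [1,2,5,6,7,8] of the
  # reduced instance, plus the fixed adjacency (3 4), gives (16)(27)(34)(58)
  g <- parse_cycles("(1 4)(2 5)(3 6)", 6)
  restored <- restore_genome(g, kept = c(1L, 2L, 5L, 6L, 7L, 8L),
                             fixed = list(c(3L, 4L)), n_original = 8L)
  expect_true(restored == parse_cycles("(1 6)(2 7)(3 4)(5 8)", 8))

  # round trip on random simulated triples
  set.seed(41)
  for (k in 1:10) {
    tr <- generate_triple(sample(3:10, 1), 0.2, "SCJ")
    red <- reduce_unanimous(tr$a, tr$b, tr$c)
    expect_true(restore_genome(red$a, red$kept, red$fixed, red$n_original) == tr$a)
    expect_true(restore_genome(red$c, red$kept, red$fixed, red$n_original) == tr$c)
  }

  # empty reduction map is the identity
  g2 <- rand_involution(5)
  expect_true(restore_genome(g2, kept = 1:5, fixed = list(),
                             n_original = 5L) == g2)
})

test_that("a reduced median restored to full size attains the original beta", {
  ex <- example_triple()
  inv <- median_invariants(ex$a, ex$b, ex$c)
  red <- reduce_unanimous(ex$a, ex$b, ex$c)
  med <- compute_median(red$a, red$b, red$c)
  full <- restore_matrix(med$m, red$kept, red$fixed, red$n_original)
  expect_equal(median_score(full, ex$a, ex$b, ex$c), inv$beta)
  expect_lt(max(abs(full - t(full))), 1e-9)
  expect_lt(max(abs(crossprod(full) - diag(12))), 1e-9)
})

test_that("median guarantees hold across simulated triples", {
  set.seed(42)
  for (k in 1:20) {
    tr <- generate_triple(sample(4:25, 1), runif(1, 0.1, 0.3),
                          sample(c("SCJ", "DCJ"), 1))
    inv <- median_invariants(tr$a, tr$b, tr$c)
    # compute_median itself asserts symmetry, orthogonality, unit row sums,
    # score == beta, diagnostics == delta and 2-of-3 conservation
    med <- compute_median(tr$a, tr$b, tr$c)
    expect_s3_class(med, "rank_median")
    expect_equal(med$score, inv$beta)
    expect_equal(med$diagnostics, rep(inv$delta, 3L))
  }
})

test_that("optimality diagnostics are delta on the examples and zero when trivial", {
  red <- reduced_triple()
  expect_equal(optimality_diagnostics(red$a, red$b, red$c), c(1L, 1L, 1L))
  g <- rand_involution(8)
  expect_equal(optimality_diagnostics(g, g, g), c(0L, 0L, 0L))
})
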