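test_that("the no-signaling example matches its published shape", {
  ns <- gen_ns_example()
  expect_equal(ns$hrep$m, 24L)
  expect_equal(ns$hrep$n, 14L)
  expect_equal(ns$hrep$b, c(rep("0", 20), rep("1", 4)))
  # first 14 rows are the negated unit vectors
  expect_equal(ns$hrep$A[1:14, ], matrix(as.character(-diag(14)), 14, 14))
  ex <- is_extreme(ns$hrep, ns$start)
  expect_true(ex$extreme)
  expect_equal(ex$sigma, 6L)
})

test_that("Birkhoff systems have the reduced shape and l! permutation vertices", {
  for (l in 2:4) {
    fx <- gen_birkhoff(l)
    expect_equal(fx$hrep$n, (l - 1L)^2)
    expect_equal(fx$hrep$m, l^2)
    G <- skeleton_graph(fx$hrep, start = fx$start)
    expect_equal(nrow(G$vertices), factorial(l))
    # every vertex lifts to a 0/1 doubly-stochastic (= permutation) matrix
    for (i in seq_len(nrow(G$vertices))) {
      P <- lift_birkhoff(G$vertices[i, ], l)
      expect_true(all(P %in% c(0, 1)))
      expect_equal(rowSums(P), rep(1, l))
      expect_equal(colSums(P), rep(1, l))
    }
  }
  expect_error(gen_birkhoff(1), "at least 2")
})

test_that("random regular systems are reproducible, bounded and regular", {
  fx1 <- gen_random_regular(3, 9, seed = 4)
  fx2 <- gen_random_regular(3, 9, seed = 4)
  expect_identical(fx1$hrep, fx2$hrep)      # bit-for-bit determinism
  expect_true(is_bounded(fx1$hrep))
  G <- skeleton_graph(fx1$hrep, start = fx1$start)
  expect_true(all(G$sigma == 0L))           # regular with probability 1
  expect_true(all(G$degree == 3L))          # n-regular skeleton
  # a second dimension/size, to not hang all regularity evidence on one draw
  fx3 <- gen_random_regular(4, 10, seed = 2)
  G3 <- skeleton_graph(fx3$hrep, start = fx3$start)
  expect_true(all(G3$sigma == 0L))
  expect_true(all(G3$degree == 4L))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_random_regular(3, 8, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("classical fixtures carry correct known facts", {
  for (fx in list(gen_classic("cube", 3), gen_classic("cube", 4),
                  gen_classic("simplex", 3), gen_classic("simplex", 5),
                  gen_classic("crosspolytope", 3),
                  gen_classic("crosspolytope", 4))) {
    G <- skeleton_graph(fx$hrep, start = fx$start)
    expect_equal(nrow(G$vertices), fx$known$n_vertices, label = fx$name)
    expect_equal(nrow(G$edges), fx$known$n_edges, label = fx$name)
    if (!is.null(fx$known$degree))
      expect_true(all(G$degree == fx$known$degree), label = fx$name)
    if (!is.null(fx$known$sigma))
      expect_true(all(G$sigma == fx$known$sigma), label = fx$name)
  }
})
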