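ns <- gen_ns_example()
Hns <- ns$hrep
origin14 <- rep(0, 14)

test_that("slack vectors are exact and detect infeasibility", {
  # at the origin the slack vector equals b: twenty 0's then four 1's
  expect_equal(slack_vector(Hns, origin14), Hns$b)
  cube <- gen_classic("cube", 3)$hrep
  expect_equal(slack_vector(cube, c("1/2", "1/2", "1/2")), rep("1/2", 6))
  s <- slack_vector(cube, c(2, 0, 0))
  expect_true(any(startsWith(s, "-")))
  expect_error(slack_vector(cube, c(0, 0)), "dimension")
})

test_that("active sets collect exactly the tight constraints", {
  expect_equal(active_set(Hns, origin14), 0:19)
  cube <- gen_classic("cube", 3)$hrep
  expect_equal(active_set(cube, c(1, 1, 1)), 0:2)   # the three upper facets
  expect_equal(active_set(cube, c("1/2", "1/3", "1/4")), integer(0))
})

test_that("extremality = feasibility + full active rank, with degeneracy", {
  ex <- is_extreme(Hns, origin14)
  expect_true(ex$feasible)
  expect_true(ex$extreme)
  expect_equal(ex$sigma, 6L)

  cube <- gen_classic("cube", 3)$hrep
  center <- is_extreme(cube, rep("1/2", 3))
  expect_true(center$feasible)
  expect_false(center$extreme)
  corner <- is_extreme(cube, c(1, 0, 1))
  expect_true(corner$extreme)
  expect_equal(corner$sigma, 0L)
  outside <- is_extreme(cube, c(2, 0, 0))
  expect_false(outside$feasible)
})

test_that("exact rank: known values, invariances, degenerate rows", {
  expect_equal(matrix_rank(Hns$A[1:20, ]), 14L)
  expect_equal(matrix_rank(NULL), 0L)
  M <- rbind(c(1, 2, 3), c(2, 4, 6))            # scalar multiple
  expect_equal(matrix_rank(M), 1L)
  # invariant under positive row scaling and permutation
  M2 <- rbind(c("2/3", "4/3", "2"), c(1, 0, 1))
  expect_equal(matrix_rank(M2), matrix_rank(M2[2:1, ]))
  expect_equal(matrix_rank(rbind(c(1, 2, 3), c(1, 0, 1))), 2L)
})

test_that("biorthogonal rays satisfy a_i . rho_j = -c delta_ij exactly", {
  # Table-system basis of negated unit vectors: rays are the unit vectors
  X <- biorthogonal_rays(Hns, 0:13)
  expect_equal(X$rays, matrix(as.character(diag(14)), 14, 14))
  expect_equal(X$active[[1]], 1:13)

  # basis +I gives the sign-flipped rays -I
  Hpos <- hrep(rbind(diag(3), c(1, 1, 1)), rep(1, 4))
  Xp <- biorthogonal_rays(Hpos, 0:2)
  expect_equal(Xp$rays, matrix(as.character(-diag(3)), 3, 3))

  # random invertible rational basis: check the defining system via slacks
  set.seed(5)
  B <- matrix(sample(-9:9, 9, replace = TRUE), 3, 3)
  while (matrix_rank(B) < 3) B <- matrix(sample(-9:9, 9, replace = TRUE), 3, 3)
  HB <- hrep(rbind(B, 0), c(0, 0, 0, 1))      # b = 0 on the basis rows
  XB <- biorthogonal_rays(HB, 0:2)
  for (j in 1:3) {
    # s_i = -a_i . rho_j must be a positive multiple of the unit vector e_j
    s <- slack_vector(HB, XB$rays[, j])[1:3]
    onj <- s[j]
    expect_false(startsWith(onj, "-"))
    expect_true(onj != "0")
    expect_equal(s[-j], c("0", "0"))
  }
  expect_error(biorthogonal_rays(Hns, 0:12), "exactly n")
  Hdup <- hrep(rbind(c(1, 0), c(2, 0), c(0, 1)), c(1, 2, 1))
  expect_error(biorthogonal_rays(Hdup, 0:1), "rank deficient")
})

test_that("the simplex search multiplicity formula is exact", {
  expect_equal(multiplicity(14, 24, 6), 2170560)
  expect_equal(multiplicity(14, 24, 6), 14 * 4 * choose(20, 14))  # n(m-n-s)C(n+s,n)
  expect_equal(multiplicity(5, 9, 0), 5 * 4)     # regular case: n (m - n)
  expect_error(multiplicity(14, 24, 11), "non-negative")
  # a value beyond double precision comes back exact as a string
  expect_type(multiplicity(40, 200, 60), "character")
})

test_that("square rational systems solve exactly or fail loudly", {
  x <- solve_rational(rbind(c(1, 1), c(1, -1)), c(1, 0))
  expect_equal(x, c("1/2", "1/2"))
  expect_error(solve_rational(rbind(c(1, 1), c(2, 2)), c(1, 0)), "singular")
})
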