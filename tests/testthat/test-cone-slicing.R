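ns <- gen_ns_example()
Hns <- ns$hrep
origin14 <- rep(0, 14)

test_that("ray partition against a cutting half-space is a sign split", {
  base <- biorthogonal_rays(Hns, 0:13)
  pt <- partition_rays(Hns, base, 14)
  expect_equal(pt$pos, c(1, 2, 3))       # unit rays e0, e1, e2
  expect_equal(pt$neg, c(6, 7))          # e5, e6
  expect_equal(sort(c(pt$pos, pt$zero, pt$neg)), 1:14)
  # a constraint orthogonal to every ray leaves all in X0
  pt2 <- partition_rays(Hns, base$rays[, 1:3, drop = FALSE], 15)
  expect_equal(pt2$zero, 1:3)
})

test_that("joint active subsets and the rejection pre-test behave as stated", {
  base <- biorthogonal_rays(Hns, 0:13)
  j01 <- joint_active_set(base$active[[1]], base$active[[2]])
  expect_equal(j01, setdiff(0:13, c(0, 1)))    # size n - 2 for a base pair
  expect_equal(length(j01), 12L)
  expect_equal(joint_active_set(base$active[[1]], base$active[[1]]),
               base$active[[1]])
  expect_false(rejection_precheck(seq_len(11), 14))   # n - 3: reject
  expect_true(rejection_precheck(seq_len(12), 14))    # n - 2: keep
  expect_true(rejection_precheck(seq_len(13), 14))    # n - 1: keep
})

test_that("algebraic and combinatorial colaminarity agree everywhere", {
  # every base-cone pair is colaminar (regular cone)
  base <- biorthogonal_rays(Hns, 0:13)
  for (pair in list(c(1, 2), c(3, 14), c(7, 8))) {
    joint <- joint_active_set(base$active[[pair[1]]], base$active[[pair[2]]])
    expect_true(colaminar_algebraic(Hns, joint))
    expect_true(colaminar_combinatorial(base$active, pair[1], pair[2]))
  }
  # duplicated constraint rows: joint of size n-2 but rank n-3 fails (b) test
  Hdup <- hrep(rbind(-diag(4), c(1, 0, 0, 0), -diag(4)[1, , drop = FALSE],
                     rep(1, 4)), c(rep(0, 4), 1, 0, 1))
  expect_equal(matrix_rank(Hdup$A[c(2, 3, 5) + 1L, ]), 3L)
  expect_false(colaminar_algebraic(Hdup, c(2, 3, 5)))

  # exhaustive agreement over every X- x X+ pair at every insertion step
  st <- dd_state(Hns, 0:13)
  for (k in 14:19) {
    pt <- partition_rays(Hns, st$rays, k)
    for (im in pt$neg) for (ip in pt$pos) {
      joint <- joint_active_set(st$active[[im]], st$active[[ip]])
      expect_identical(colaminar_algebraic(Hns, joint),
                       colaminar_combinatorial(st$active, im, ip))
    }
    st <- insert_halfspace(Hns, st, k)
  }
})

test_that("combining a colaminar pair yields a primitive ray on the cut", {
  e <- function(...) {
    v <- rep("0", 14)
    for (i in c(...)) v[i + 1L] <- "1"
    v
  }
  phi <- combine_rays(Hns, 14, e(5), e(0))
  expect_equal(paste(phi, collapse = ","), esum(14, 0, 5))
  phi2 <- combine_rays(Hns, 14, e(6), e(2))
  expect_equal(paste(phi2, collapse = ","), esum(14, 2, 6))
  # the result lies exactly on the cutting hyperplane
  pt <- partition_rays(Hns, matrix(phi, ncol = 1), 14)
  expect_equal(pt$zero, 1L)
  expect_error(combine_rays(Hns, 14, e(0), e(5)), "rho_neg")
})

test_that("one insertion on the worked example: 12 kept + 6 gained", {
  st <- dd_state(Hns, 0:13)
  st1 <- insert_halfspace(Hns, st, 14)
  expect_equal(ncol(st1$rays), 18L)
  step <- attr(st1, "step")
  expect_equal(length(step$pos), 3L)
  expect_equal(length(step$zero), 9L)
  expect_equal(length(step$neg), 2L)
  gained <- apply(step$new_rays, 2L, paste, collapse = ",")
  expect_setequal(gained, c(esum(14, 0, 5), esum(14, 1, 5), esum(14, 2, 5),
                            esum(14, 0, 6), esum(14, 1, 6), esum(14, 2, 6)))
  # inserting a half-space with an empty X- changes no rays, only bookkeeping
  extra <- as_rational(-rational_to_double(Hns$A[21, , drop = FALSE]))
  Hpad <- hrep(rbind(Hns$A, extra), c(Hns$b, "0"))
  stp <- dd_state(Hpad, 0:13)
  stp1 <- insert_halfspace(Hpad, stp, 24)    # -a20: no ray on the outside
  expect_equal(length(attr(stp1, "step")$neg), 0L)
  expect_equal(ray_keys(stp1), ray_keys(stp))
  expect_error(insert_halfspace(Hns, st1, 14), "already")
})

test_that("slicing the origin cone: 54 rays via a rising trajectory", {
  X <- slice_cone(Hns, origin14, basis = 0:13, order = 14:19)
  expect_equal(ncol(X$rays), 54L)
  expect_equal(X$trajectory, c(14L, 18L, 22L, 31L, 40L, 47L, 54L))
  # a regular vertex: no insertions, the n biorthogonal rays
  cube <- gen_classic("cube", 3)$hrep
  Xc <- slice_cone(cube, c(0, 0, 0))
  expect_equal(ncol(Xc$rays), 3L)
  expect_equal(Xc$trajectory, 3L)
})

test_that("standard and recorded slicers agree step by step", {
  s_std <- dd_state(Hns, 0:13)
  s_rec <- dd_state(Hns, 0:13)
  for (k in 14:19) {
    s_std <- insert_halfspace(Hns, s_std, k, record = FALSE)
    s_rec <- insert_halfspace(Hns, s_rec, k, record = TRUE)
    expect_identical(ray_keys(s_std), ray_keys(s_rec))
  }
  expect_equal(ncol(s_rec$rays), 54L)
  # the record saves work: hits + rejections traded for tests
  expect_gt(s_rec$counters$record_hits + s_rec$counters$rejections, 0)
  expect_lt(s_rec$counters$tests_run, s_std$counters$tests_run)
  expect_equal(s_rec$counters$duplicates_merged, 0)
  expect_equal(s_std$counters$duplicates_merged, 0)
})

test_that("the 2-face record stays sound at every step", {
  st <- dd_state(Hns, 0:13)
  for (k in 14:19) {
    st <- insert_halfspace(Hns, st, k)
    keys <- apply(st$rays, 2L, paste, collapse = ",")
    for (r in seq_len(nrow(st$record))) {
      i <- match(st$record[r, 1L], keys)
      j <- match(st$record[r, 2L], keys)
      if (is.na(i) || is.na(j)) next     # stale entry for a dropped ray
      joint <- joint_active_set(st$active[[i]], st$active[[j]])
      expect_true(colaminar_algebraic(Hns, joint))
    }
  }
})

test_that("the double-description invariant holds after every insertion", {
  st <- dd_state(Hns, 0:13)
  for (k in 14:19) {
    st <- insert_halfspace(Hns, st, k)
    # every ray satisfies every processed constraint
    for (kk in st$J) {
      pt <- partition_rays(Hns, st$rays, kk)
      expect_equal(length(pt$neg), 0L)
    }
    # every ray carries a full extreme-ray certificate: rank(act) = n - 1
    for (j in seq_len(ncol(st$rays)))
      expect_equal(matrix_rank(Hns$A[st$active[[j]] + 1L, , drop = FALSE]),
                   13L)
  }
})

test_that("the final ray set is invariant under insertion order and basis", {
  ref <- ray_keys(slice_cone(Hns, origin14, basis = 0:13, order = 14:19))
  # a sample of insertion orders, plus descending
  set.seed(42)
  orders <- c(list(19:14), replicate(12, sample(14:19), simplify = FALSE))
  for (ord in orders)
    expect_identical(ray_keys(slice_cone(Hns, origin14, basis = 0:13,
                                         order = ord,
                                         test = "combinatorial")), ref)
  # a sample of alternative bases drawn from the enumerated basis list
  eb <- enumerate_bases(Hns, 0:19, keep = TRUE)
  set.seed(7)
  for (i in sample(nrow(eb$bases), 8)) {
    B <- eb$bases[i, ]
    X <- slice_cone(Hns, origin14, basis = B, order = setdiff(0:19, B))
    expect_identical(ray_keys(X), ref)
  }
})

test_that("degenerate cones beyond the worked example slice correctly", {
  oct <- gen_classic("crosspolytope", 3)
  v <- c("1", "0", "0")
  expect_equal(is_extreme(oct$hrep, v)$sigma, 1L)
  X <- slice_cone(oct$hrep, v)
  expect_equal(ncol(X$rays), 4L)     # 4 edges meet at an octahedron vertex
})
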