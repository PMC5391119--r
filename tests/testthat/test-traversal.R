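ns <- gen_ns_example()
Hns <- ns$hrep

test_that("greedy basis choice is deterministic and skips dependent rows", {
  cb <- choose_basis(Hns, 0:19)
  expect_equal(cb$basis, 0:13)
  expect_equal(cb$bprime, 14:19)
  # regular vertex: basis is the whole active set
  cube <- gen_classic("cube", 3)$hrep
  cb2 <- choose_basis(cube, active_set(cube, c(0, 0, 0)))
  expect_equal(cb2$bprime, integer(0))
  # duplicated leading row: the greedy scan skips the dependent copy
  Hdup <- hrep(rbind(c(-1, 0), c(-2, 0), c(0, -1), c(1, 1)),
               c(0, 0, 0, 1))
  cb3 <- choose_basis(Hdup, 0:2)
  expect_equal(cb3$basis, c(0L, 2L))
  expect_equal(cb3$bprime, 1L)
  expect_error(choose_basis(Hdup, 0:1), "rank")
})

test_that("tightening walks any feasible point to an extreme point", {
  # a vertex is returned unchanged
  expect_equal(tighten_to_vertex(Hns, rep(0, 14)), rep("0", 14))
  # the cube centre lands on some corner, deterministically
  cube <- gen_classic("cube", 3)$hrep
  v1 <- tighten_to_vertex(cube, rep("1/2", 3))
  expect_true(is_extreme(cube, v1)$extreme)
  expect_identical(tighten_to_vertex(cube, rep("1/2", 3)), v1)
  # the uniform doubly-stochastic matrix tightens to a permutation matrix
  b3 <- gen_birkhoff(3)
  v <- tighten_to_vertex(b3$hrep, b3$start)
  P <- lift_birkhoff(v, 3)
  expect_true(all(P %in% c(0, 1)))
  expect_equal(rowSums(P), rep(1, 3))
  expect_equal(colSums(P), rep(1, 3))
  expect_error(tighten_to_vertex(cube, c(2, 0, 0)), "infeasible")
})

test_that("classical skeletons come out exactly", {
  G <- skeleton_graph(gen_classic("cube", 3)$hrep, start = rep(0, 3))
  expect_equal(nrow(G$vertices), 8L)
  expect_equal(nrow(G$edges), 12L)
  expect_true(all(G$degree == 3L))

  G <- skeleton_graph(gen_classic("simplex", 4)$hrep, start = rep(0, 4))
  expect_equal(nrow(G$vertices), 5L)
  expect_equal(nrow(G$edges), 10L)   # K5

  G <- skeleton_graph(gen_classic("crosspolytope", 3)$hrep,
                      start = c(1, 0, 0))
  expect_equal(nrow(G$vertices), 6L)
  expect_equal(nrow(G$edges), 12L)
  expect_true(all(G$sigma == 1L))
})

test_that("traversal equals the brute-force subset oracle on small systems", {
  for (fx in small_fixtures()) {
    G <- skeleton_graph(fx$hrep, start = fixture_vertex(fx))
    expect_identical(graph_keys(G), brute_force_graph(fx$hrep),
                     label = fx$name)
  }
})

test_that("the graph is invariant to start vertex, basis and order choices", {
  fx <- gen_classic("crosspolytope", 3)
  H <- fx$hrep
  ref <- graph_keys(skeleton_graph(H, start = c(1, 0, 0)))
  # start from every other vertex
  for (k in seq_along(ref$vkeys)) {
    p <- strsplit(ref$vkeys[k], ",")[[1]]
    expect_identical(graph_keys(skeleton_graph(H, start = p)), ref)
  }
  # randomized per-vertex basis and insertion order, several seeds
  for (s in c(1, 2, 99))
    expect_identical(graph_keys(skeleton_graph(H, start = c(1, 0, 0),
                                               randomize = TRUE, seed = s)),
                     ref)
  # the same holds on the degenerate worked example
  refns <- graph_keys(skeleton_graph(Hns, start = rep(0, 14)))
  expect_identical(graph_keys(skeleton_graph(Hns, start = rep(0, 14),
                                             randomize = TRUE, seed = 3)),
                   refns)
  # and from a different start vertex (e0 is one)
  expect_identical(graph_keys(skeleton_graph(Hns, start = c(1, rep(0, 13)))),
                   refns)
})

test_that("two identical runs give byte-identical results", {
  fx <- gen_birkhoff(3)
  G1 <- skeleton_graph(fx$hrep, start = fx$start)
  G2 <- skeleton_graph(fx$hrep, start = fx$start)
  expect_identical(G1$vertices, G2$vertices)
  expect_identical(G1$edges, G2$edges)
})

test_that("vertex degree equals the number of extreme rays of its cone", {
  G <- skeleton_graph(Hns, start = rep(0, 14))
  for (i in sample(nrow(G$vertices), 6)) {
    X <- slice_cone(Hns, G$vertices[i, ])
    expect_equal(G$degree[i], ncol(X$rays))
  }
})

test_that("start handling: auto origin, tightening, clear failures", {
  cube <- gen_classic("cube", 3)$hrep
  expect_equal(nrow(skeleton_graph(cube, start = "auto")$vertices), 8L)
  expect_equal(nrow(skeleton_graph(cube, start = rep("1/3", 3))$vertices), 8L)
  shifted <- hrep(rbind(diag(2), -diag(2)), c(3, 3, "-1", "-1"))  # 1<=x<=3
  expect_error(skeleton_graph(shifted, start = "auto"), "infeasible")
  expect_error(skeleton_graph(shifted, start = c(0, 0)), "infeasible")
  expect_equal(nrow(skeleton_graph(shifted, start = c(2, 2))$vertices), 4L)
})

test_that("unbounded systems error during traversal unless allowed", {
  Hu <- hrep(rbind(-diag(3), c(-1, -1, -1)), rep(0, 4))
  expect_error(skeleton_graph(Hu, start = rep(0, 3)), "unbounded")
  G <- skeleton_graph(Hu, start = rep(0, 3), allow_unbounded = TRUE)
  expect_true(G$partial)
})

test_that("basis enumeration counts full-rank subsets with a guard", {
  cube <- gen_classic("cube", 3)$hrep
  eb <- enumerate_bases(cube, active_set(cube, c(0, 0, 0)))
  expect_equal(eb$count, 1)
  oct <- gen_classic("crosspolytope", 3)$hrep
  ebo <- enumerate_bases(oct, active_set(oct, c(1, 0, 0)), keep = TRUE)
  expect_equal(ebo$total, 4)        # C(4, 3) subsets
  expect_equal(ebo$count, 4)        # all are bases at an octahedron vertex
  expect_equal(nrow(ebo$bases), 4L)
  expect_error(enumerate_bases(Hns, 0:19, cap = 100), "cap")
})
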