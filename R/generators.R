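#' @title Benchmark input families
#' @description Generators for the half-space families used to exercise the
#'   converter.  Each returns a `fixture_spec`: the [hrep()], a suggested
#'   start point (a vertex, or an interior point to be tightened), and the
#'   ground-truth facts known for the family (vertex/edge counts, degrees,
#'   diameter), which the test-suite asserts after a full conversion.
#' @name generators
NULL

fixture_spec <- function(name, H, start, known = list(), params = list()) {
  structure(list(name = name, hrep = H, start = start, known = known,
                 params = params), class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("fixture '", x$name, "': m = ", x$hrep$m, ", n = ", x$hrep$n, "\n",
      sep = "")
  if (length(x$known))
    cat("  known facts:", paste(names(x$known), collapse = ", "), "\n")
  invisible(x)
}

#' No-signaling correlation polytope example (m = 24, n = 14)
#'
#' The two-party no-signaling scenario with binary inputs and asymmetric
#' outputs (3 and 2 outcomes): 20 non-negativity/no-signaling constraints
#' through the origin plus 4 normalization constraints.  The origin is a
#' 6-fold degenerate vertex; the skeleton graph has 108 vertices and 1548
#' edges with degrees 16 (72 vertices) and 54 (36 vertices).
#'
#' @return a `fixture_spec`; the start point is the origin.
#' @family generators
#' @export
gen_ns_example <- function() {
  n <- 14L
  ex <- function(...) {
    v <- rep(0, n)
    for (i in c(...)) v[i + 1L] <- v[i + 1L] + 1
    v
  }
  A <- matrix(0, 24, n)
  for (i in 0:13) A[i + 1L, i + 1L] <- -1
  A[15, ] <- -ex(0) - ex(1) - ex(2) + ex(5) + ex(6)          # a14
  A[16, ] <- -ex(9) - ex(10) - ex(11) + ex(12) + ex(13)      # a15
  A[17, ] <- -ex(0) - ex(3) + ex(9)                          # a16
  A[18, ] <- -ex(1) - ex(4) + ex(10)                         # a17
  A[19, ] <- -ex(5) - ex(7) + ex(12)                         # a18
  A[20, ] <- -ex(6) - ex(8) + ex(13)                         # a19
  A[21, ] <- ex(0, 1, 2, 3, 4)                               # a20
  A[22, ] <- ex(0, 1, 2, 7, 8)                               # a21
  A[23, ] <- ex(0, 1, 3, 4, 11)                              # a22
  A[24, ] <- ex(5, 6, 7, 8, 9, 10, 11) - ex(12) - ex(13)     # a23
  b <- c(rep(0, 20), rep(1, 4))
  fixture_spec("ns-example", hrep(A, b), start = rep("0", n),
               known = list(n_vertices = 108L, n_edges = 1548L,
                            degree_histogram = c(`16` = 72L, `54` = 36L),
                            origin_sigma = 6L, origin_rays = 54L,
                            origin_bases = 6144L))
}

#' Birkhoff polytope of doubly-stochastic matrices
#'
#' The polytope of l x l doubly-stochastic matrices, in the reduced
#' coordinates of the upper-left (l-1) x (l-1) block: eliminating the last
#' row and column through the normalization equalities leaves
#' \eqn{n = (l-1)^2} free variables and \eqn{m = l^2} inequalities (block
#' entries non-negative; row and column sums at most 1; total block sum at
#' least l-2).  The vertices are the l! permutation matrices, and the
#' skeleton graph has diameter 2 for l >= 4.
#'
#' @param l matrix size, at least 2.
#' @return a `fixture_spec`; the start point is the uniform matrix (all
#'   entries 1/l), an interior point.
#' @family generators
#' @export
gen_birkhoff <- function(l) {
  l <- as.integer(l)
  if (l < 2L) stop("l must be at least 2")
  k <- l - 1L
  n <- k * k
  idx <- function(i, j) (i - 1L) * k + j     # row-major block coordinates
  rows <- list()
  b <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {    # x_ij >= 0
    r <- rep("0", n)
    r[idx(i, j)] <- "-1"
    rows[[length(rows) + 1L]] <- r
    b <- c(b, "0")
  }
  for (i in seq_len(k)) {                          # row sums <= 1
    r <- rep("0", n)
    r[idx(i, seq_len(k))] <- "1"
    rows[[length(rows) + 1L]] <- r
    b <- c(b, "1")
  }
  for (j in seq_len(k)) {                          # column sums <= 1
    r <- rep("0", n)
    r[idx(seq_len(k), j)] <- "1"
    rows[[length(rows) + 1L]] <- r
    b <- c(b, "1")
  }
  r <- rep("-1", n)                                # total sum >= l - 2
  rows[[length(rows) + 1L]] <- r
  b <- c(b, as.character(-(l - 2L)))
  H <- hrep(do.call(rbind, rows), b)
  known <- list(n_vertices = factorial(l))
  if (l >= 4L) known$diameter <- 2L
  fixture_spec(paste0("birkhoff-", l), H,
               start = rep(paste0("1/", l), n), known = known,
               params = list(l = l))
}

#' Lift a reduced Birkhoff point to the full l x l matrix
#'
#' Inverse of the row/column elimination used by [gen_birkhoff()]: fills the
#' last row and column from the normalization conditions.
#'
#' @param x a point in the reduced `(l-1)^2` coordinates (numeric or
#'   character rationals; vertices are 0/1 so doubles are exact).
#' @param l matrix size.
#' @return an `l x l` numeric matrix.
#' @family generators
#' @export
lift_birkhoff <- function(x, l) {
  if (is.character(x)) x <- rational_to_double(x)
  k <- l - 1L
  B <- matrix(x, k, k, byrow = TRUE)
  P <- matrix(0, l, l)
  P[seq_len(k), seq_len(k)] <- B
  P[seq_len(k), l] <- 1 - rowSums(B)
  P[l, seq_len(k)] <- 1 - colSums(B)
  P[l, l] <- sum(B) - (l - 2L)
  P
}

#' Random regular polytope from sphere-tangent half-spaces
#'
#' Draws `m` directions uniformly on the unit sphere in dimension `n`,
#' rationalizes each coordinate to denominator `scale` (so the exact kernel
#' ingests them losslessly), and bounds the polytope by the tangent
#' constraints \eqn{u_i \cdot x \le 1}.  Such systems are regular (every
#' vertex has \eqn{\sigma = 0}) with probability 1, and the skeleton graph
#' is `n`-regular.  Draws whose tangent directions fail to span positively
#' (an unbounded intersection) are rejected and redrawn.
#'
#' @param n dimension (>= 2).
#' @param m number of half-spaces (> n).
#' @param seed integer seed; the same `(n, m, seed)` reproduces the system
#'   bit for bit.
#' @param scale rationalization denominator.
#' @param max_tries rejection cap for unbounded draws.
#' @return a `fixture_spec`; the start point is the origin (interior).
#' @family generators
#' @export
gen_random_regular <- function(n, m, seed, scale = 1e6, max_tries = 50L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L) stop("n must be at least 2")
  if (m <= n) stop("need m > n")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    U <- matrix(rnorm(m * n), m, n)
    U <- U / sqrt(rowSums(U^2))
    num <- round(U * scale)
    if (any(rowSums(abs(num)) == 0)) next   # degenerate zero row
    A <- matrix(paste0(as.integer(num), "/", format(scale, scientific = FALSE)),
                m, n)
    H <- hrep(A, rep("1", m))
    if (is_bounded(H))
      return(fixture_spec(sprintf("random-regular-n%d-m%d-s%d", n, m, seed),
                          H, start = rep("0", n),
                          known = list(regular = TRUE, degree = n),
                          params = list(n = n, m = m, seed = seed,
                                        scale = scale)))
  }
  stop("failed to draw a bounded system in ", max_tries, " attempts")
}

#' Classical polytopes with known skeletons
#'
#' Unit hypercube (`2n` facets, regular vertices), standard simplex
#' (`n + 1` facets, complete skeleton) and cross-polytope (`2^n` facets;
#' every vertex has \eqn{2^{n-1}} active facets, hence degeneracy
#' \eqn{\sigma = 2^{n-1} - n > 0} for `n > 2`'s dual exercise).
#'
#' @param family `"cube"`, `"simplex"` or `"crosspolytope"`.
#' @param n dimension (>= 2).
#' @return a `fixture_spec` with a vertex as start point.
#' @family generators
#' @export
gen_classic <- function(family = c("cube", "simplex", "crosspolytope"), n) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (family == "cube") {
    A <- rbind(diag(n), -diag(n))
    b <- c(rep(1, n), rep(0, n))
    fx <- fixture_spec(paste0("cube-", n), hrep(A, b), start = rep("0", n),
                       known = list(n_vertices = 2L^n,
                                    n_edges = n * 2L^(n - 1L),
                                    degree = n, sigma = 0L))
  } else if (family == "simplex") {
    A <- rbind(-diag(n), rep(1, n))
    b <- c(rep(0, n), 1)
    fx <- fixture_spec(paste0("simplex-", n), hrep(A, b),
                       start = rep("0", n),
                       known = list(n_vertices = n + 1L,
                                    n_edges = choose(n + 1L, 2L),
                                    degree = n))
  } else {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
    H <- hrep(signs, rep(1, nrow(signs)))
    start <- rep("0", n); start[1L] <- "1"
    fx <- fixture_spec(paste0("crosspolytope-", n), H, start = start,
                       known = list(n_vertices = 2L * n,
                                    n_edges = 2L * n * (n - 1L),
                                    sigma = 2L^(n - 1L) - n))
  }
  fx
}
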