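#' Slack vector of a point
#'
#' The slack vector is \eqn{s(p) = b - Ap}; `p` lies in the feasible region
#' exactly when every entry is non-negative, and the zero entries mark the
#' active constraints.
#'
#' @param H an [hrep()].
#' @param p a point of length `n` (numeric or character rationals).
#' @return length-`m` character vector of exact slacks.
#' @examples
#' H <- gen_classic("cube", 3)$hrep
#' slack_vector(H, c("1/2", "1/2", "1/2"))
#' @export
slack_vector <- function(H, p) {
  stopifnot_hrep(H)
  cpp_slack(H$A, H$b, as_point(H, p))
}

#' Active set of a point
#'
#' Indices (0-based) of the constraints satisfied with equality at `p`:
#' \eqn{Z(p) = \{i \in I : a_i \cdot p = b_i\}}.
#'
#' @inheritParams slack_vector
#' @return sorted integer vector of 0-based row indices.
#' @export
active_set <- function(H, p) {
  s <- slack_vector(H, p)
  which(s == "0") - 1L
}

#' Exact rank of a set of constraint vectors
#'
#' Rank over the rationals by exact Gaussian elimination -- no tolerance is
#' involved, so rank decisions are stable under row scaling and permutation.
#'
#' @param M a matrix (rows are vectors), numeric or character rationals.
#' @return integer rank.
#' @export
matrix_rank <- function(M) {
  if (is.null(M) || length(M) == 0L) return(0L)
  if (!is.matrix(M)) M <- matrix(M, nrow = 1L)
  cpp_rank(as_rational(M))
}

#' Test whether a point is an extreme point (vertex)
#'
#' `p` is feasible when its slack vector is non-negative, and extreme when in
#' addition its active rows span the full dimension `n`.  The degeneracy of
#' an extreme point is \eqn{\sigma = |Z(p)| - n}; \eqn{\sigma = 0} is a
#' regular vertex, \eqn{\sigma \ge 1} a degenerate one.
#'
#' @inheritParams slack_vector
#' @return a list with elements `feasible`, `extreme` (logicals), `sigma`
#'   (integer, `NA` when not extreme) and `active` (the active set).
#' @examples
#' ns <- gen_ns_example()
#' is_extreme(ns$hrep, rep(0, 14))   # degenerate vertex, sigma = 6
#' @export
is_extreme <- function(H, p) {
  stopifnot_hrep(H)
  s <- slack_vector(H, p)
  neg <- startsWith(s, "-")
  Z <- which(s == "0") - 1L
  feasible <- !any(neg)
  extreme <- FALSE
  sigma <- NA_integer_
  if (feasible && length(Z) >= H$n) {
    extreme <- cpp_rank(H$A[Z + 1L, , drop = FALSE]) == H$n
    if (extreme) sigma <- length(Z) - H$n
  }
  list(feasible = feasible, extreme = extreme, sigma = sigma, active = Z)
}

#' Extreme rays of a regular (basis) cone
#'
#' For a basis `B` (a rank-`n` set of `n` constraint indices) the cone
#' \eqn{D_B = \{x : a_i \cdot x \le 0, i \in B\}} is regular and its extreme
#' rays are the negated biorthogonal companion of the basis rows: the vectors
#' \eqn{\rho_j} with \eqn{a_i \cdot \rho_j = -\delta_{ij}} for
#' \eqn{i, j \in B}.  Ray `j` is active on exactly `B \ {j}`.
#'
#' @param H an [hrep()].
#' @param basis integer vector of `n` 0-based row indices with full rank.
#' @return a `cone_rays` object: list with `rays` (an `n x n` character
#'   matrix, columns are primitive integer ray directions), `active` (list of
#'   0-based active index sets) and `J` (the processed index set = `basis`).
#' @examples
#' ns <- gen_ns_example()
#' biorthogonal_rays(ns$hrep, 0:13)   # the 14 standard unit vectors
#' @export
biorthogonal_rays <- function(H, basis) {
  stopifnot_hrep(H)
  basis <- as.integer(basis)
  if (length(basis) != H$n)
    stop("basis must contain exactly n = ", H$n, " indices")
  if (any(basis < 0L | basis >= H$m)) stop("basis indices out of range")
  out <- cpp_biorthogonal(H$A, basis)
  structure(list(rays = out$rays, active = out$active,
                 J = sort(basis)), class = "cone_rays")
}

#' @export
print.cone_rays <- function(x, ...) {
  cat("cone rays:", ncol(x$rays), "extreme rays in dimension",
      nrow(x$rays), "\n")
  invisible(x)
}

#' Simplex search multiplicity at a degenerate vertex
#'
#' The number of simplex pivot alternatives that an exhaustive neighbour
#' search faces at a \eqn{\sigma}-degenerate vertex:
#' \deqn{\mu = n (m - n - \sigma) \binom{n + \sigma}{n}.}
#' This is the combinatorial cost the double-description slicing avoids by
#' inserting only the \eqn{\sigma} extra half-spaces.
#'
#' @param n dimension.
#' @param m number of half-spaces.
#' @param sigma degeneracy of the vertex.
#' @return the exact value, as numeric when it fits a double exactly,
#'   otherwise as a character integer.
#' @examples
#' multiplicity(14, 24, 6)   # 2170560
#' @export
multiplicity <- function(n, m, sigma) {
  s <- cpp_multiplicity(as.integer(n), as.integer(m), as.integer(sigma))
  v <- suppressWarnings(as.numeric(s))
  if (!is.na(v) && v < 2^53) v else s
}

#' Solve a square rational linear system exactly
#'
#' @param A square matrix (numeric or character rationals).
#' @param b right-hand side.
#' @return character vector of exact rationals, or an error if singular.
#' @export
solve_rational <- function(A, b) {
  out <- cpp_solve(as_rational(as.matrix(A)), as_rational(b))
  if (!isTRUE(out$ok)) stop("matrix is singular over the rationals")
  out$x
}
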