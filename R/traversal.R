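#' Choose a basis within an active set
#'
#' Deterministic greedy rule: scan the active indices in ascending order and
#' keep each row that increases the rank, until `n` rows are collected.  The
#' complement \eqn{B' = Z \setminus B} is returned in ascending order as the
#' default insertion order.
#'
#' @param H an [hrep()].
#' @param Z active set (0-based indices) of rank `n`.
#' @return list with integer vectors `basis` and `bprime`.
#' @examples
#' ns <- gen_ns_example()
#' choose_basis(ns$hrep, 0:19)   # basis 0..13, bprime 14..19
#' @export
choose_basis <- function(H, Z) {
  stopifnot_hrep(H)
  cpp_choose_basis(H$A, as.integer(Z))
}

#' Tighten a feasible point to a vertex
#'
#' From any feasible point, repeatedly move along an exact null-space
#' direction of the current active rows until blocked by a new constraint;
#' each move keeps all active constraints active and adds one of independent
#' direction, so at most `n` moves reach an extreme point.  The direction is
#' the first reduced null vector (deterministic); its orientation is flipped
#' if the initial one is unblocked.
#'
#' @param H an [hrep()].
#' @param x0 a feasible point.
#' @return an exact extreme point (character vector).
#' @examples
#' cube <- gen_classic("cube", 3)
#' tighten_to_vertex(cube$hrep, c("1/2", "1/2", "1/2"))
#' @export
tighten_to_vertex <- function(H, x0) {
  stopifnot_hrep(H)
  cpp_tighten(H$A, H$b, as_point(H, x0))$x
}

#' Convert an H-representation into the skeleton graph of its polytope
#'
#' Breadth-first traversal of the extreme points: starting from a known
#' vertex, each popped vertex has its cone sliced ([slice_cone()]) and its
#' neighbours found by min-ratio pivoting ([neighbors()]); unseen neighbours
#' join the FIFO queue and every incident pair becomes an edge.  Vertices are
#' deduplicated by their exact coordinates, and a neighbour is enqueued only
#' if it is neither scanned nor already queued.  The resulting vertex and
#' edge sets are independent of the basis choice, the insertion order and
#' the start vertex.
#'
#' @param H an [hrep()].
#' @param start an extreme point, a feasible point (tightened automatically),
#'   or `"auto"` to try the origin and fail with guidance otherwise.
#' @param test colaminarity test: `"algebraic"`, `"combinatorial"` or
#'   `"auto"` (runs both on the first vertex and keeps the faster).
#' @param record use the 2-face record + rejection pre-test.
#' @param randomize randomize basis choice and insertion order per vertex
#'   (seeded; the output graph must not change -- used to exercise
#'   invariance).
#' @param seed integer seed for `randomize`.
#' @param allow_unbounded skip unbounded rays and mark the graph partial
#'   instead of erroring.
#' @param max_vertices guard against runaway enumerations.
#' @return a `skeleton_graph`: list with `vertices` (character matrix, one
#'   exact point per row), `edges` (2-column integer matrix of 1-based vertex
#'   row ids, each row `i < j`, lexicographically sorted), `active_sets`,
#'   `sigma`, `degree`, `counters`, `timings`, `test_used`, `partial`, and
#'   the originating `hrep` as `$hrep`.
#' @examples
#' G <- skeleton_graph(gen_classic("cube", 3)$hrep, start = rep(0, 3))
#' c(nrow(G$vertices), nrow(G$edges))   # 8 vertices, 12 edges
#' @export
skeleton_graph <- function(H, start = "auto",
                           test = c("auto", "algebraic", "combinatorial"),
                           record = TRUE, randomize = FALSE, seed = 1L,
                           allow_unbounded = FALSE, max_vertices = 1e6) {
  stopifnot_hrep(H)
  test <- match.arg(test)
  tcode <- switch(test, algebraic = 0L, combinatorial = 1L, auto = 2L)
  if (identical(start, "auto")) {
    org <- rep("0", H$n)
    ok <- is_extreme(H, org)
    if (!ok$extreme)
      stop("start = \"auto\" tries the origin, which is ",
           if (!ok$feasible) "infeasible" else "not a vertex",
           " here; supply a feasible start point (it will be tightened ",
           "to a vertex) or an explicit extreme point")
    start <- org
  } else {
    start <- as_point(H, start)
    ext <- is_extreme(H, start)
    if (!ext$feasible) stop("start point is infeasible")
    if (!ext$extreme) start <- tighten_to_vertex(H, start)
  }
  t0 <- proc.time()[["elapsed"]]
  out <- cpp_skeleton(H$A, H$b, start, tcode, record, randomize,
                      as.integer(seed), allow_unbounded, max_vertices)
  total <- proc.time()[["elapsed"]] - t0
  out$timings$total_sec <- total
  out$hrep <- H
  class(out) <- "skeleton_graph"
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton graph: |V| =", nrow(x$vertices), ", |E| =", nrow(x$edges),
      if (isTRUE(x$partial)) " (partial: unbounded rays skipped)", "\n")
  cat("  degeneracy sigma: ", paste(range(x$sigma), collapse = ".."),
      "; mean degree ", round(2 * nrow(x$edges) / nrow(x$vertices), 3),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate the bases inside an active set
#'
#' Exhaustively counts the size-`n` subsets of the active set `Z` whose
#' constraint rows have full rank `n` -- the possible starting bases for
#' incremental slicing at that vertex.  Each basis admits \eqn{\sigma!}
#' insertion orders of its complement.
#'
#' @param H an [hrep()].
#' @param Z active set (0-based), e.g. from [active_set()].
#' @param cap refuse to enumerate more than this many subsets.
#' @param keep return the bases themselves (as a matrix of 0-based indices),
#'   not just the count.
#' @return list with `count` (rank-`n` subsets), `total` (all size-`n`
#'   subsets scanned) and optionally `bases`.
#' @examples
#' ns <- gen_ns_example()
#' \donttest{enumerate_bases(ns$hrep, 0:19)   # 6144 of 38760}
#' @export
enumerate_bases <- function(H, Z, cap = 1e7, keep = FALSE) {
  stopifnot_hrep(H)
  cpp_enumerate_bases(H$A, as.integer(Z), cap, keep)
}

#' Is the feasible region bounded?
#'
#' Tests pointedness of the recession cone \eqn{\{x : Ax \le 0\}} by slicing
#' it down with all constraint rows; the polytope is bounded exactly when no
#' extreme ray (and no lineality direction) survives.
#'
#' @param H an [hrep()].
#' @return logical.
#' @export
is_bounded <- function(H) {
  stopifnot_hrep(H)
  cpp_is_bounded(H$A)
}
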