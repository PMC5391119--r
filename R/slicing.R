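#' Initialize a double-description state at a vertex cone
#'
#' A `dd_state` is the pair \eqn{(J, X_J)}: the processed constraint index
#' set `J` (initially a basis `B` of the active set) together with the
#' extreme rays of the cone \eqn{D_J = \{x : a_i \cdot x \le 0, i \in J\}},
#' plus the record `L` of ray pairs known to span 2-faces.  For a basis every
#' pair of rays is colaminar, so `L` starts as all pairs.
#'
#' @param H an [hrep()].
#' @param basis `n` 0-based row indices of full rank (e.g. from
#'   [choose_basis()]).
#' @return a `dd_state`: list with `J`, `rays`, `active`, `record`,
#'   `counters`.
#' @seealso [insert_halfspace()] to advance the state, [slice_cone()] for the
#'   whole loop.
#' @export
dd_state <- function(H, basis) {
  stopifnot_hrep(H)
  base <- biorthogonal_rays(H, basis)
  keys <- apply(base$rays, 2L, paste, collapse = ",")
  if (length(keys) >= 2L) {
    pairs <- t(utils::combn(keys, 2L))
    pairs <- t(apply(pairs, 1L, sort))
  } else {
    pairs <- matrix(character(0), 0L, 2L)
  }
  structure(list(J = sort(as.integer(basis)), rays = base$rays,
                 active = base$active, record = pairs,
                 counters = list(pairs_considered = 0, tests_run = 0,
                                 record_hits = 0, rejections = 0,
                                 duplicates_merged = 0,
                                 peak_rays = ncol(base$rays))),
            class = "dd_state")
}

#' @export
print.dd_state <- function(x, ...) {
  cat("double-description state: |J| =", length(x$J), ", rays =",
      ncol(x$rays), ", recorded pairs =", nrow(x$record), "\n")
  invisible(x)
}

#' Partition rays by the sign of a cutting half-space
#'
#' Splits a ray set against constraint `k` into \eqn{X^+} (strictly inside
#' the feasible half-space, \eqn{a_k \cdot \rho < 0}), \eqn{X^0} (on the
#' hyperplane) and \eqn{X^-} (outside).
#'
#' @param H an [hrep()].
#' @param rays an `n x r` character matrix of integer ray directions
#'   (columns), or a `cone_rays` / `dd_state` object.
#' @param k 0-based constraint index.
#' @return list of three integer vectors `pos`, `zero`, `neg` holding 1-based
#'   column indices into `rays`.
#' @export
partition_rays <- function(H, rays, k) {
  stopifnot_hrep(H)
  if (is.list(rays)) rays <- rays$rays
  out <- cpp_partition(H$A, rays, as.integer(k))
  lapply(out, function(i) i + 1L)
}

#' Joint active subset of a pair of rays
#'
#' The intersection \eqn{J|(\rho, \rho') = J|\rho \cap J|\rho'} of the two
#' rays' active index sets within their cone.
#'
#' @param act1,act2 integer vectors of 0-based active indices.
#' @return sorted integer vector.
#' @export
joint_active_set <- function(act1, act2) {
  sort(intersect(as.integer(act1), as.integer(act2)))
}

#' Necessary-condition pre-test for colaminarity
#'
#' A colaminar pair of extreme rays must share at least \eqn{n - 2} active
#' constraints, so a pair whose joint active set is smaller can be rejected
#' without running a rank or adjacency test.
#'
#' @param joint joint active subset (from [joint_active_set()]).
#' @param n ambient dimension.
#' @return `TRUE` to keep the pair (possibly colaminar), `FALSE` to reject.
#' @export
rejection_precheck <- function(joint, n) {
  length(joint) >= n - 2L
}

#' Algebraic colaminarity test
#'
#' A pair of extreme rays spans a 2-face of the cone exactly when its joint
#' active rows have rank \eqn{n - 2}.
#'
#' @param H an [hrep()].
#' @param joint joint active subset (0-based indices).
#' @return logical.
#' @export
colaminar_algebraic <- function(H, joint) {
  stopifnot_hrep(H)
  if (length(joint) == 0L) return(H$n == 2L)
  cpp_rank(H$A[joint + 1L, , drop = FALSE]) == H$n - 2L
}

#' Combinatorial colaminarity test
#'
#' A pair of extreme rays spans a 2-face exactly when no third extreme ray of
#' the same cone is active on every constraint of the pair's joint active
#' subset.
#'
#' @param active list of 0-based active index sets, one per ray of the
#'   current cone (e.g. `state$active`).
#' @param i,j 1-based positions of the pair within `active`.
#' @return logical.
#' @export
colaminar_combinatorial <- function(active, i, j) {
  joint <- joint_active_set(active[[i]], active[[j]])
  for (t in seq_along(active)) {
    if (t == i || t == j) next
    if (all(joint %in% active[[t]])) return(FALSE)
  }
  TRUE
}

#' Combine a dying and a surviving ray into a new extreme ray
#'
#' For a cutting constraint `k` and a colaminar pair with
#' \eqn{a_k \cdot \rho' > 0} (dying) and \eqn{a_k \cdot \rho < 0}
#' (surviving), the ray
#' \deqn{\varphi_k(\rho', \rho) = (a_k \cdot \rho')\,\rho -
#'       (a_k \cdot \rho)\,\rho'}
#' lies on the hyperplane \eqn{\partial H_k} and is extreme for the sliced
#' cone.  The result is reduced to primitive integer form.
#'
#' @param H an [hrep()].
#' @param k 0-based index of the cutting constraint.
#' @param rho_neg,rho_pos character vectors: the dying and surviving ray.
#' @return character vector: the new primitive ray direction.
#' @export
combine_rays <- function(H, k, rho_neg, rho_pos) {
  stopifnot_hrep(H)
  cpp_combine_ray(H$A, as.integer(k), rho_neg, rho_pos)
}

#' Insert one half-space into a double-description state
#'
#' One step of incremental slicing: partition the current rays against
#' constraint `k`, keep \eqn{X^+ \cup X^0}, and for every colaminar pair in
#' \eqn{X^- \times X^+} add the combined ray on \eqn{\partial H_k}.  With
#' `record = TRUE` the improved variant is used: pairs failing the
#' [rejection_precheck()] are discarded, pairs found in the 2-face record
#' skip the colaminarity test (the dying partner is replaced by the newborn
#' ray in the record), and freshly tested positives are added to the record.
#' New rays' active subsets are recomputed by direct dot products over
#' \eqn{J \cup \{k\}}, which captures coincidental incidences in highly
#' degenerate systems.
#'
#' @param H an [hrep()].
#' @param state a [dd_state()].
#' @param k 0-based index of the half-space to insert; must be outside
#'   `state$J` and keep `rank(J + k) = n` trivially satisfied (any row does).
#' @param test `"algebraic"` or `"combinatorial"` colaminarity test.
#' @param record use the 2-face record and rejection pre-test.
#' @return the advanced `dd_state`; the last step's details are attached as
#'   `attr(, "step")` (partition, colaminar pairs, new rays).
#' @export
insert_halfspace <- function(H, state, k,
                             test = c("algebraic", "combinatorial"),
                             record = TRUE) {
  stopifnot_hrep(H)
  if (!inherits(state, "dd_state")) stop("expected a 'dd_state'")
  test <- match.arg(test)
  k <- as.integer(k)
  if (k %in% state$J) stop("half-space ", k, " is already in J")
  out <- cpp_insert_halfspace(H$A, state$J, state$rays, state$active,
                              state$record, k,
                              if (test == "algebraic") 0L else 1L, record)
  st <- structure(list(J = out$J, rays = out$rays, active = out$active,
                       record = out$record,
                       counters = Map(`+`, state$counters,
                                      out$counters[names(state$counters)])),
                  class = "dd_state")
  st$counters$peak_rays <- max(state$counters$peak_rays,
                               out$counters$peak_rays, ncol(out$rays))
  attr(st, "step") <- out$step
  st
}

#' Enumerate the extreme rays of a vertex cone by incremental slicing
#'
#' Computes the extreme rays of the cone
#' \eqn{D_{Z(p)} = \{x : a_i \cdot x \le 0, i \in Z(p)\}} at an extreme
#' point.  Starting from the regular base cone of a basis
#' \eqn{B \subset Z(p)} ([biorthogonal_rays()]), the remaining half-spaces
#' \eqn{B' = Z(p) \setminus B} are inserted one at a time.  The final ray set
#' is independent of both the basis and the insertion order; the work done is
#' not, which is why the order can be chosen.
#'
#' @param H an [hrep()].
#' @param p an extreme point of the polytope, or `NULL` when `basis` and
#'   `order` fully describe the target cone.
#' @param basis optional explicit basis (0-based indices); default: greedy
#'   first-of-rank from the active set ([choose_basis()]).
#' @param order optional explicit insertion order for \eqn{B'}; default
#'   ascending.
#' @param test colaminarity test: `"algebraic"`, `"combinatorial"`.
#' @param record use the 2-face record + rejection pre-test (the improved
#'   slicer); `FALSE` runs the standard insertion function.
#' @param trace keep per-step details (partitions, colaminar pairs, new
#'   rays).
#' @return a `cone_rays` object with `rays`, `active`, `J`, `counters`,
#'   `trajectory` (ray count after each insertion) and, when `trace = TRUE`,
#'   `steps`.
#' @examples
#' ns <- gen_ns_example()
#' X <- slice_cone(ns$hrep, rep(0, 14))
#' ncol(X$rays)        # 54 extreme rays at the degenerate origin
#' X$trajectory
#' @export
slice_cone <- function(H, p, basis = NULL, order = NULL,
                       test = c("algebraic", "combinatorial"),
                       record = TRUE, trace = FALSE) {
  stopifnot_hrep(H)
  test <- match.arg(test)
  if (is.null(basis)) {
    if (is.null(p)) stop("either p or basis must be given")
    ext <- is_extreme(H, p)
    if (!ext$feasible) stop("p is not feasible")
    if (!ext$extreme) stop("p is not an extreme point")
    cb <- choose_basis(H, ext$active)
    basis <- cb$basis
    if (is.null(order)) order <- cb$bprime
  } else {
    basis <- sort(as.integer(basis))
    if (is.null(order)) {
      if (is.null(p)) stop("without p, an explicit order must accompany basis")
      Z <- active_set(H, p)
      order <- setdiff(Z, basis)
    }
  }
  order <- as.integer(order)
  if (length(intersect(basis, order)))
    stop("insertion order overlaps the basis")
  out <- cpp_slice_cone(H$A, as.integer(basis), order,
                        if (test == "algebraic") 0L else 1L, record, trace)
  structure(list(rays = out$rays, active = out$active, J = out$J,
                 basis = basis, order = order,
                 counters = out$counters, trajectory = out$trajectory,
                 steps = if (trace) out$steps else NULL),
            class = "cone_rays")
}
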