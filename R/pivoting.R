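#' Step length along an extreme ray to a blocking hyperplane
#'
#' For a vertex `p`, an extreme ray \eqn{\rho} of its cone and a constraint
#' \eqn{t \notin Z(p)} with \eqn{a_t \cdot \rho > 0}, the ray pierces
#' \eqn{\partial H_t} at \eqn{p + \lambda_t \rho} with
#' \deqn{\lambda_t = (b_t - p \cdot a_t) / (\rho \cdot a_t) > 0.}
#' Scaling the ray rescales \eqn{\lambda_t} inversely; the pierce point is
#' unchanged.
#'
#' @param H an [hrep()].
#' @param p the vertex (exact point).
#' @param ray character vector: integer ray direction.
#' @param t 0-based constraint index; must be blocking
#'   (\eqn{a_t \cdot \rho > 0}), otherwise an error.
#' @return exact rational \eqn{\lambda_t} as a character scalar.
#' @export
step_length <- function(H, p, ray, t) {
  stopifnot_hrep(H)
  cpp_step_length(H$A, H$b, as_point(H, p), ray, as.integer(t))
}

#' Neighbouring vertices by min-ratio pivoting
#'
#' Walks from the vertex `p` along each extreme ray of its cone to the first
#' blocking hyperplane: for ray \eqn{\rho} the neighbour is
#' \eqn{q = p + \lambda \rho} with
#' \eqn{\lambda = \min_{t \in N_p(\rho)} \lambda_t} over the blocking set
#' \eqn{N_p(\rho) = \{t \notin Z(p) : a_t \cdot \rho > 0\}}.  For a compact
#' feasible region every ray is blocked; an unblocked ray means the polytope
#' is unbounded, which raises an error unless `allow_unbounded = TRUE`
#' (such rays are then skipped and the result flagged partial).
#'
#' Each extreme ray is a 1-face direction, so distinct rays reach distinct
#' neighbours and every pair `{p, q}` is an edge of the skeleton graph.
#'
#' @param H an [hrep()].
#' @param p the vertex.
#' @param rays a `cone_rays` object from [slice_cone()] (or a compatible
#'   list with `rays` and `active`).
#' @param allow_unbounded skip unblocked rays instead of erroring.
#' @return a list with `neighbors` (character matrix, one row per neighbour),
#'   `unbounded` (logical per ray) and `partial` (any ray unblocked).
#' @examples
#' ns <- gen_ns_example()
#' p <- rep(0, 14)
#' nb <- neighbors(ns$hrep, p, slice_cone(ns$hrep, p))
#' nrow(nb$neighbors)   # 54 neighbours of the origin
#' @export
neighbors <- function(H, p, rays, allow_unbounded = FALSE) {
  stopifnot_hrep(H)
  p <- as_point(H, p)
  if (!is.list(rays) || is.null(rays$rays))
    stop("rays must be a cone_rays object (see slice_cone())")
  out <- cpp_neighbors(H$A, H$b, p, rays$rays, rays$active, allow_unbounded)
  keep <- !out$unbounded
  nb <- out$neighbors[keep, , drop = FALSE]
  if (anyDuplicated(apply(nb, 1L, paste, collapse = ",")))
    stop("two extreme rays reached the same neighbour; ",
         "this should be impossible in exact arithmetic")
  list(neighbors = nb, unbounded = out$unbounded, partial = any(out$unbounded))
}
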