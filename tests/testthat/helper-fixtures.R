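# Shared helpers: canonical graph forms for invariance checks and a
# brute-force vertex/edge oracle built only on the low-level exact
# primitives (solve/rank/slack), independent of the slicing and traversal
# code paths it is used to check.

# unit-sum vector in dimension n as a canonical key string, 0-based indices
esum <- function(n, ...) {
  v <- rep(0L, n)
  for (i in c(...)) v[i + 1L] <- v[i + 1L] + 1L
  paste(v, collapse = ",")
}

graph_keys <- function(G) {
  keys <- apply(G$vertices, 1L, paste, collapse = ",")
  ek <- if (nrow(G$edges))
    apply(G$edges, 1L, function(e) paste(sort(keys[e]), collapse = " | "))
  else character(0)
  list(vkeys = sort(keys), ekeys = sort(ek))
}

ray_keys <- function(X) sort(apply(X$rays, 2L, paste, collapse = ","))

# exhaustive C(m, n) oracle: every full-rank row subset yields a candidate
# point; feasible ones are vertices; adjacency via rank(Z(p) ^ Z(q)) = n - 1
brute_force_graph <- function(H) {
  n <- H$n
  combs <- utils::combn(H$m, n)
  keys <- character(0)
  Zs <- list()
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    M <- H$A[S, , drop = FALSE]
    if (matrix_rank(M) < n) next
    x <- solve_rational(M, H$b[S])
    s <- slack_vector(H, x)
    if (any(startsWith(s, "-"))) next
    k <- paste(x, collapse = ",")
    if (!(k %in% keys)) {
      keys <- c(keys, k)
      Zs[[length(Zs) + 1L]] <- which(s == "0") - 1L
    }
  }
  edges <- character(0)
  nv <- length(keys)
  if (nv > 1L) {
    for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
      joint <- intersect(Zs[[i]], Zs[[j]])
      if (length(joint) >= n - 1L &&
          matrix_rank(H$A[joint + 1L, , drop = FALSE]) == n - 1L)
        edges <- c(edges, paste(sort(c(keys[i], keys[j])),
                                collapse = " | "))
    }
  }
  list(vkeys = sort(keys), ekeys = sort(edges))
}

# small fixture set reused across suites (all with m <= 12 for the oracle)
small_fixtures <- function() {
  list(gen_classic("cube", 3),
       gen_classic("simplex", 3),
       gen_classic("simplex", 4),
       gen_classic("crosspolytope", 3),
       gen_birkhoff(3),
       gen_random_regular(3, 8, seed = 11))
}

# start point turned into a vertex where needed
fixture_vertex <- function(fx) {
  if (is_extreme(fx$hrep, fx$start)$extreme) as_rational(fx$start)
  else tighten_to_vertex(fx$hrep, fx$start)
}
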