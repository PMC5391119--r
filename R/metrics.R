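#' Convert a skeleton graph to an igraph object
#'
#' Vertices keep their exact coordinates (comma-joined rational string) as
#' the `coords` attribute and their degeneracy as `sigma`.
#'
#' @param G a `skeleton_graph` from [skeleton_graph()].
#' @return an undirected [igraph::graph].
#' @export
as_igraph <- function(G) {
  if (!inherits(G, "skeleton_graph")) stop("expected a 'skeleton_graph'")
  nv <- nrow(G$vertices)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (nrow(G$edges) > 0)
    g <- igraph::add_edges(g, t(G$edges))
  igraph::vertex_attr(g, "coords") <- apply(G$vertices, 1L, paste,
                                            collapse = ",")
  igraph::vertex_attr(g, "sigma") <- G$sigma
  g
}

#' Size and connectivity metrics of a conversion
#'
#' Summarizes the input system and the output graph with the measures used
#' to classify conversion complexity: the input size
#' \eqn{\zeta = n\,m\,\langle Z\rangle} (with
#' \eqn{\langle Z\rangle = n + \langle\sigma\rangle} the mean number of
#' active hyperplanes over vertices), the mean degree
#' \eqn{\langle X\rangle = 2|E|/|V|}, and the output connectivity
#' \eqn{\kappa = \langle X\rangle / |V|} (below 1 for non-complete graphs).
#' The product \eqn{\kappa\zeta} combines both sides.  The slicer's
#' instrumentation counters and the slicing/pivoting time split are carried
#' through.
#'
#' @param G a `skeleton_graph`.
#' @param diameter_cap compute the graph diameter (all-pairs BFS via igraph)
#'   only when \eqn{|V|} does not exceed this.
#' @return a `conversion_report` list; see Details for fields.
#' @details Fields: `n_vertices`, `n_edges`, `degree_histogram`,
#'   `mean_degree`, `kappa`, `mean_active` (\eqn{\langle Z\rangle}),
#'   `mean_sigma`, `zeta`, `kappa_zeta`, `edge_fraction` (share of the
#'   complete graph's edges), `diameter` (or `NA` beyond the cap),
#'   `handshake_ok`, `counters`, `timings`.
#' @examples
#' G <- skeleton_graph(gen_classic("cube", 3)$hrep, start = rep(0, 3))
#' compute_metrics(G)
#' @export
compute_metrics <- function(G, diameter_cap = 4096L) {
  if (!inherits(G, "skeleton_graph")) stop("expected a 'skeleton_graph'")
  H <- G$hrep
  nv <- nrow(G$vertices)
  ne <- nrow(G$edges)
  meanX <- 2 * ne / nv
  meanZ <- mean(lengths(G$active_sets))
  dia <- if (nv <= diameter_cap) igraph::diameter(as_igraph(G)) else NA
  rep <- list(
    n_vertices = nv,
    n_edges = ne,
    degree_histogram = table(G$degree),
    mean_degree = meanX,
    kappa = meanX / nv,
    mean_active = meanZ,
    mean_sigma = mean(G$sigma),
    zeta = H$n * H$m * meanZ,
    kappa_zeta = (meanX / nv) * H$n * H$m * meanZ,
    edge_fraction = if (nv > 1) ne / choose(nv, 2) else NA,
    diameter = dia,
    handshake_ok = sum(G$degree) == 2L * ne,
    counters = G$counters,
    timings = G$timings)
  class(rep) <- "conversion_report"
  rep
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("conversion report\n")
  cat(sprintf("  |V| = %d, |E| = %d, <X> = %.4g, kappa = %.4g\n",
              x$n_vertices, x$n_edges, x$mean_degree, x$kappa))
  cat(sprintf("  <Z> = %.4g, <sigma> = %.4g, zeta = %.6g, kappa*zeta = %.6g\n",
              x$mean_active, x$mean_sigma, x$zeta, x$kappa_zeta))
  if (!is.na(x$diameter)) cat("  diameter =", x$diameter, "\n")
  cat("  degree histogram:",
      paste(sprintf("%s:%d", names(x$degree_histogram),
                    as.integer(x$degree_histogram)), collapse = "  "), "\n")
  ct <- x$counters
  cat(sprintf("  slicer: %g pairs, %g tests, %g record hits, %g rejections, peak %d rays\n",
              ct$pairs_considered, ct$tests_run, ct$record_hits,
              ct$rejections, ct$peak_rays))
  cat(sprintf("  time: slicing %.3fs, pivoting %.3fs\n",
              x$timings$slicing_sec, x$timings$pivoting_sec))
  invisible(x)
}

#' Serialize a skeleton graph
#'
#' Writes the graph with exact rational vertex coordinates (as strings) in a
#' deterministic order, so repeated runs produce byte-identical files.
#' Formats: `edgelist` (one `i j` pair of 1-based vertex ids per line, after
#' a `# vertex` block), `dot` (Graphviz), `graphml` (via igraph) and `json`
#' (vertices with coordinates, active sets and degeneracy, plus the edge
#' list).
#'
#' @param G a `skeleton_graph`.
#' @param path output file.
#' @param format one of `"edgelist"`, `"dot"`, `"graphml"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(G, path,
                        format = c("edgelist", "dot", "graphml", "json")) {
  if (!inherits(G, "skeleton_graph")) stop("expected a 'skeleton_graph'")
  format <- match.arg(format)
  keys <- apply(G$vertices, 1L, paste, collapse = ",")
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %d vertices, %d edges", nrow(G$vertices),
                       nrow(G$edges)), con)
    writeLines(sprintf("v %d %s", seq_along(keys), keys), con)
    if (nrow(G$edges))
      writeLines(sprintf("e %d %d", G$edges[, 1L], G$edges[, 2L]), con)
  } else if (format == "dot") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("graph skeleton {", con)
    writeLines(sprintf("  v%d [label=\"(%s)\"];", seq_along(keys), keys),
               con)
    if (nrow(G$edges))
      writeLines(sprintf("  v%d -- v%d;", G$edges[, 1L], G$edges[, 2L]),
                 con)
    writeLines("}", con)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(G), path, format = "graphml")
  } else {
    out <- list(
      n = G$hrep$n, m = G$hrep$m,
      vertices = lapply(seq_len(nrow(G$vertices)), function(i)
        list(id = i, coords = unname(G$vertices[i, ]),
             active = G$active_sets[[i]], sigma = G$sigma[i],
             degree = G$degree[i])),
      edges = if (nrow(G$edges)) unname(split(G$edges, row(G$edges)))
              else list())
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
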