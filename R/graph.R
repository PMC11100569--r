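#' Build a spatial cell graph for one region
#'
#' Two neighbourhood models are supported. \code{knn}: each cell is linked
#' to its \code{k} nearest neighbours by Euclidean centroid distance (default
#' \code{k = 6}), and the directed relation is symmetrized by union, so a
#' node's degree can exceed \code{k}. Distance ties are broken by
#' lexicographic \code{cell_id} for determinism. \code{contact}: an edge
#' joins every pair of cells whose centroid distance is at most
#' \code{contact_radius} (a centroid-level stand-in for touching
#' segmentation masks).
#'
#' @param cells a \code{cell_table}.
#' @param region_id region to build the graph for.
#' @param mode \code{"knn"} or \code{"contact"}.
#' @param k neighbour count for knn mode (default 6).
#' @param contact_radius contact threshold in um (default 15).
#' @return an \code{igraph} graph; vertices are named by \code{cell_id} and
#'   carry a \code{population} attribute; graph attributes record the mode
#'   and parameters.
#' @export
build_graph <- function(cells, region_id, mode = c("knn", "contact"),
                        k = 6, contact_radius = 15) {
  mode <- match.arg(mode)
  v <- region_view(cells, region_id)
  n <- nrow(v)
  if (n < 2L) stop("region '", region_id, "' has fewer than 2 cells")
  D <- as.matrix(dist(cbind(v$x, v$y)))
  if (mode == "knn") {
    stopifnot(k >= 1)
    if (k >= n) {
      warning("k >= region size; graph is complete")
      k <- n - 1L
    }
    from <- integer(0); to <- integer(0)
    ids <- v$cell_id
    for (i in seq_len(n)) {
      o <- order(D[i, ], ids)        # ties broken by cell_id
      o <- o[o != i][seq_len(k)]
      from <- c(from, rep.int(i, k)); to <- c(to, o)
    }
    e <- cbind(pmin(from, to), pmax(from, to))
    e <- unique(e)
  } else {
    stopifnot(contact_radius > 0)
    hit <- which(D <= contact_radius & upper.tri(D), arr.ind = TRUE)
    e <- hit[, c(1, 2), drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = v$cell_id)
  g <- igraph::set_vertex_attr(g, "population", value = v$population)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  g <- igraph::set_graph_attr(g, "mode", mode)
  g <- igraph::set_graph_attr(g, "region_id", region_id)
  g <- igraph::set_graph_attr(g, if (mode == "knn") "k" else "contact_radius",
                              if (mode == "knn") k else contact_radius)
  g
}

# CSR adjacency (0-based, sorted) of an igraph graph, for the C++ kernels
graph_csr <- function(g) {
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(a) sort(as.integer(a) - 1L))
  list(indptr = c(0L, cumsum(lengths(adj))),
       indices = as.integer(unlist(adj, use.names = FALSE)))
}

#' Nearest-neighbour distances between two populations
#'
#' For every cell of \code{source_pop} in one region, the Euclidean distance
#' to the nearest cell of \code{target_pop}, the cell itself excluded when
#' the populations coincide.
#'
#' @param cells a \code{cell_table}.
#' @param region_id region to evaluate.
#' @param source_pop,target_pop population labels.
#' @return named numeric vector (names = source cell ids), in um. Entries
#'   are \code{NA} (with a warning) when no target cell is available.
#' @export
nearest_distances <- function(cells, region_id, source_pop, target_pop) {
  v <- region_view(cells, region_id)
  src <- which(v$population == source_pop)
  if (!length(src)) stop("source population '", source_pop,
                         "' empty in region '", region_id, "'")
  tgt <- which(v$population == target_pop)
  out <- setNames(rep(NA_real_, length(src)), v$cell_id[src])
  if (!length(tgt)) {
    warning("target population '", target_pop, "' empty in region '",
            region_id, "'; distances undefined")
    return(out)
  }
  tx <- v$x[tgt]; ty <- v$y[tgt]
  for (ii in seq_along(src)) {
    i <- src[ii]
    d2 <- (tx - v$x[i])^2 + (ty - v$y[i])^2
    if (source_pop == target_pop) d2[tgt == i] <- Inf
    m <- min(d2)
    out[ii] <- if (is.finite(m)) sqrt(m) else NA_real_
  }
  if (anyNA(out))
    warning("some source cells have no available target (self excluded)")
  out
}
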