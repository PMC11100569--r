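#' Clustering coefficient of one population's induced subgraph
#'
#' Extracts the vertex-induced subgraph of a population (edges between that
#' population's members only) and averages the local clustering coefficient
#' over its nodes: triangles through a node divided by its possible
#' neighbour pairs, with nodes of induced degree < 2 contributing 0.
#' Populations with fewer than 3 members return 0, flagged.
#'
#' @param graph a graph from \code{\link{build_graph}}.
#' @param population population label present in the graph.
#' @return number in \code{[0, 1]}; attribute \code{"flag"} set to
#'   \code{"too_few_members"} for populations of size < 3.
#' @export
population_clustering <- function(graph, population) {
  lab_chr <- igraph::V(graph)$population
  if (!population %in% lab_chr)
    stop("population '", population, "' absent from graph")
  lab <- as.integer(lab_chr == population) + 1L  # 2 = focal population
  csr <- graph_csr(graph)
  val <- perm_pop_clustering(csr$indptr, csr$indices,
                             matrix(lab, ncol = 1L), 2L)[2L, 1L]
  if (sum(lab == 2L) < 3L)
    return(structure(0, flag = "too_few_members"))
  val
}

#' Abundance-corrected clustering coefficients
#'
#' Observed per-population clustering coefficients minus their mean over
#' label permutations on the same fixed graph (default 300 draws). Positive
#' values mean a population forms denser homotypic clusters than its
#' abundance alone predicts.
#'
#' @inheritParams distance_enrichment
#' @param graph optional prebuilt region graph; default 6-nearest-neighbour.
#' @param ... passed to \code{\link{build_graph}} when \code{graph} is NULL.
#' @return data.frame: population, n_cells, observed, expected, null_sd,
#'   corrected, flag (populations with < 3 members are undefined).
#' @export
corrected_clustering <- function(cells, region_id, graph = NULL,
                                 n_perm = 300, seed = NULL, perm_fun = NULL,
                                 ...) {
  v <- region_view(cells, region_id)
  graph <- graph %||% build_graph(cells, region_id, mode = "knn", ...)
  stopifnot(identical(igraph::V(graph)$name, v$cell_id), n_perm >= 1)
  pops <- sort(unique(v$population))
  lab <- as.integer(factor(v$population, levels = pops))
  lm <- label_matrix(lab, n_perm, derive_seed(seed, region_id, "clustering"),
                     perm_fun)
  csr <- graph_csr(graph)
  m <- perm_pop_clustering(csr$indptr, csr$indices, lm, length(pops))
  observed <- m[, 1L]
  expected <- rowMeans(m[, -1L, drop = FALSE], na.rm = TRUE)
  null_sd <- apply(m[, -1L, drop = FALSE], 1, sd, na.rm = TRUE)
  out <- data.frame(population = pops, n_cells = tabulate(lab, length(pops)),
                    observed = observed, expected = expected,
                    null_sd = null_sd, corrected = observed - expected,
                    flag = "")
  small <- out$n_cells < 3L
  out$corrected[small] <- NA_real_
  out$flag[small] <- "too_few_members"
  rownames(out) <- NULL
  out
}

#' Label assortativity of a cell graph
#'
#' Newman's discrete assortativity coefficient over the population label:
#' from the edge mixing matrix \eqn{e}, \eqn{(\sum_i e_{ii} - \sum_i a_i
#' b_i) / (1 - \sum_i a_i b_i)}, where \eqn{a}, \eqn{b} are its marginals.
#' 1 means cells connect only within their population, negative values mean
#' heterotypic preference. With \code{per_population = TRUE} the per-label
#' decomposition \eqn{e_{ii} - a_i b_i} is also returned, since a single
#' coefficient hides which populations drive the mixing.
#'
#' @param graph a graph from \code{\link{build_graph}} with >= 1 edge.
#' @param per_population also return the per-label terms.
#' @return the coefficient in \code{[-1, 1]} (NA with a flag when only one
#'   population is present), or a list with elements \code{assortativity}
#'   and \code{per_population}.
#' @export
label_assortativity <- function(graph, per_population = FALSE) {
  lab_chr <- igraph::V(graph)$population
  pops <- sort(unique(lab_chr))
  if (igraph::ecount(graph) == 0L) stop("graph has no edges")
  if (length(pops) < 2L) {
    r <- structure(NA_real_, flag = "single_population")
    return(if (per_population) list(assortativity = r,
                                    per_population = setNames(NA_real_, pops))
           else r)
  }
  r <- igraph::assortativity_nominal(
    graph, as.integer(factor(lab_chr, levels = pops)), directed = FALSE)
  if (!per_population) return(r)
  e <- igraph::as_edgelist(graph, names = FALSE)
  l1 <- factor(lab_chr[e[, 1]], levels = pops)
  l2 <- factor(lab_chr[e[, 2]], levels = pops)
  mix <- (table(l1, l2) + table(l2, l1)) / (2 * nrow(e))
  ai <- rowSums(mix)
  per <- diag(mix) - ai * ai   # undirected: marginals coincide
  list(assortativity = r, per_population = setNames(as.numeric(per), pops))
}
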