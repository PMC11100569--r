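#' Randomly permute population labels
#'
#' The elementary move of the permutation null: cell positions stay fixed
#' while the vector of population labels is uniformly reshuffled, conserving
#' each population's count exactly.
#'
#' @param labels character vector of population labels.
#' @param seed optional seed for a reproducible draw (the caller's RNG
#'   stream is left untouched).
#' @return a permuted label vector of the same length and composition.
#' @export
permute_labels <- function(labels, seed = NULL) {
  with_seed(seed, sample(labels))
}

# n x (n_perm + 1) integer label matrix; column 1 is the observed labeling.
# perm_fun replaces the default uniform shuffle (used by identity-null
# tests and diagnostics).
label_matrix <- function(lab_int, n_perm, seed, perm_fun = NULL) {
  perm_fun <- perm_fun %||% sample
  with_seed(seed, {
    m <- matrix(0L, length(lab_int), n_perm + 1L)
    m[, 1L] <- lab_int
    for (p in seq_len(n_perm)) m[, p + 1L] <- perm_fun(lab_int)
    m
  })
}

new_enrichment_result <- function(region_id, region_class, statistic,
                                  observed, expected, diff, null_sd,
                                  n_perm, seed) {
  structure(list(region_id = region_id, region_class = region_class,
                 statistic = statistic, observed = observed,
                 expected = expected, diff = diff, null_sd = null_sd,
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result [%s] region %s (%s), %d permutations\n",
              x$statistic, x$region_id, x$region_class, x$n_perm))
  cat("observed - expected:\n")
  print(round(x$diff, 4))
  invisible(x)
}

#' Nearest-distance enrichment against a label-permutation null
#'
#' For one region, the observed statistic is the population-by-population
#' matrix of mean nearest-neighbour distances (mean over population-i cells
#' of the distance to the nearest population-j cell). The null holds
#' positions fixed and reshuffles labels \code{n_perm} times (default 300);
#' the result is observed minus the null mean, so negative diagonal values
#' indicate populations sitting closer to themselves than chance predicts.
#'
#' @param cells a \code{cell_table}.
#' @param region_id region to evaluate.
#' @param n_perm number of label permutations (default 300).
#' @param seed master seed; each region x statistic derives its own stream.
#' @param perm_fun advanced: replacement for the uniform shuffle (e.g.
#'   \code{identity} freezes the null for calibration checks).
#' @return an \code{enrichment_result} with \code{observed}, \code{expected}
#'   (null mean), \code{diff}, and \code{null_sd} matrices. Entries
#'   undefined under a labeling (empty source or target) are \code{NA} and
#'   excluded from null averaging.
#' @export
distance_enrichment <- function(cells, region_id, n_perm = 300, seed = NULL,
                                perm_fun = NULL) {
  v <- region_view(cells, region_id)
  if (nrow(v) < 2L) stop("region '", region_id, "' has fewer than 2 cells")
  pops <- sort(unique(v$population))
  if (length(pops) < 2L) stop("need >= 2 populations in region '",
                              region_id, "'")
  stopifnot(n_perm >= 1)
  lab <- as.integer(factor(v$population, levels = pops))
  lm <- label_matrix(lab, n_perm, derive_seed(seed, region_id, "distance"),
                     perm_fun)
  D <- as.matrix(dist(cbind(v$x, v$y)))
  arr <- perm_nearest_means(D, lm, length(pops))
  dimnames(arr) <- list(pops, pops, NULL)
  observed <- arr[, , 1L, drop = TRUE]
  nulls <- arr[, , -1L, drop = FALSE]
  expected <- apply(nulls, c(1, 2), mean, na.rm = TRUE)
  null_sd <- apply(nulls, c(1, 2), sd, na.rm = TRUE)
  expected[is.nan(expected)] <- NA_real_
  new_enrichment_result(region_id, v$region_class[1], "nearest_distance",
                        observed, expected, observed - expected, null_sd,
                        n_perm, seed)
}

# population x population edge-endpoint proportion matrix for one labeling
endpoint_proportions <- function(e1, e2, lab, npop) {
  idx <- c((lab[e1] - 1L) * npop + lab[e2], (lab[e2] - 1L) * npop + lab[e1])
  counts <- matrix(tabulate(idx, npop * npop), npop, npop, byrow = TRUE)
  tot <- rowSums(counts)
  prop <- counts / tot
  prop[tot == 0, ] <- NA_real_
  prop
}

#' Interaction proportions on a cell graph
#'
#' Entry \code{(i, j)} is the fraction of population-i edge endpoints that
#' land on population-j cells; rows sum to 1 for populations with at least
#' one edge. Populations present but isolated get an \code{NA} row (flagged
#' in the \code{"undefined"} attribute).
#'
#' @param graph a graph from \code{\link{build_graph}}.
#' @return population x population proportion matrix.
#' @export
interaction_proportions <- function(graph) {
  lab_chr <- igraph::V(graph)$population
  pops <- sort(unique(lab_chr))
  lab <- as.integer(factor(lab_chr, levels = pops))
  e <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(e) == 0L) stop("graph has no edges")
  prop <- endpoint_proportions(e[, 1], e[, 2], lab, length(pops))
  dimnames(prop) <- list(pops, pops)
  attr(prop, "undefined") <- pops[rowSums(!is.na(prop)) == 0]
  prop
}

#' Interaction enrichment against a label-permutation null
#'
#' Observed interaction proportions minus their mean over label
#' permutations on the same fixed graph (topology is never recomputed under
#' the null), correcting interaction rates for population abundances.
#'
#' @inheritParams distance_enrichment
#' @param graph optional prebuilt graph for the region; default is the
#'   6-nearest-neighbour graph.
#' @param ... passed to \code{\link{build_graph}} when \code{graph} is NULL.
#' @return an \code{enrichment_result} (statistic
#'   \code{"interaction_proportion"}).
#' @export
interaction_enrichment <- function(cells, region_id, graph = NULL,
                                   n_perm = 300, seed = NULL,
                                   perm_fun = NULL, ...) {
  v <- region_view(cells, region_id)
  graph <- graph %||% build_graph(cells, region_id, mode = "knn", ...)
  stopifnot(identical(igraph::V(graph)$name, v$cell_id))
  pops <- sort(unique(v$population))
  lab <- as.integer(factor(v$population, levels = pops))
  npop <- length(pops)
  e <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(e) == 0L) stop("graph has no edges")
  lm <- label_matrix(lab, n_perm, derive_seed(seed, region_id, "interaction"),
                     perm_fun)
  arr <- vapply(seq_len(ncol(lm)),
                function(p) endpoint_proportions(e[, 1], e[, 2], lm[, p], npop),
                matrix(0, npop, npop))
  dimnames(arr) <- list(pops, pops, NULL)
  observed <- arr[, , 1L, drop = TRUE]
  nulls <- arr[, , -1L, drop = FALSE]
  expected <- apply(nulls, c(1, 2), mean, na.rm = TRUE)
  null_sd <- apply(nulls, c(1, 2), sd, na.rm = TRUE)
  expected[is.nan(expected)] <- NA_real_
  new_enrichment_result(region_id, v$region_class[1],
                        "interaction_proportion", observed, expected,
                        observed - expected, null_sd, n_perm, seed)
}

#' Cross-region group tests of enrichment differences
#'
#' Pools per-region observed-minus-expected matrices by tissue group (edge
#' and core regions separately) and tests each population pair's diff
#' against 0 with a one-sample Wilcoxon signed-rank test, one value per
#' region. Benjamini-Hochberg adjustment is applied over all entries tested
#' within a group. Undefined (NA) entries are skipped; families whose diffs
#' are identically zero get p = 1 with a degeneracy flag.
#'
#' @param results list of \code{enrichment_result}s for the same statistic.
#' @param groups optional named vector mapping region ids to group labels;
#'   default is each region's recorded \code{edge}/\code{core} class.
#' @return data.frame: statistic, group, pop_i, pop_j, n_regions,
#'   mean_diff, p, p_adj, flag.
#' @export
group_test <- function(results, groups = NULL) {
  stopifnot(length(results) >= 1)
  stat <- unique(vapply(results, `[[`, "", "statistic"))
  if (length(stat) != 1L)
    stop("all results must share one statistic, got: ",
         paste(stat, collapse = ", "))
  grp <- if (is.null(groups))
    vapply(results, `[[`, "", "region_class")
  else unname(groups[vapply(results, `[[`, "", "region_id")])
  rows <- list()
  for (g in unique(grp)) {
    rs <- results[grp == g]
    pops <- sort(unique(unlist(lapply(rs, function(r) rownames(r$diff)))))
    for (a in pops) for (b in pops) {
      d <- vapply(rs, function(r) {
        if (a %in% rownames(r$diff) && b %in% colnames(r$diff))
          r$diff[a, b] else NA_real_
      }, 0)
      d <- d[!is.na(d)]
      if (length(d) < 2L) {
        rows[[length(rows) + 1L]] <-
          data.frame(statistic = stat, group = g, pop_i = a, pop_j = b,
                     n_regions = length(d), mean_diff = mean(d),
                     p = NA_real_, flag = "insufficient_regions")
        next
      }
      if (all(d == 0)) {
        rows[[length(rows) + 1L]] <-
          data.frame(statistic = stat, group = g, pop_i = a, pop_j = b,
                     n_regions = length(d), mean_diff = 0,
                     p = 1, flag = "degenerate")
        next
      }
      p <- suppressWarnings(wilcox.test(d, mu = 0)$p.value)
      rows[[length(rows) + 1L]] <-
        data.frame(statistic = stat, group = g, pop_i = a, pop_j = b,
                   n_regions = length(d), mean_diff = mean(d),
                   p = p, flag = "")
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (g in unique(out$group)) {
    sel <- out$group == g
    out$p_adj[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}
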