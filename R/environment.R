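#' Rao's quadratic entropy of cell neighbourhoods
#'
#' For each cell, the neighbourhood is the cell plus its graph neighbours
#' (contact-mode graphs by convention). With uniform weights
#' \eqn{p_i = 1/m} over the \eqn{m} neighbourhood members, the entropy is
#' \eqn{Q = \sum_i \sum_j p_i p_j d(i, j)} with \eqn{d} the Euclidean
#' distance between normalized marker (phenotype) vectors. Q is 0 when all
#' contacted phenotypes are identical; isolated cells return 0, flagged.
#'
#' @param cells a normalized \code{cell_table} (markers in \code{[0, 1]}).
#' @param graph a contact-mode graph for one region of \code{cells}.
#' @param markers marker columns to use as the phenotype; default all.
#' @return named numeric vector of entropies (one per graph vertex);
#'   attribute \code{"isolated"} lists cells without contacts.
#' @export
rao_entropy <- function(cells, graph, markers = NULL) {
  markers <- markers %||% marker_names(cells)
  ids <- igraph::V(graph)$name
  idx <- match(ids, cells$cell_id)
  if (anyNA(idx)) stop("graph contains cells unknown to the table")
  M <- as.matrix(as.data.frame(cells)[idx, markers, drop = FALSE])
  if (any(M < -1e-9) || any(M > 1 + 1e-9))
    warning("phenotype markers outside [0, 1]; normalize first")
  adj <- igraph::as_adj_list(graph, mode = "all")
  out <- setNames(numeric(length(ids)), ids)
  iso <- character(0)
  for (i in seq_along(ids)) {
    nb <- as.integer(adj[[i]])
    if (!length(nb)) { iso <- c(iso, ids[i]); next }
    hood <- c(i, nb)
    d <- as.matrix(dist(M[hood, , drop = FALSE]))
    out[i] <- sum(d) / length(hood)^2
  }
  attr(out, "isolated") <- iso
  out
}

#' Windowed marker expression around each cell
#'
#' Mean raster intensity in a window centered on each cell: by default an
#' axis-aligned square of side \code{window_um} (40 um), optionally a disc
#' of that diameter. A pixel belongs to the window when its center falls
#' inside; windows are clipped at the raster border and averaged over
#' in-bounds pixels only. The square path uses an exact summed-area table.
#'
#' @param cells a \code{cell_table} (one region, coordinates covered by the
#'   raster).
#' @param raster a \code{marker_raster}.
#' @param window_um window side (square) or diameter (disc), default 40.
#' @param shape \code{"square"} (default) or \code{"disc"}.
#' @return named numeric vector of per-cell means; cells whose window holds
#'   no pixel center are \code{NA} and listed in attribute \code{"empty"}.
#' @export
window_expression <- function(cells, raster, window_um = 40,
                              shape = c("square", "disc")) {
  shape <- match.arg(shape)
  stopifnot(inherits(raster, "marker_raster"), window_um > 0)
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g)
  s <- raster$scale; ox <- raster$origin[1]; oy <- raster$origin[2]
  h <- window_um / 2
  out <- setNames(rep(NA_real_, nrow(cells)), cells$cell_id)
  if (shape == "square") {
    # summed-area table with zero padding
    S <- matrix(0, nr + 1L, nc + 1L)
    S[-1L, -1L] <- t(apply(apply(g, 2, cumsum), 1, cumsum))
    jlo <- pmax(1L, ceiling((cells$x - h - ox) / s + 0.5))
    jhi <- pmin(nc, floor((cells$x + h - ox) / s + 0.5))
    ilo <- pmax(1L, ceiling((cells$y - h - oy) / s + 0.5))
    ihi <- pmin(nr, floor((cells$y + h - oy) / s + 0.5))
    ok <- which(jlo <= jhi & ilo <= ihi & jlo <= nc & ilo <= nr &
                  jhi >= 1L & ihi >= 1L)
    tot <- S[cbind(ihi[ok] + 1L, jhi[ok] + 1L)] -
      S[cbind(ilo[ok], jhi[ok] + 1L)] -
      S[cbind(ihi[ok] + 1L, jlo[ok])] + S[cbind(ilo[ok], jlo[ok])]
    npx <- (ihi[ok] - ilo[ok] + 1) * (jhi[ok] - jlo[ok] + 1)
    out[ok] <- tot / npx
  } else {
    ctr <- raster_centers(raster)
    for (i in seq_len(nrow(cells))) {
      dx2 <- (ctr$x - cells$x[i])^2
      dy2 <- (ctr$y - cells$y[i])^2
      keep_j <- which(dx2 <= h^2)
      if (!length(keep_j)) next
      msk <- outer(dy2, dx2[keep_j], `+`) <= h^2
      if (!any(msk)) next
      out[i] <- mean(g[, keep_j, drop = FALSE][msk])
    }
  }
  empty <- names(out)[is.na(out)]
  if (length(empty)) warning(length(empty), " window(s) held no pixel center")
  attr(out, "empty") <- empty
  out
}

#' Cross-pair interaction statistic at a fixed radius
#'
#' Counts pairs of cells from two populations within \code{radius_um}
#' (default 20 um), normalized by the number of possible pairs, and
#' compares the observed value to the label-permutation null. A positive
#' diff means the populations co-occur at interaction range more often than
#' a random labeling predicts. The empirical two-sided p-value uses the
#' add-one correction \eqn{(1 + \#\{null \ge obs\}) / (n_{perm} + 1)}.
#'
#' @inheritParams distance_enrichment
#' @param pop_a,pop_b population labels (may coincide).
#' @param radius_um interaction radius in um, default 20.
#' @return list: observed, expected, diff, null_sd, p, n_perm; or a flagged
#'   undefined result when either population is empty.
#' @export
cross_pcf <- function(cells, region_id, pop_a, pop_b, radius_um = 20,
                      n_perm = 300, seed = NULL, perm_fun = NULL) {
  v <- region_view(cells, region_id)
  pops <- sort(unique(v$population))
  if (!pop_a %in% pops || !pop_b %in% pops) {
    warning("empty population; cross-PCF undefined")
    return(list(observed = NA_real_, expected = NA_real_, diff = NA_real_,
                null_sd = NA_real_, p = NA_real_, flag = "empty_population"))
  }
  lab <- as.integer(factor(v$population, levels = pops))
  ia <- match(pop_a, pops); ib <- match(pop_b, pops)
  D <- as.matrix(dist(cbind(v$x, v$y)))
  hit <- which(D <= radius_um & upper.tri(D), arr.ind = TRUE)
  lm <- label_matrix(lab, n_perm,
                     derive_seed(seed, region_id, "cross_pcf"), perm_fun)
  count_pairs <- function(l) {
    if (ia == ib) sum(l[hit[, 1]] == ia & l[hit[, 2]] == ia)
    else sum((l[hit[, 1]] == ia & l[hit[, 2]] == ib) |
               (l[hit[, 1]] == ib & l[hit[, 2]] == ia))
  }
  norm_for <- function(l) {
    na <- sum(l == ia)
    if (ia == ib) na * (na - 1) / 2 else na * sum(l == ib)
  }
  stat <- vapply(seq_len(ncol(lm)), function(p) {
    np <- norm_for(lm[, p])
    if (np == 0) NA_real_ else count_pairs(lm[, p]) / np
  }, 0)
  observed <- stat[1L]
  nulls <- stat[-1L]
  p_hi <- (1 + sum(nulls >= observed, na.rm = TRUE)) / (n_perm + 1)
  p_lo <- (1 + sum(nulls <= observed, na.rm = TRUE)) / (n_perm + 1)
  list(observed = observed, expected = mean(nulls, na.rm = TRUE),
       diff = observed - mean(nulls, na.rm = TRUE),
       null_sd = sd(nulls, na.rm = TRUE),
       p = min(1, 2 * min(p_hi, p_lo)), n_perm = n_perm)
}

#' Vascular distance classes
#'
#' Classifies every non-vascular cell of a region by the distance to its
#' nearest vascular cell: \code{vascular} when at most \code{near_um} away
#' (default 0, i.e. coincident/contact), \code{perivascular} when within
#' \code{(near_um, far_um]} (default 10 um), and \code{infiltrated} beyond
#' that. The per-population infiltration rate (fraction infiltrated) is
#' attached as an attribute.
#'
#' @param cells a \code{cell_table}.
#' @param region_id region to classify.
#' @param vascular_pop label of the vascular population.
#' @param near_um,far_um class thresholds in um, \code{0 <= near_um <
#'   far_um}; defaults 0 and 10.
#' @return data.frame: cell_id, population, distance_to_vessel,
#'   vascular_class; attribute \code{"infiltration_rate"} is the per-
#'   population fraction of infiltrated cells. If the region has no
#'   vascular cells, distances are \code{NA} and classification is skipped
#'   with a warning.
#' @export
vascular_classes <- function(cells, region_id, vascular_pop,
                             near_um = 0, far_um = 10) {
  stopifnot(near_um >= 0, near_um < far_um)
  v <- region_view(cells, region_id)
  vas <- v$population == vascular_pop
  out <- data.frame(cell_id = v$cell_id[!vas],
                    population = v$population[!vas],
                    distance_to_vessel = NA_real_,
                    vascular_class = NA_character_)
  if (!any(vas)) {
    warning("region '", region_id, "' has no vascular cells; ",
            "classification skipped")
    return(out)
  }
  vx <- v$x[vas]; vy <- v$y[vas]
  qx <- v$x[!vas]; qy <- v$y[!vas]
  d <- vapply(seq_along(qx),
              function(i) sqrt(min((vx - qx[i])^2 + (vy - qy[i])^2)), 0)
  cls <- ifelse(d <= near_um, "vascular",
                ifelse(d <= far_um, "perivascular", "infiltrated"))
  out$distance_to_vessel <- d
  out$vascular_class <- cls
  rate <- tapply(cls == "infiltrated", out$population, mean)
  attr(out, "infiltration_rate") <- rate
  out
}
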