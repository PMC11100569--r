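#' Population placement specification
#'
#' Describes how one synthetic population is laid out in a region:
#' complete spatial randomness (\code{csr}), a Thomas cluster process
#' (\code{thomas}: Poisson parents with Gaussian-dispersed offspring),
#' placement decaying with distance from the vascular skeleton
#' (\code{vessel}), or placement biased towards high values of the hypoxia
#' field (\code{hypoxia}).
#'
#' @param label population name.
#' @param n expected cell count.
#' @param placement one of \code{"csr"}, \code{"thomas"}, \code{"vessel"},
#'   \code{"hypoxia"}.
#' @param sigma Thomas offspring dispersion (um), default 30.
#' @param mu Thomas mean offspring per parent, default 25.
#' @param decay vessel-distance decay length (um), default 25.
#' @param weight hypoxia bias weight (placement probability proportional to
#'   \code{exp(weight * hypoxia)}), default 3.
#' @return a \code{pop_spec} list.
#' @export
pop_spec <- function(label, n, placement = c("csr", "thomas", "vessel",
                                             "hypoxia"),
                     sigma = 30, mu = 25, decay = 25, weight = 3) {
  placement <- match.arg(placement)
  stopifnot(n > 0, sigma > 0, mu > 0, decay > 0)
  structure(list(label = label, n = n, placement = placement, sigma = sigma,
                 mu = mu, decay = decay, weight = weight),
            class = "pop_spec")
}

default_populations <- function() {
  list(pop_spec("Mg", 350, "thomas"),
       pop_spec("TAM-Mac", 300, "thomas"),
       pop_spec("TAM-Supp", 150, "vessel"),
       pop_spec("Tumor", 500, "csr"))
}

# min distance from points (px, py) to a set of segments (matrix with
# columns x0, y0, x1, y1)
segment_distance <- function(px, py, segs) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    x0 <- segs[i, 1]; y0 <- segs[i, 2]
    dx <- segs[i, 3] - x0; dy <- segs[i, 4] - y0
    L2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
    d <- pmin(d, sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2))
  }
  d
}

# low-pass noise field: coarse white noise bilinearly upsampled
smooth_noise <- function(nr, nc, step_px = 50) {
  C <- matrix(rnorm(max(2, ceiling(nr / step_px) + 1) *
                      max(2, ceiling(nc / step_px) + 1)),
              max(2, ceiling(nr / step_px) + 1))
  rows_at <- seq(1, nrow(C), length.out = nr)
  cols_at <- seq(1, ncol(C), length.out = nc)
  tmp <- apply(C, 2, function(cl) approx(seq_len(nrow(C)), cl, rows_at)$y)
  t(apply(tmp, 1, function(rw) approx(seq_len(ncol(C)), rw, cols_at)$y))
}

# nearest-pixel raster lookup at um coordinates
raster_at <- function(grid, scale, x, y) {
  j <- pmin(ncol(grid), pmax(1L, as.integer(ceiling(x / scale))))
  i <- pmin(nrow(grid), pmax(1L, as.integer(ceiling(y / scale))))
  grid[cbind(i, j)]
}

#' Simulate one labeled tissue region
#'
#' Generates a synthetic region with the statistical structure the analysis
#' assumes: a vascular skeleton of random line segments carrying vascular
#' cells, a hypoxia field rising with distance from vessels (plus smooth
#' noise), a fibrinogen field concentrated in a perivascular halo with leak
#' blobs at a subset of vessels, and cell populations placed per their
#' \code{\link{pop_spec}}. Marker intensities are population archetypes
#' plus Gaussian noise truncated at zero. A fixed seed reproduces the
#' output bitwise.
#'
#' @param region_id,case_id,region_class identifiers for the region.
#' @param width,height region extent in um.
#' @param populations list of \code{\link{pop_spec}}s.
#' @param vessels list: \code{n_segments}, segment \code{length} (um),
#'   \code{lumen} half-width (um), \code{cell_spacing} of vascular cells
#'   along segments, \code{leak_fraction} of segments flagged as leaky.
#' @param hypoxia list: \code{amplitude}, \code{length_scale} (um),
#'   \code{noise_sd} (all in normalized intensity units).
#' @param fibrinogen list: \code{halo} (um), \code{amplitude},
#'   \code{leak_amplitude}, \code{leak_sd} (um).
#' @param archetypes optional populations x markers intensity matrix;
#'   default gives each population its own high marker (4 vs 0.2
#'   background).
#' @param marker_noise_sd Gaussian marker noise SD (counts scale),
#'   default 0.5.
#' @param raster_scale um per raster pixel, default 1.
#' @param vascular_label label given to vessel-skeleton cells.
#' @param seed RNG seed.
#' @return list: \code{cells} (a \code{cell_table}), \code{rasters} (named
#'   list of \code{marker_raster}s: hypoxia, fibrinogen), \code{vessels}
#'   (segment matrix with leak flags).
#' @export
simulate_region <- function(region_id = "R1", case_id = "C1",
                            region_class = "core",
                            width = 1000, height = 1000,
                            populations = default_populations(),
                            vessels = list(), hypoxia = list(),
                            fibrinogen = list(), archetypes = NULL,
                            marker_noise_sd = 0.5, raster_scale = 1,
                            vascular_label = "Vascular", seed = NULL) {
  vessels <- utils::modifyList(list(n_segments = 4, length = 400, lumen = 8,
                                    cell_spacing = 15, leak_fraction = 0.5),
                               vessels)
  hypoxia <- utils::modifyList(list(amplitude = 1, length_scale = 150,
                                    noise_sd = 0.05), hypoxia)
  fibrinogen <- utils::modifyList(list(halo = 10, amplitude = 1,
                                       leak_amplitude = 1.5, leak_sd = 25),
                                  fibrinogen)
  if (sum(vapply(populations, `[[`, 0, "n")) <= 0)
    stop("expected cell count is zero")
  with_seed(derive_seed(seed, region_id, "simulate_region") %||% NULL, {
    ## vascular skeleton
    ns <- vessels$n_segments
    segs <- NULL
    if (ns > 0) {
      x0 <- runif(ns, 0.1 * width, 0.9 * width)
      y0 <- runif(ns, 0.1 * height, 0.9 * height)
      ang <- runif(ns, 0, 2 * pi)
      x1 <- pmin(width, pmax(0, x0 + vessels$length * cos(ang)))
      y1 <- pmin(height, pmax(0, y0 + vessels$length * sin(ang)))
      segs <- cbind(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                    leak = as.numeric(runif(ns) < vessels$leak_fraction))
    }
    ## rasters
    nr <- as.integer(ceiling(height / raster_scale))
    nc <- as.integer(ceiling(width / raster_scale))
    cx <- (seq_len(nc) - 0.5) * raster_scale
    cy <- (seq_len(nr) - 0.5) * raster_scale
    px <- rep(cx, each = nr); py <- rep(cy, times = nc)
    dv <- if (is.null(segs)) rep(sqrt(width^2 + height^2), nr * nc)
    else segment_distance(px, py, segs)
    dvg <- matrix(dv, nr, nc)
    hyp <- hypoxia$amplitude *
      (1 - exp(-pmax(dvg - vessels$lumen, 0) / hypoxia$length_scale))
    if (hypoxia$noise_sd > 0)
      hyp <- hyp + hypoxia$noise_sd * smooth_noise(nr, nc)
    hyp <- pmax(hyp, 0)
    fbg <- fibrinogen$amplitude * exp(-dvg / fibrinogen$halo)
    if (!is.null(segs) && any(segs[, "leak"] > 0)) {
      for (i in which(segs[, "leak"] > 0)) {
        t0 <- runif(1)
        bx <- segs[i, "x0"] + t0 * (segs[i, "x1"] - segs[i, "x0"])
        by <- segs[i, "y0"] + t0 * (segs[i, "y1"] - segs[i, "y0"])
        fbg <- fbg + fibrinogen$leak_amplitude *
          exp(-((matrix(px, nr, nc) - bx)^2 + (matrix(py, nr, nc) - by)^2) /
                (2 * fibrinogen$leak_sd^2))
      }
    }
    fbg <- pmax(fbg, 0)
    ## cell placement
    place <- function(spec) {
      switch(spec$placement,
        csr = {
          N <- rpois(1, spec$n)
          cbind(runif(N, 0, width), runif(N, 0, height))
        },
        thomas = {
          npar <- rpois(1, spec$n / spec$mu)
          pts <- matrix(0, 0, 2)
          if (npar > 0) {
            parx <- runif(npar, 0, width); pary <- runif(npar, 0, height)
            for (q in seq_len(npar)) {
              m <- rpois(1, spec$mu)
              if (m == 0) next
              ox <- parx[q] + rnorm(m, sd = spec$sigma)
              oy <- pary[q] + rnorm(m, sd = spec$sigma)
              keep <- ox >= 0 & ox <= width & oy >= 0 & oy <= height
              pts <- rbind(pts, cbind(ox[keep], oy[keep]))
            }
          }
          pts
        },
        vessel = ,
        hypoxia = {
          M <- max(500L, 10L * as.integer(spec$n))
          qx <- runif(M, 0, width); qy <- runif(M, 0, height)
          w <- if (spec$placement == "vessel") {
            if (is.null(segs)) stop("vessel-biased placement needs vessels")
            exp(-segment_distance(qx, qy, segs) / spec$decay)
          } else exp(spec$weight * raster_at(hyp, raster_scale, qx, qy))
          N <- min(rpois(1, spec$n), M)
          idx <- sample.int(M, N, prob = w)
          cbind(qx[idx], qy[idx])
        })
    }
    xy <- lapply(populations, place)
    labels <- rep(vapply(populations, `[[`, "", "label"),
                  vapply(xy, nrow, 0L))
    xy <- do.call(rbind, xy)
    ## vascular cells along segments
    if (!is.null(segs)) {
      for (i in seq_len(nrow(segs))) {
        L <- sqrt((segs[i, "x1"] - segs[i, "x0"])^2 +
                    (segs[i, "y1"] - segs[i, "y0"])^2)
        nv <- max(2L, as.integer(floor(L / vessels$cell_spacing)))
        tt <- seq(0, 1, length.out = nv)
        vx <- segs[i, "x0"] + tt * (segs[i, "x1"] - segs[i, "x0"]) +
          rnorm(nv, sd = 2)
        vy <- segs[i, "y0"] + tt * (segs[i, "y1"] - segs[i, "y0"]) +
          rnorm(nv, sd = 2)
        keep <- vx >= 0 & vx <= width & vy >= 0 & vy <= height
        xy <- rbind(xy, cbind(vx[keep], vy[keep]))
        labels <- c(labels, rep(vascular_label, sum(keep)))
      }
    }
    n <- nrow(xy)
    if (n == 0L) stop("no cells generated")
    ## marker intensities from archetypes
    pops_all <- unique(labels)
    if (is.null(archetypes)) {
      mk <- paste0("M_", gsub("[^[:alnum:]]", "", pops_all))
      archetypes <- matrix(0.2, length(pops_all), length(mk),
                           dimnames = list(pops_all, mk))
      diag(archetypes) <- 4
    }
    A <- archetypes[labels, , drop = FALSE]
    noise <- matrix(rnorm(length(A), sd = marker_noise_sd), nrow(A))
    M <- pmax(A + noise, 0)
    df <- data.frame(cell_id = sprintf("%s_c%05d", region_id, seq_len(n)),
                     x = xy[, 1], y = xy[, 2], case_id = case_id,
                     region_id = region_id, region_class = region_class,
                     population = labels, check.names = FALSE)
    df <- cbind(df, as.data.frame(M))
    cells <- cell_table(df, markers = colnames(archetypes))
    list(cells = cells,
         rasters = list(
           hypoxia = marker_raster(hyp, "hypoxia", scale = raster_scale),
           fibrinogen = marker_raster(fbg, "fibrinogen",
                                      scale = raster_scale)),
         vessels = segs)
  })
}

#' Simulate a multi-case study
#'
#' Convenience wrapper producing a full synthetic study: \code{n_cases}
#' cases with \code{regions_per_case} regions each (odd region indices are
#' edge, even are core), sharing one population layout. Per-region seeds
#' are derived deterministically from the master seed.
#'
#' @param n_cases,regions_per_case study dimensions (defaults 2 and 3).
#' @param seed master seed.
#' @param ... passed on to \code{\link{simulate_region}}.
#' @return list: \code{cells} (all regions combined), \code{rasters} and
#'   \code{vessels} (named by region id).
#' @export
simulate_study <- function(n_cases = 2, regions_per_case = 3, seed = NULL,
                           ...) {
  out_cells <- list(); rasters <- list(); vess <- list()
  for (ci in seq_len(n_cases)) for (ri in seq_len(regions_per_case)) {
    rid <- sprintf("C%d_R%d", ci, ri)
    r <- simulate_region(region_id = rid, case_id = sprintf("C%d", ci),
                         region_class = if (ri %% 2 == 1) "edge" else "core",
                         seed = derive_seed(seed, rid, "study"), ...)
    out_cells[[rid]] <- as.data.frame(r$cells)
    rasters[[rid]] <- r$rasters
    vess[[rid]] <- r$vessels
  }
  all_cells <- do.call(rbind, out_cells)
  rownames(all_cells) <- NULL
  list(cells = cell_table(all_cells), rasters = rasters, vessels = vess)
}
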