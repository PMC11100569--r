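# Small programmatic fixtures and independent brute-force oracles.

# minimal hand-laid table: 2 regions of one case, 2 populations
tiny_cells <- function() {
  cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:8),
    x = c(0, 3, 1, 10, 0, 5, 2, 8),
    y = c(0, 4, 0, 0, 0, 0, 2, 6),
    case_id = "case1",
    region_id = rep(c("r1", "r2"), each = 4),
    region_class = rep(c("edge", "core"), each = 4),
    population = c("A", "B", "A", "B", "A", "A", "B", "B"),
    CD68 = c(0, 50, 100, 25, 10, 20, 30, 40),
    P2RY12 = c(5, 5, 5, 5, 1, 2, 3, 4)))
}

# uniformly labeled CSR point pattern in one region
csr_cells <- function(n = 200, npop = 2, width = 500, seed = 1,
                      region_id = "r1", region_class = "edge",
                      case_id = "case1") {
  set.seed(seed)
  cell_table(data.frame(
    cell_id = sprintf("%s_c%04d", region_id, seq_len(n)),
    x = runif(n, 0, width), y = runif(n, 0, width),
    case_id = case_id, region_id = region_id,
    region_class = region_class,
    population = sample(LETTERS[seq_len(npop)], n, replace = TRUE)))
}

# two far-separated monotypic Thomas-style blobs (A around one center,
# B around another)
segregated_cells <- function(n_each = 80, seed = 1) {
  set.seed(seed)
  mk <- function(cx, cy, pop, off) data.frame(
    cell_id = sprintf("c%04d", off + seq_len(n_each)),
    x = rnorm(n_each, cx, 15), y = rnorm(n_each, cy, 15),
    case_id = "case1", region_id = "r1", region_class = "core",
    population = pop)
  cell_table(rbind(mk(100, 100, "A", 0), mk(500, 500, "B", n_each)))
}

# --- oracles -------------------------------------------------------------

# mean local clustering of the induced subgraph, by exhaustive triple
# enumeration on an igraph graph
bf_population_clustering <- function(graph, population) {
  keep <- which(igraph::V(graph)$population == population)
  sub <- igraph::induced_subgraph(graph, keep)
  A <- as.matrix(igraph::as_adjacency_matrix(sub))
  n <- nrow(A)
  if (n == 0) return(NA_real_)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, 0)
  mean(vals)
}

# Newman nominal assortativity from an explicit edge-list tally
bf_assortativity <- function(graph) {
  lab <- igraph::V(graph)$population
  e <- igraph::as_edgelist(graph, names = FALSE)
  pops <- sort(unique(lab))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (r in seq_len(nrow(e))) {
    a <- lab[e[r, 1]]; b <- lab[e[r, 2]]
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m <- m / sum(m)
  ai <- rowSums(m)
  (sum(diag(m)) - sum(ai^2)) / (1 - sum(ai^2))
}

# Rao quadratic entropy by direct double sum over the neighbourhood
bf_rao <- function(M) {
  m <- nrow(M)
  q <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    q <- q + sqrt(sum((M[i, ] - M[j, ])^2)) / m^2
  q
}

# windowed raster mean by brute-force pixel scan (pixel-center rule)
bf_window_mean <- function(raster, x, y, window_um, shape = "square") {
  g <- raster$grid; s <- raster$scale
  ox <- raster$origin[1]; oy <- raster$origin[2]
  h <- window_um / 2
  vals <- c()
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    cx <- ox + (j - 0.5) * s; cy <- oy + (i - 0.5) * s
    inside <- if (shape == "square")
      abs(cx - x) <= h && abs(cy - y) <= h
    else (cx - x)^2 + (cy - y)^2 <= h^2
    if (inside) vals <- c(vals, g[i, j])
  }
  if (length(vals)) mean(vals) else NA_real_
}

# exact two-sided one-sample signed-rank p by full sign enumeration
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, 0)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  p
}

# exact hypergeometric upper tail by combinatorial enumeration
bf_hyper_tail <- function(overlap, set_size, universe, n_sel) {
  j <- overlap:min(set_size, n_sel)
  sum(choose(set_size, j) * choose(universe - set_size, n_sel - j)) /
    choose(universe, n_sel)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
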