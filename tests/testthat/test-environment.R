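norm_cells <- function(n = 30, seed = 1, width = 60) {
  set.seed(seed)
  cell_table(data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    x = runif(n, 0, width), y = runif(n, 0, width),
    case_id = "k", region_id = "r", region_class = "core",
    population = sample(c("A", "B"), n, replace = TRUE),
    m1 = runif(n), m2 = runif(n), m3 = runif(n)))
}

test_that("Rao entropy: zero on identical phenotypes, closed form at m = 2,
           brute-force double sum in general", {
  ct <- norm_cells(10, seed = 2, width = 20)
  ct$m1 <- 0.5; ct$m2 <- 0.5; ct$m3 <- 0.5
  g <- build_graph(ct, "r", "contact", contact_radius = 30)
  q <- rao_entropy(ct, g)
  expect_true(all(q < 1e-12))

  # two-cell neighbourhood: Q = d / 2
  two <- cell_table(data.frame(
    cell_id = c("u", "v"), x = c(0, 5), y = 0, case_id = "k",
    region_id = "r", region_class = "core", population = "A",
    m1 = c(0.2, 0.8), m2 = c(0.1, 0.5)))
  g2 <- build_graph(two, "r", "contact", contact_radius = 10)
  d <- sqrt(0.6^2 + 0.4^2)
  q2 <- rao_entropy(two, g2)
  expect_equal(unname(q2), rep(d / 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # random neighbourhoods vs direct pairwise enumeration
  ct3 <- norm_cells(25, seed = 5, width = 40)
  g3 <- build_graph(ct3, "r", "contact", contact_radius = 15)
  q3 <- rao_entropy(ct3, g3)
  adj <- igraph::as_adj_list(g3, mode = "all")
  M <- as.matrix(as.data.frame(ct3)[match(igraph::V(g3)$name, ct3$cell_id),
                                    c("m1", "m2", "m3")])
  for (i in seq_along(q3)) {
    nb <- as.integer(adj[[i]])
    if (!length(nb)) next
    expect_equal(unname(q3[i]), bf_rao(M[c(i, nb), , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # bounded by the max pairwise phenotype distance
  expect_true(all(q3 <= max(dist(M)) + 1e-12))
})

test_that("isolated cells get zero entropy with a flag", {
  ct <- cell_table(data.frame(
    cell_id = c("a", "b", "c"), x = c(0, 5, 100), y = 0, case_id = "k",
    region_id = "r", region_class = "core", population = "A",
    m1 = c(0.1, 0.9, 0.4)))
  g <- build_graph(ct, "r", "contact", contact_radius = 10)
  q <- rao_entropy(ct, g)
  expect_equal(unname(q["c"]), 0)
  expect_equal(attr(q, "isolated"), "c")
})

test_that("window means: constant raster, corner clipping, hot pixel,
           brute-force scans", {
  ct <- cell_table(data.frame(
    cell_id = c("mid", "corner"), x = c(50, 1), y = c(50, 1),
    case_id = "k", region_id = "r", region_class = "core",
    population = "A"))
  r_const <- marker_raster(matrix(3.5, 100, 100), "c")
  w <- window_expression(ct, r_const, 40)
  expect_equal(unname(w), c(3.5, 3.5), ignore_attr = TRUE)

  # hot pixel: 40x40 window at 1 um/px holds 1600 pixels
  gmat <- matrix(0, 100, 100)
  gmat[50, 50] <- 800
  r_hot <- marker_raster(gmat, "h")
  w2 <- window_expression(ct, r_hot, 40)
  expect_equal(unname(w2["mid"]), 800 / 1600)

  # corner window is clipped to in-bounds pixels only
  gmat2 <- matrix(runif(100 * 100), 100, 100)
  r3 <- marker_raster(gmat2, "x")
  w3 <- window_expression(ct, r3, 40)
  expect_equal(unname(w3["corner"]),
               bf_window_mean(r3, 1, 1, 40), tolerance = 1e-12)

  # random cells, square and disc, vs brute-force pixel scan
  set.seed(8)
  ct4 <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:6), x = runif(6, 0, 60),
    y = runif(6, 0, 60), case_id = "k", region_id = "r",
    region_class = "core", population = "A"))
  r4 <- marker_raster(matrix(runif(60 * 60), 60, 60), "y")
  for (shape in c("square", "disc")) {
    got <- window_expression(ct4, r4, 25, shape = shape)
    for (i in 1:6)
      expect_equal(unname(got[i]),
                   bf_window_mean(r4, ct4$x[i], ct4$y[i], 25, shape),
                   tolerance = 1e-12)
  }
})

test_that("windows holding no pixel center are flagged undefined", {
  ct <- cell_table(data.frame(
    cell_id = "far", x = 500, y = 500, case_id = "k", region_id = "r",
    region_class = "core", population = "A"))
  r <- marker_raster(matrix(1, 10, 10), "z")
  expect_warning(w <- window_expression(ct, r, 4), "no pixel center")
  expect_true(is.na(w))
  expect_equal(attr(w, "empty"), "far")
})

test_that("cross-PCF flags empty populations and centers on CSR", {
  ct <- csr_cells(n = 400, npop = 2, seed = 21)
  expect_warning(r0 <- cross_pcf(ct, "r1", "A", "Z", n_perm = 10, seed = 1))
  expect_equal(r0$flag, "empty_population")

  r <- cross_pcf(ct, "r1", "A", "B", radius_um = 20, n_perm = 200, seed = 3)
  expect_lt(abs(r$diff), 4 * r$null_sd)
  expect_gt(r$p, 0.01)
})

test_that("co-clustered populations give positive diff with small p", {
  set.seed(12)
  centers <- cbind(runif(6, 50, 450), runif(6, 50, 450))
  mk <- function(pop, off) {
    idx <- sample(6, 120, replace = TRUE)
    data.frame(cell_id = sprintf("c%04d", off + 1:120),
               x = centers[idx, 1] + rnorm(120, sd = 10),
               y = centers[idx, 2] + rnorm(120, sd = 10),
               case_id = "k", region_id = "r", region_class = "core",
               population = pop)
  }
  # CSR background makes the A/B co-clustering detectable: without it the
  # two labels are exchangeable and the permutation null reproduces the data
  bg <- data.frame(cell_id = sprintf("c%04d", 240 + 1:300),
                   x = runif(300, 0, 500), y = runif(300, 0, 500),
                   case_id = "k", region_id = "r", region_class = "core",
                   population = "C")
  ct <- cell_table(rbind(mk("A", 0), mk("B", 120), bg))
  r <- cross_pcf(ct, "r", "A", "B", radius_um = 20, n_perm = 300, seed = 4)
  expect_gt(r$diff, 0)
  expect_lte(r$p, 0.01)

  # sign agreement with the distance-enrichment diff (co-clustering:
  # closer than chance, so distance diff negative while pair diff positive)
  de <- distance_enrichment(ct, "r", n_perm = 100, seed = 4)
  expect_lt(de$diff["A", "B"], 0)
})

test_that("vascular classes follow the distance thresholds exactly", {
  ct <- cell_table(data.frame(
    cell_id = c("v1", "at", "peri", "far"),
    x = c(0, 0, 6, 15), y = 0, case_id = "k", region_id = "r",
    region_class = "core",
    population = c("Vascular", "T", "T", "T")))
  vc <- vascular_classes(ct, "r", "Vascular", near_um = 0, far_um = 10)
  got <- setNames(vc$vascular_class, vc$cell_id)
  expect_equal(got[["at"]], "vascular")      # coincident with a vessel cell
  expect_equal(got[["peri"]], "perivascular")
  expect_equal(got[["far"]], "infiltrated")  # 15 um > 10 um threshold
  expect_equal(unname(attr(vc, "infiltration_rate")["T"]), 1 / 3)

  # mixed region: per-class counts equal brute-force thresholding
  ct2 <- csr_cells(n = 120, npop = 3, seed = 31, width = 200)
  ct2$population[ct2$population == "C"] <- "Vascular"
  attr(ct2, "populations") <- sort(unique(ct2$population))
  vc2 <- vascular_classes(ct2, "r1", "Vascular", far_um = 10)
  v <- ct2[order(ct2$cell_id), ]
  vas <- v$population == "Vascular"
  d_bf <- vapply(which(!vas), function(i)
    sqrt(min((v$x[vas] - v$x[i])^2 + (v$y[vas] - v$y[i])^2)), 0)
  expect_equal(sum(vc2$vascular_class == "infiltrated"), sum(d_bf > 10))
  expect_equal(sum(vc2$vascular_class == "perivascular"),
               sum(d_bf > 0 & d_bf <= 10))
  # class proportions sum to one over classified cells
  expect_equal(sum(table(vc2$vascular_class)) , nrow(vc2))

  ct3 <- csr_cells(n = 10, seed = 2)
  expect_warning(vc3 <- vascular_classes(ct3, "r1", "Vascular"),
                 "no vascular cells")
  expect_true(all(is.na(vc3$vascular_class)))
})

test_that("Holm-Sidak follows the closed-form ladder and handles ties", {
  p <- c(0.02, 0.02, 0.02, 0.02)
  # identical raw p: every adjusted value is 1 - (1 - p)^k
  expect_equal(p_adjust_holm_sidak(p), rep(1 - (1 - 0.02)^4, 4),
               tolerance = 1e-12)
  p2 <- c(0.01, 0.4, 0.03, NA)
  adj <- p_adjust_holm_sidak(p2)
  expect_equal(adj[1], 1 - (1 - 0.01)^3, tolerance = 1e-12)
  expect_equal(adj[3], max(1 - (1 - 0.03)^2, adj[1]), tolerance = 1e-12)
  expect_true(is.na(adj[4]))
  expect_true(all(diff(sort(adj[!is.na(adj)])) >= 0))
})

test_that("nested comparison recovers a planted population shift", {
  sim_study_values <- function(shift, seed) {
    set.seed(seed)
    rows <- list()
    for (ca in 1:6) for (re in 1:3) {
      base <- rnorm(1, sd = 0.3) + rnorm(1, sd = 0.2)
      for (pop in c("P", "Q")) {
        v <- base + (pop == "Q") * shift + rnorm(25)
        rows[[length(rows) + 1]] <- data.frame(
          case_id = paste0("c", ca), region_id = paste0("r", re),
          population = pop, value = v)
      }
    }
    do.call(rbind, rows)
  }
  d <- sim_study_values(1.0, 42)
  res <- nested_compare(d, "value", "population")
  expect_equal(nrow(res$contrasts), 1)
  expect_lt(res$contrasts$p_adj, 0.05)
  expect_equal(res$contrasts$estimate, 1.0, tolerance = 0.25)

  d0 <- sim_study_values(0, 43)
  res0 <- nested_compare(d0, "value", "population")
  expect_gt(res0$contrasts$p_adj, 0.05)
})

test_that("nested comparison degrades gracefully with one region per case", {
  set.seed(3)
  d <- data.frame(case_id = rep(paste0("c", 1:4), each = 40),
                  region_id = "r1",
                  population = rep(c("P", "Q"), 80),
                  value = rnorm(160))
  res <- nested_compare(d, "value", "population")
  expect_true("case_only" %in% res$flags)
  expect_equal(nrow(res$contrasts), 1)
})
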