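make_spots <- function(counts, npop = 2, pitch = 100) {
  n <- nrow(counts)
  side <- ceiling(sqrt(n))
  rows_full <- rep(seq_len(side) - 1L, each = side)
  cols_full <- rep(seq_len(side) - 1L, times = side) - rows_full %/% 2L
  rows <- rows_full[seq_len(n)]
  cols <- cols_full[seq_len(n)]
  ids <- sprintf("s%03d", seq_len(n))
  rownames(counts) <- ids
  ab <- matrix(runif(n * npop), n, npop,
               dimnames = list(ids, paste0("P", seq_len(npop))))
  spot_dataset(counts,
               data.frame(spot_id = ids, col = cols, row = rows),
               ab, pitch = pitch)
}

test_that("spot QC applies the strict count threshold and mito prefixes", {
  set.seed(1)
  counts <- matrix(rpois(12 * 6, 300), 12, 6)
  colnames(counts) <- c("GAPDH", "MT-CO1", "ACTB", "MT-ND1", "VIM", "CD68")
  counts[1, ] <- c(999, 0, 0, 0, 0, 0)     # exactly 999 total: dropped
  counts[2, ] <- c(1000, 0, 0, 0, 0, 0)    # exactly 1000: retained
  sp <- make_spots(counts)
  q <- qc_normalize(sp, min_counts = 1000, mito_prefixes = "MT-")
  expect_false("s001" %in% rownames(q$counts))
  expect_true("s002" %in% rownames(q$counts))
  expect_false(any(c("MT-CO1", "MT-ND1") %in% colnames(q$counts)))
  expect_true(all(rowSums(q$counts) + rowSums(sp$counts[rownames(q$counts),
                                                        c("MT-CO1", "MT-ND1")]) >= 1000))
})

test_that("library-size normalization is scale-invariant and monotone", {
  counts <- rbind(c(100, 200, 700), c(300, 600, 2100), c(500, 100, 900))
  colnames(counts) <- c("g1", "g2", "g3")
  sp <- make_spots(counts)
  q <- qc_normalize(sp, min_counts = 0)
  # proportional spots end up identical after normalization
  expect_equal(q$norm["s001", ], q$norm["s002", ], tolerance = 1e-12)
  # within a spot, normalized values are a monotone transform of counts
  expect_equal(order(q$norm["s003", ]), order(counts[3, ]))
  expect_true(all(q$norm >= 0))
})

test_that("hypergeometric scores equal the enumeration oracle", {
  # universe of 20 genes; spot's top-5 set fixed by construction
  set.seed(2)
  genes <- sprintf("g%02d", 1:20)
  counts <- matrix(rpois(3 * 20, 50), 3, 20, dimnames = list(NULL, genes))
  counts[1, ] <- c(rep(1000, 5), rep(10, 15))  # top 5 = g01..g05
  sp <- make_spots(counts)
  q <- qc_normalize(sp, min_counts = 0)
  gene_set <- c("g01", "g02", "g03", "g18")    # overlap 3 of set 4
  sc <- score_signature(q, gene_set, top_fraction = 0.25)
  p_oracle <- bf_hyper_tail(3, 4, 20, 5)
  expect_equal(unname(sc["s001"]), -log10(p_oracle), tolerance = 1e-9)
  expect_true(all(sc >= 0))

  expect_error(score_signature(q, c("zz1", "zz2"), name = "missing"),
               "missing")
})

test_that("larger overlap at fixed margins never lowers the score", {
  ps <- vapply(0:4, function(ov) bf_hyper_tail(ov, 4, 20, 5), 0)
  expect_true(all(diff(-log10(ps)) >= 0))
})

test_that("factor screen: linearity, SD filter, closed-form r", {
  set.seed(5)
  ab <- matrix(runif(8 * 2), 8, 2, dimnames = list(NULL, c("P1", "P2")))
  fac <- cbind(lin = 2 * ab[, 1] + 1,
               flat = rep(0.5, 8) + rnorm(8, sd = 0.001),
               noise = rnorm(8))
  res <- correlate_factors(ab, fac, min_factor_sd = 0.05)
  expect_equal(attr(res, "dropped_factors"), "flat")
  expect_equal(res$r[res$factor == "lin" & res$population == "P1"], 1,
               tolerance = 1e-9)
  # closed-form covariance ratio on a small table
  r_hand <- sum((fac[, "noise"] - mean(fac[, "noise"])) *
                  (ab[, 2] - mean(ab[, 2]))) /
    sqrt(sum((fac[, "noise"] - mean(fac[, "noise"]))^2) *
           sum((ab[, 2] - mean(ab[, 2]))^2))
  expect_equal(res$r[res$factor == "noise" & res$population == "P2"],
               r_hand, tolerance = 1e-12)
  # BH over all tests in the screen
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("environment clustering standardizes, renumbers by size, and is
           stable under duplication and row shuffles", {
  set.seed(7)
  arch <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  ab <- arch[sample(1:3, 90, replace = TRUE, prob = c(0.5, 0.3, 0.2)), ] +
    matrix(rnorm(270, sd = 0.5), 90)
  lab <- cluster_environments(ab, k = 3, seed = 11)
  # standardization check
  z <- scale(ab)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  # labels renumbered in descending cluster size
  expect_true(all(diff(as.integer(table(lab))) <= 0))
  # duplicated spots always co-labeled
  ab2 <- rbind(ab, ab)
  lab2 <- cluster_environments(ab2, k = 3, seed = 11)
  expect_equal(lab2[1:90], lab2[91:180], ignore_attr = TRUE)
  # planted archetypes recovered
  expect_error(cluster_environments(ab[1:2, ], k = 3), "exceeds")
})

test_that("hex connectivity: single environment, interior degree 6,
           half-plane border oracle", {
  # 10x10 axial patch
  rows <- rep(0:9, each = 10)
  cols <- rep(0:9, times = 10) - rows %/% 2
  coords <- data.frame(spot_id = sprintf("s%03d", 1:100),
                       col = cols, row = rows)
  one <- environment_connectivity(coords, labels = rep(1, 100))
  expect_equal(unname(one), matrix(1), ignore_attr = TRUE)

  # interior spot has exactly six neighbours
  e <- gliospat:::hex_edges(coords)
  deg <- tabulate(c(e[, 1], e[, 2]), 100)
  inner <- which(rows %in% 3:6 & (cols + rows %/% 2) %in% 3:6)
  expect_true(all(deg[inner] == 6))

  # two half-plane environments: off-diagonal endpoints = border edges
  lab <- ifelse(rows < 5, 1, 2)
  m <- environment_connectivity(coords, labels = lab)
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-9)
  cross <- sum(lab[e[, 1]] != lab[e[, 2]])
  ends1 <- sum(lab[e[, 1]] == 1) + sum(lab[e[, 2]] == 1)
  expect_equal(m[1, 2], cross / ends1, tolerance = 1e-12)
})

test_that("non-myeloid gene filter matches a direct SD recomputation", {
  sig <- rbind(A = c(1, 1, 0.5, 2), B = c(1, 1.05, 0.5, 0.1),
               C = c(1, 0.95, 0.5, 4))
  colnames(sig) <- c("flat", "mild", "const", "marker")
  r <- nonmyeloid_signature(sig, sd_threshold = 0.1)
  expect_true(all(c("flat", "const", "mild") %in% r$retained))
  expect_equal(r$excluded, "marker")

  set.seed(9)
  sig2 <- matrix(runif(5 * 100, 0, 0.6), 5,
                 dimnames = list(NULL, sprintf("g%03d", 1:100)))
  r2 <- nonmyeloid_signature(sig2, 0.1)
  expect_setequal(r2$retained,
                  colnames(sig2)[apply(sig2, 2, sd) <= 0.1])
  expect_equal(r2$n_excluded, sum(apply(sig2, 2, sd) > 0.1))
})

test_that("environment markers apply the p and fold gates", {
  set.seed(13)
  n <- 120
  counts <- matrix(rpois(n * 30, 40), n, 30,
                   dimnames = list(NULL, sprintf("g%02d", 1:30)))
  env <- rep(1:3, each = 40)
  counts[env == 1, "g01"] <- rpois(40, 400)   # exclusive marker of env 1
  sp <- make_spots(counts)
  sp$environment <- env
  q <- qc_normalize(sp, min_counts = 0)
  q$environment <- env
  mk <- environment_markers(q, p_max = 0.01, min_fold = 1.5)
  expect_true("g01" %in% mk[["1"]]$gene)
  expect_false("g01" %in% mk[["2"]]$gene)
  # strong p but sub-threshold fold is rejected
  counts2 <- counts
  counts2[env == 1, "g02"] <- rpois(40, 52)   # ~1.3-fold, highly significant
  sp2 <- make_spots(counts2)
  q2 <- qc_normalize(sp2, min_counts = 0)
  q2$environment <- env
  mk2 <- environment_markers(q2, p_max = 0.5, min_fold = 1.5)
  expect_false("g02" %in% mk2[["1"]]$gene)

  q3 <- q
  q3$environment <- c(rep(1, 2), rep(2, n - 2))
  expect_warning(environment_markers(q3), "< 3 spots")
})

test_that("null data yield marker lists near the nominal false-positive
           budget", {
  set.seed(17)
  counts <- matrix(rnbinom(300 * 150, mu = 30, size = 2), 300, 150,
                   dimnames = list(NULL, sprintf("g%03d", 1:150)))
  sp <- make_spots(counts)
  q <- qc_normalize(sp, min_counts = 0)
  q$environment <- rep(1:5, each = 60)
  mk <- environment_markers(q, p_max = 0.01, min_fold = 1.0)
  expect_lte(mean(lengths(lapply(mk, `[[`, "gene"))), 0.01 * 150 * 2)
})

test_that("survival association: median split, constant covariates,
           preconditions", {
  co <- simulate_cohort(n = 100, betas = c(0.05, 0), censor_frac = 0,
                        seed = 5)
  res <- survival_association(co)
  expect_equal(res$n_high, res$n_low, tolerance = 1)  # even split, no ties
  expect_equal(res$p_adj, p_adjust_holm_sidak(res$p))

  co$env_3 <- 0.5
  res2 <- survival_association(co, env_cols = c("env_1", "env_2", "env_3"))
  expect_equal(res2$flag[3], "constant_covariate")
  expect_true(is.na(res2$coef[3]))

  expect_error(survival_association(co[1:10, ]), ">= 20 samples")
})
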