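#' Construct a hex-grid spot dataset
#'
#' Container for spot-level spatial transcriptomics: a spots-by-genes count
#' matrix, axial hexagonal coordinates, and per-spot cell-population
#' abundances (deconvolution output, treated as an input). Axial
#' coordinates \code{(col, row)} define the 6-neighbour adjacency; centers
#' in um are derived from the grid pitch.
#'
#' @param counts non-negative integer matrix, spots x genes, with spot ids
#'   as rownames and gene names as colnames.
#' @param coords data.frame with columns \code{spot_id}, \code{col},
#'   \code{row} (axial), matching the count matrix rows.
#' @param abundances non-negative matrix, spots x populations.
#' @param pitch center-to-center spot distance in um, default 100.
#' @return an object of class \code{spot_dataset} with fields
#'   \code{counts}, \code{coords} (including um centers \code{x}, \code{y}),
#'   \code{abundances}, \code{norm} (NULL until \code{\link{qc_normalize}}),
#'   and \code{environment} (NULL until \code{\link{cluster_environments}}).
#' @export
spot_dataset <- function(counts, coords, abundances, pitch = 100) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(all(c("spot_id", "col", "row") %in% names(coords)))
  coords$spot_id <- as.character(coords$spot_id)
  if (!identical(rownames(counts), coords$spot_id))
    stop("count matrix rownames must match coords$spot_id in order")
  abundances <- as.matrix(abundances)
  if (!identical(rownames(abundances), coords$spot_id))
    stop("abundance rownames must match coords$spot_id in order")
  if (any(!is.finite(abundances)) || any(abundances < 0))
    stop("abundances must be finite and >= 0")
  coords$x <- pitch * (coords$col + coords$row / 2)
  coords$y <- pitch * sqrt(3) / 2 * coords$row
  structure(list(counts = counts, coords = coords, abundances = abundances,
                 norm = NULL, environment = NULL, pitch = pitch),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes, %d populations%s%s\n",
              nrow(x$counts), ncol(x$counts), ncol(x$abundances),
              if (is.null(x$norm)) "" else ", normalized",
              if (is.null(x$environment)) "" else
                sprintf(", %d environments", length(unique(x$environment)))))
  invisible(x)
}

subset_spots <- function(spots, keep) {
  spots$counts <- spots$counts[keep, , drop = FALSE]
  spots$coords <- spots$coords[keep, , drop = FALSE]
  spots$abundances <- spots$abundances[keep, , drop = FALSE]
  if (!is.null(spots$norm)) spots$norm <- spots$norm[keep, , drop = FALSE]
  if (!is.null(spots$environment))
    spots$environment <- spots$environment[keep]
  spots
}

#' Spot quality control and normalization
#'
#' Drops low-quality spots (raw total counts strictly below
#' \code{min_counts}, default 1000) and mitochondrial genes (name prefix
#' match, default \code{"MT-"}), then library-size-normalizes each
#' remaining spot to the median pre-scaling total and applies
#' \code{log(1 + x)}.
#'
#' @param spots a \code{spot_dataset} with raw counts.
#' @param min_counts minimum total counts per spot, default 1000.
#' @param mito_prefixes character vector of gene-name prefixes to drop.
#' @return the filtered dataset with its \code{norm} matrix filled in and
#'   attributes \code{"dropped_spots"} / \code{"dropped_genes"}.
#' @export
qc_normalize <- function(spots, min_counts = 1000, mito_prefixes = "MT-") {
  stopifnot(inherits(spots, "spot_dataset"))
  tot <- rowSums(spots$counts)
  keep <- tot >= min_counts
  if (!any(keep)) stop("all spots fail the count threshold")
  dropped <- rownames(spots$counts)[!keep]
  spots <- subset_spots(spots, keep)
  pat <- paste0("^(", paste(gsub("([^[:alnum:]])", "\\\\\\1", mito_prefixes),
                            collapse = "|"), ")")
  mito <- grepl(pat, colnames(spots$counts))
  gene_dropped <- colnames(spots$counts)[mito]
  spots$counts <- spots$counts[, !mito, drop = FALSE]
  tot2 <- rowSums(spots$counts)
  target <- median(tot2)
  spots$norm <- log1p(spots$counts / tot2 * target)
  attr(spots, "dropped_spots") <- dropped
  attr(spots, "dropped_genes") <- gene_dropped
  spots
}

#' Hypergeometric signature score per spot
#'
#' For each spot the \code{top_fraction} most highly expressed genes (ties
#' broken by gene name) form its selected set; the score is
#' \eqn{-\log_{10}} of the hypergeometric upper-tail probability of the
#' observed overlap between the selected set and the signature gene set,
#' with the universe being all retained genes.
#'
#' @param spots a normalized \code{spot_dataset}.
#' @param gene_set character vector of signature genes.
#' @param top_fraction fraction of genes selected per spot, default 0.05.
#' @param name signature name used in error messages.
#' @return named numeric vector of per-spot scores (>= 0).
#' @export
score_signature <- function(spots, gene_set, top_fraction = 0.05,
                            name = "signature") {
  if (is.null(spots$norm)) stop("run qc_normalize() first")
  genes <- colnames(spots$norm)
  set <- intersect(gene_set, genes)
  if (!length(set)) stop("gene set '", name,
                         "' has no genes in the dataset universe")
  G <- length(genes)
  K <- length(set)
  n_sel <- max(1L, ceiling(top_fraction * G))
  scores <- apply(spots$norm, 1, function(e) {
    sel <- genes[order(-e, genes)][seq_len(n_sel)]
    ov <- length(intersect(sel, set))
    p <- phyper(ov - 1, K, G - K, n_sel, lower.tail = FALSE)
    -log10(p)
  })
  setNames(scores, rownames(spots$norm))
}

#' Abundance-factor correlation screen
#'
#' Pearson correlation of each explanatory factor (a gene, signature score,
#' or pathway activity per spot) against each population abundance across
#' spots. Factors whose standard deviation falls below \code{min_factor_sd}
#' (default 0.05) are removed before testing; p-values are
#' Benjamini-Hochberg adjusted over every test in the screen.
#'
#' @param abundances spots x populations matrix.
#' @param factors spots x factors matrix (same row order).
#' @param min_factor_sd variability threshold for factor inclusion.
#' @return data.frame: factor, population, r, p, p_adj, flag; attribute
#'   \code{"dropped_factors"} lists the excluded factors.
#' @export
correlate_factors <- function(abundances, factors, min_factor_sd = 0.05) {
  abundances <- as.matrix(abundances); factors <- as.matrix(factors)
  stopifnot(nrow(abundances) == nrow(factors))
  sds <- apply(factors, 2, sd)
  dropped <- colnames(factors)[sds < min_factor_sd]
  factors <- factors[, sds >= min_factor_sd, drop = FALSE]
  if (ncol(factors) == 0L) {
    out <- data.frame(factor = character(0), population = character(0),
                      r = numeric(0), p = numeric(0), p_adj = numeric(0),
                      flag = character(0))
    attr(out, "dropped_factors") <- dropped
    return(out)
  }
  grid <- expand.grid(factor = colnames(factors),
                      population = colnames(abundances),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- factors[, grid$factor[i]]
    y <- abundances[, grid$population[i]]
    if (sd(y) == 0)
      return(data.frame(r = NA_real_, p = NA_real_, flag = "constant_abundance"))
    ct <- cor.test(x, y, method = "pearson")
    data.frame(r = unname(ct$estimate), p = ct$p.value, flag = "")
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_adj <- p.adjust(out$p, method = "BH")
  attr(out, "dropped_factors") <- dropped
  out
}

#' Cluster spots into myeloid environments
#'
#' Standardizes each population abundance to zero mean and unit variance
#' across spots and partitions the spots by k-means (default k = 5, 25
#' restarts under a fixed seed). Cluster labels are renumbered in
#' descending cluster size so the labeling is deterministic.
#'
#' @param spots a \code{spot_dataset}, or a spots x populations abundance
#'   matrix.
#' @param k number of environments, default 5.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of random restarts, default 25.
#' @param batch accepted for interface compatibility and ignored (single
#'   synthetic batch), with a warning when non-NULL.
#' @return for a matrix input, an integer label vector (1 = largest
#'   environment); for a \code{spot_dataset}, the dataset with
#'   \code{environment} filled in.
#' @export
cluster_environments <- function(spots, k = 5, seed = NULL, nstart = 25,
                                 batch = NULL) {
  if (!is.null(batch)) warning("batch field ignored (single batch)")
  ab <- if (inherits(spots, "spot_dataset")) spots$abundances else as.matrix(spots)
  if (k > nrow(ab)) stop("k exceeds the number of spots")
  stopifnot(k >= 2)
  z <- scale(ab)
  z[, attr(z, "scaled:scale") == 0] <- 0
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart,
                               iter.max = 100))
  sizes <- tabulate(km$cluster, k)
  relab <- match(seq_len(k), order(-sizes, seq_len(k)))
  lab <- relab[km$cluster]
  if (inherits(spots, "spot_dataset")) {
    spots$environment <- setNames(lab, rownames(ab))
    spots
  } else setNames(lab, rownames(ab))
}

# axial hex neighbour offsets (col, row)
hex_offsets <- cbind(c(1, -1, 0, 0, 1, -1), c(0, 0, 1, -1, -1, 1))

hex_edges <- function(coords) {
  key <- paste(coords$col, coords$row)
  idx <- seq_len(nrow(coords))
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(hex_offsets))) {
    nb <- match(paste(coords$col + hex_offsets[o, 1],
                      coords$row + hex_offsets[o, 2]), key)
    ok <- !is.na(nb)
    from <- c(from, idx[ok]); to <- c(to, nb[ok])
  }
  keep <- from < to   # each undirected adjacency once
  cbind(from[keep], to[keep])
}

#' Connectivity between myeloid environments
#'
#' Connects each spot to its (at most) six surrounding hex neighbours and
#' reports, for each environment pair \code{(e, f)}, the fraction of
#' environment-e spot-edge endpoints adjacent to environment-f spots. Rows
#' sum to 1; diagonal dominance indicates spatially contiguous
#' environments.
#'
#' @param spots a \code{spot_dataset} with environments assigned, or a
#'   coords data.frame (with \code{col}, \code{row}) plus \code{labels}.
#' @param labels environment labels, required for the data.frame form.
#' @return environment x environment proportion matrix; attribute
#'   \code{"n_unassigned"} counts excluded spots.
#' @export
environment_connectivity <- function(spots, labels = NULL) {
  if (inherits(spots, "spot_dataset")) {
    coords <- spots$coords
    labels <- labels %||% spots$environment
  } else coords <- spots
  if (is.null(labels)) stop("environments not assigned")
  assigned <- !is.na(labels)
  n_un <- sum(!assigned)
  coords <- coords[assigned, , drop = FALSE]
  labels <- labels[assigned]
  e <- hex_edges(coords)
  if (nrow(e) == 0L) stop("no hex adjacencies among assigned spots")
  envs <- sort(unique(labels))
  lab <- as.integer(factor(labels, levels = envs))
  prop <- endpoint_proportions(e[, 1], e[, 2], lab, length(envs))
  dimnames(prop) <- list(envs, envs)
  attr(prop, "n_unassigned") <- n_un
  prop
}

#' Filter genes to a non-myeloid signature set
#'
#' Removes genes that vary between the myeloid reference populations
#' (standard deviation across population columns above
#' \code{sd_threshold}, default 0.1 on the counts scale), leaving genes
#' whose spot-level variation must come from non-myeloid cells.
#'
#' @param signatures populations x genes reference matrix (counts scale).
#' @param sd_threshold exclusion threshold, default 0.1.
#' @return list: \code{retained} gene names, \code{excluded} gene names,
#'   \code{n_excluded}.
#' @export
nonmyeloid_signature <- function(signatures, sd_threshold = 0.1) {
  signatures <- as.matrix(signatures)
  if (!length(signatures)) stop("empty signature matrix")
  sds <- apply(signatures, 2, sd)
  list(retained = colnames(signatures)[sds <= sd_threshold],
       excluded = colnames(signatures)[sds > sd_threshold],
       n_excluded = sum(sds > sd_threshold))
}

#' Environment marker genes (one-vs-rest DEGs)
#'
#' For each environment, Wilcoxon rank-sum tests of each gene's normalized
#' expression in that environment's spots against all other spots; genes
#' with raw \code{p < p_max} (default 0.01) and fold change at least
#' \code{min_fold} (default 1.5, computed on \code{expm1}-backtransformed
#' means with a small pseudocount) are kept and ranked by p-value.
#'
#' @param spots a normalized \code{spot_dataset} with environments.
#' @param gene_subset genes eligible for testing (typically the
#'   \code{\link{nonmyeloid_signature}} retained set).
#' @param p_max raw p-value ceiling, default 0.01.
#' @param min_fold minimum fold enrichment, default 1.5.
#' @return named list (one element per environment) of data.frames: gene,
#'   p, fold; environments with fewer than 3 spots are skipped with a
#'   warning.
#' @export
environment_markers <- function(spots, gene_subset = NULL, p_max = 0.01,
                                min_fold = 1.5) {
  if (is.null(spots$norm)) stop("run qc_normalize() first")
  if (is.null(spots$environment)) stop("environments not assigned")
  genes <- intersect(gene_subset %||% colnames(spots$norm),
                     colnames(spots$norm))
  X <- spots$norm[, genes, drop = FALSE]
  env <- spots$environment
  eps <- 1e-9
  out <- list()
  for (e in sort(unique(env))) {
    inn <- env == e
    if (sum(inn) < 3L) {
      warning("environment ", e, " has < 3 spots; skipped")
      out[[as.character(e)]] <- data.frame(gene = character(0),
                                           p = numeric(0), fold = numeric(0))
      next
    }
    p <- vapply(genes, function(g)
      suppressWarnings(wilcox.test(X[inn, g], X[!inn, g],
                                   exact = FALSE)$p.value), 0)
    fold <- vapply(genes, function(g)
      (mean(expm1(X[inn, g])) + eps) / (mean(expm1(X[!inn, g])) + eps), 0)
    keep <- !is.na(p) & p < p_max & fold >= min_fold
    d <- data.frame(gene = genes[keep], p = p[keep], fold = fold[keep])
    out[[as.character(e)]] <- d[order(d$p), , drop = FALSE]
  }
  out
}
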