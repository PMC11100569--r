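default_mixtures <- function() {
  pops <- c("Mg-Ho", "Mg-like", "TAM-Mg", "TAM-Mac", "TAM-Supp", "TAM-Int")
  m <- rbind(c(8,   6,   4,   0.5, 0.5, 1),
             c(1.5, 1.5, 1.5, 0.2, 0.2, 0.2),
             c(0.5, 0.5, 1,   8,   6,   1),
             c(0.2, 0.2, 0.2, 1.5, 1.5, 1.5),
             c(1,   0.5, 6,   1,   1,   8))
  dimnames(m) <- list(paste0("env", seq_len(nrow(m))), pops)
  m
}

#' Simulate a hex-grid spot dataset with planted myeloid environments
#'
#' Builds a rectangular patch of axial hex spots, partitions it into
#' \code{k_env} contiguous environment domains (Voronoi cells of randomly
#' chosen seed spots), assigns each spot its environment's myeloid
#' population mixture plus Gaussian noise, and assembles gene counts as
#' negative-binomial draws around population signatures weighted by
#' abundance, plus environment-specific boosts on planted non-myeloid
#' marker genes, scaled to a log-normal library size.
#'
#' The gene panel is: per-population myeloid marker genes (variable across
#' the reference populations, hence removed by
#' \code{\link{nonmyeloid_signature}}), constant non-myeloid genes of which
#' the first \code{k_env * degs_per_env} are planted environment markers at
#' \code{deg_fold}, and a few mitochondrial (\code{MT-}) genes exercising
#' QC.
#'
#' @param n_col,n_row hex grid dimensions, defaults 20 x 20 (400 spots).
#' @param mixtures environments x populations abundance archetypes;
#'   default 5 environments x 6 myeloid populations.
#' @param pitch spot center distance in um, default 100.
#' @param abundance_noise_sd abundance noise SD; default 0.1 times the
#'   largest archetype value.
#' @param myeloid_genes_per_pop marker genes per myeloid population
#'   (default 10).
#' @param n_nonmyeloid non-myeloid gene count (default 60).
#' @param degs_per_env planted marker genes per environment (default 8).
#' @param deg_fold planted fold enrichment (> 1, default 3).
#' @param nonmyeloid_mass non-myeloid cell mass per spot in abundance
#'   units (default 10).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size
#'   parameters, defaults \code{log(2500)} and 0.4.
#' @param dispersion negative-binomial dispersion (0 = Poisson),
#'   default 0.5.
#' @param seed RNG seed.
#' @return list: \code{spots} (a \code{\link{spot_dataset}}) and
#'   \code{truth} (planted \code{environment} labels, per-environment
#'   \code{degs}, myeloid reference \code{signatures}, \code{mixtures}).
#' @export
simulate_spots <- function(n_col = 20, n_row = 20, mixtures = NULL,
                           pitch = 100, abundance_noise_sd = NULL,
                           myeloid_genes_per_pop = 10, n_nonmyeloid = 60,
                           degs_per_env = 8, deg_fold = 3,
                           nonmyeloid_mass = 10,
                           libsize_meanlog = log(2500),
                           libsize_sdlog = 0.4, dispersion = 0.5,
                           seed = NULL) {
  mixtures <- mixtures %||% default_mixtures()
  if (any(mixtures < 0) || any(rowSums(mixtures) == 0))
    stop("degenerate mixture")
  stopifnot(deg_fold > 1)
  k_env <- nrow(mixtures)
  pops <- colnames(mixtures)
  abundance_noise_sd <- abundance_noise_sd %||% (0.1 * max(mixtures))
  with_seed(derive_seed(seed, "simulate_spots"), {
    ## hex patch, axial coordinates
    rows <- rep(seq_len(n_row) - 1L, each = n_col)
    cols <- rep(seq_len(n_col) - 1L, times = n_row) - rows %/% 2L
    coords <- data.frame(spot_id = sprintf("s%04d", seq_along(rows)),
                         col = cols, row = rows)
    cx <- pitch * (coords$col + coords$row / 2)
    cy <- pitch * sqrt(3) / 2 * coords$row
    ## contiguous environment domains: Voronoi of k_env seed spots
    ctr <- sample.int(nrow(coords), k_env)
    d2 <- vapply(ctr, function(s) (cx - cx[s])^2 + (cy - cy[s])^2,
                 numeric(nrow(coords)))
    env <- max.col(-d2)
    ## abundances
    ab <- mixtures[env, , drop = FALSE] +
      matrix(rnorm(length(env) * length(pops), sd = abundance_noise_sd),
             ncol = length(pops))
    ab <- pmax(ab, 0)
    dimnames(ab) <- list(coords$spot_id, pops)
    ## gene panel and myeloid reference signatures
    my_genes <- unlist(lapply(pops, function(p)
      sprintf("MY-%s-%02d", gsub("[^[:alnum:]]", "", p),
              seq_len(myeloid_genes_per_pop))))
    nm_genes <- sprintf("NM-%03d", seq_len(n_nonmyeloid))
    mt_genes <- c("MT-CO1", "MT-ND1", "MT-CYB")
    genes <- c(my_genes, nm_genes, mt_genes)
    sig <- matrix(0.1, length(pops), length(genes),
                  dimnames = list(pops, genes))
    for (pi in seq_along(pops)) {
      own <- sprintf("MY-%s-%02d", gsub("[^[:alnum:]]", "", pops[pi]),
                     seq_len(myeloid_genes_per_pop))
      sig[pi, own] <- 3
    }
    sig[, nm_genes] <- 0.3   # constant across myeloid populations
    sig[, mt_genes] <- 0.5
    ## planted environment DEGs among the non-myeloid genes
    if (k_env * degs_per_env > n_nonmyeloid)
      stop("not enough non-myeloid genes for the requested DEGs")
    degs <- split(nm_genes[seq_len(k_env * degs_per_env)],
                  rep(seq_len(k_env), each = degs_per_env))
    names(degs) <- rownames(mixtures)
    ## expected expression and counts
    mu <- ab %*% sig
    mu[, nm_genes] <- mu[, nm_genes] + nonmyeloid_mass * 0.3
    mu[, mt_genes] <- mu[, mt_genes] + nonmyeloid_mass * 0.5
    for (e in seq_len(k_env)) {
      sel <- env == e
      mu[sel, degs[[e]]] <- mu[sel, degs[[e]]] * deg_fold
    }
    lib <- rlnorm(nrow(mu), libsize_meanlog, libsize_sdlog)
    mu <- mu / rowSums(mu) * lib
    counts <- if (dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow(mu))
    else matrix(rpois(length(mu), mu), nrow(mu))
    dimnames(counts) <- dimnames(mu)
    spots <- spot_dataset(counts, coords, ab, pitch = pitch)
    list(spots = spots,
         truth = list(environment = setNames(env, coords$spot_id),
                      degs = degs, signatures = sig, mixtures = mixtures,
                      library_size = setNames(lib, coords$spot_id)))
  })
}

#' Simulate a survival cohort with planted environment effects
#'
#' Environment proportions are drawn per sample from a symmetric Dirichlet
#' distribution (so they are non-negative and sum to 1). Event times are
#' exponential with rate \eqn{\lambda_0 \exp(\sum_k \beta_k \cdot 100
#' p_k)}, i.e. \code{betas} are log hazard ratios per percentage point of
#' environment abundance. Censoring is independent uniform on
#' \code{(0, c_max)} with \code{c_max} calibrated to the requested
#' censoring fraction.
#'
#' @param n number of samples (default 400).
#' @param betas per-environment log-HR per percentage point; default one
#'   harmful environment at +0.05 among five.
#' @param censor_frac target censoring fraction in \code{[0, 1)},
#'   default 0.2.
#' @param baseline_rate exponential baseline hazard per month; default
#'   gives a 14-month median at zero covariates.
#' @param alpha symmetric Dirichlet concentration, default 1.
#' @param seed RNG seed.
#' @return data.frame: sample_id, env_1..env_k proportions, time (months),
#'   event; planted parameters in the \code{"truth"} attribute.
#' @export
simulate_cohort <- function(n = 400, betas = c(0.05, 0, 0, 0, 0),
                            censor_frac = 0.2,
                            baseline_rate = log(2) / 14, alpha = 1,
                            seed = NULL) {
  stopifnot(n >= 1, censor_frac >= 0, censor_frac < 1)
  k <- length(betas)
  with_seed(derive_seed(seed, "simulate_cohort"), {
    g <- matrix(rgamma(n * k, shape = alpha), n, k)
    props <- g / rowSums(g)
    colnames(props) <- paste0("env_", seq_len(k))
    lp <- as.vector(props %*% (betas * 100))
    t_event <- rexp(n, rate = baseline_rate * exp(lp))
    if (censor_frac > 0) {
      f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_frac
      cmax <- uniroot(f, c(min(t_event) * 1e-3, max(t_event) * 1e3))$root
      cens <- runif(n, 0, cmax)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    out <- data.frame(sample_id = sprintf("case%04d", seq_len(n)), props,
                      time = time, event = event)
    attr(out, "truth") <- list(betas = betas, censor_frac = censor_frac,
                               baseline_rate = baseline_rate)
    out
  })
}
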