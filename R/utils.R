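`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm-Sidak step-down adjustment
#'
#' Family-wise step-down correction: with the \eqn{m} raw p-values sorted
#' increasingly, the \eqn{i}-th is adjusted to
#' \eqn{1 - (1 - p_{(i)})^{m - i + 1}}, then monotonicity is enforced by a
#' running maximum and values are capped at 1. \code{NA}s are left in place
#' and do not count towards the family size.
#'
#' @param p numeric vector of raw p-values in \code{[0, 1]} (NAs allowed).
#' @return adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out[ok[o]] <- adj
  out
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a master seed plus string context,
# so each region x statistic gets its own reproducible permutation stream.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  txt <- paste(c(...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

# seq_len over rows of matching matrix entries, used in long-format reshapes
mat_to_long <- function(m, dimnames_ab = c("pop_i", "pop_j"),
                        value_name = "value") {
  d <- expand.grid(a = rownames(m), b = colnames(m),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d[[value_name]] <- as.vector(m)
  names(d)[1:2] <- dimnames_ab
  d
}
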