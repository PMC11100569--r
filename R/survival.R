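#' Survival association of environment proportions
#'
#' Fits one univariate Cox proportional-hazards model per myeloid
#' environment: hazard on that environment's proportion, expressed per
#' percentage point of abundance. P-values are Holm-Sidak adjusted across
#' the environments. For each environment a Kaplan-Meier comparison of
#' high (top 50%, i.e. above the median proportion; or above the mean with
#' \code{split = "mean"}) versus low samples is run with a log-rank test.
#'
#' @param cohort data.frame with survival time (months), event indicator
#'   (0/1), and one column per environment proportion.
#' @param env_cols names of the proportion columns; default every column
#'   starting with \code{"env"}.
#' @param time_col,event_col column names, defaults \code{time} and
#'   \code{event}.
#' @param split \code{"median"} (default) or \code{"mean"} high/low rule.
#' @param scale \code{"fraction"} (default; proportions in \code{[0, 1]}
#'   are multiplied by 100) or \code{"percent"} (used as given).
#' @return data.frame with one row per environment: log-hazard coefficient
#'   per percentage point, hazard ratio, se, z, p, Holm-Sidak p_adj,
#'   log-rank \code{km_p}, high/low group sizes, and a flag (constant
#'   covariates and non-convergence are flagged, not dropped silently).
#'   The fitted \code{coxph}/\code{survfit} objects are attached as the
#'   \code{"fits"} attribute.
#' @export
survival_association <- function(cohort, env_cols = NULL, time_col = "time",
                                 event_col = "event",
                                 split = c("median", "mean"),
                                 scale = c("fraction", "percent")) {
  split <- match.arg(split)
  scale <- match.arg(scale)
  env_cols <- env_cols %||% grep("^env", names(cohort), value = TRUE)
  stopifnot(length(env_cols) >= 1,
            all(c(time_col, event_col) %in% names(cohort)))
  if (any(is.na(cohort[[time_col]])) || any(cohort[[time_col]] <= 0))
    stop("survival times must be positive and non-missing")
  if (nrow(cohort) < 20 || sum(cohort[[event_col]]) < 5)
    stop("need >= 20 samples and >= 5 events")
  srv <- survival::Surv(cohort[[time_col]], cohort[[event_col]])
  fits <- list()
  rows <- lapply(env_cols, function(ec) {
    x <- cohort[[ec]]
    if (scale == "fraction") x <- 100 * x
    if (sd(x) == 0)
      return(data.frame(environment = ec, coef = NA_real_, hr = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        km_p = NA_real_, n_high = NA_integer_,
                        n_low = NA_integer_, flag = "constant_covariate"))
    fit <- tryCatch(survival::coxph(srv ~ x), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit))
      return(data.frame(environment = ec, coef = NA_real_, hr = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        km_p = NA_real_, n_high = NA_integer_,
                        n_low = NA_integer_, flag = "non_convergence"))
    s <- summary(fit)$coefficients
    thr <- if (split == "median") median(x) else mean(x)
    grp <- factor(ifelse(x > thr, "high", "low"), levels = c("low", "high"))
    km_p <- NA_real_
    if (nlevels(droplevels(grp)) == 2L) {
      sd_ <- survival::survdiff(srv ~ grp)
      km_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
    }
    fits[[ec]] <<- list(cox = fit,
                        km = survival::survfit(srv ~ grp))
    data.frame(environment = ec, coef = s[1, "coef"],
               hr = s[1, "exp(coef)"], se = s[1, "se(coef)"],
               z = s[1, "z"], p = s[1, "Pr(>|z|)"], km_p = km_p,
               n_high = sum(grp == "high"), n_low = sum(grp == "low"),
               flag = "")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p_adjust_holm_sidak(out$p)
  out <- out[c("environment", "coef", "hr", "se", "z", "p", "p_adj",
               "km_p", "n_high", "n_low", "flag")]
  attr(out, "fits") <- fits
  rownames(out) <- NULL
  out
}
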