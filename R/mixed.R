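#' Nested mixed-model comparison of per-cell environment values
#'
#' Compares a per-cell quantity (e.g. windowed hypoxia marker expression or
#' quadratic entropy) between levels of a factor (population, or
#' edge-vs-core region class) while respecting the sampling hierarchy:
#' cells are nested within regions, which are nested within cases. The
#' model is a linear mixed model with random intercepts for case and
#' region-within-case, fitted by REML via \pkg{lmerTest} (Satterthwaite
#' denominator degrees of freedom). The reported family of contrasts is
#' each factor level against the reference (first) level, adjusted by
#' Holm-Sidak.
#'
#' When every case contributes a single region the region term is dropped
#' (flag \code{case_only}); when the fit fails to converge the function
#' falls back to Wilcoxon rank-sum tests on region means (flag
#' \code{wilcoxon_fallback}).
#'
#' @param data data.frame with one row per cell.
#' @param value name of the numeric response column.
#' @param factor_col name of the factor column to compare (>= 2 levels).
#' @param case_col,region_col grouping columns; defaults \code{case_id},
#'   \code{region_id}.
#' @return list with \code{contrasts} (data.frame: level, reference,
#'   estimate, se, df, statistic, p, p_adj), \code{model}, and
#'   \code{flags}.
#' @export
nested_compare <- function(data, value, factor_col, case_col = "case_id",
                           region_col = "region_id") {
  data <- as.data.frame(data)
  stopifnot(all(c(value, factor_col, case_col, region_col) %in% names(data)))
  data$.y <- data[[value]]
  data$.f <- factor(data[[factor_col]])
  data$.case <- factor(data[[case_col]])
  data$.region <- factor(paste(data[[case_col]], data[[region_col]], sep = ":"))
  if (nlevels(data$.f) < 2L) stop("factor needs >= 2 levels")
  if (nlevels(data$.case) < 2L) stop("need >= 2 cases")
  flags <- character(0)
  one_region <- all(tapply(data$.region, data$.case,
                           function(r) length(unique(r))) == 1L)
  form <- if (one_region) .y ~ .f + (1 | .case)
  else .y ~ .f + (1 | .case) + (1 | .region)
  if (one_region) flags <- c(flags, "case_only")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = data)),
    error = function(e) NULL, warning = function(w) NULL)
  lv <- levels(data$.f)
  if (!is.null(fit)) {
    if (lme4::isSingular(fit, tol = 1e-5)) flags <- c(flags, "singular_fit")
    cf <- coef(summary(fit))
    rows <- paste0(".f", lv[-1])
    ctr <- data.frame(level = lv[-1], reference = lv[1],
                      estimate = cf[rows, "Estimate"],
                      se = cf[rows, "Std. Error"],
                      df = cf[rows, "df"],
                      statistic = cf[rows, "t value"],
                      p = cf[rows, "Pr(>|t|)"])
  } else {
    flags <- c(flags, "wilcoxon_fallback")
    rm_ <- aggregate(list(y = data$.y),
                     list(region = data$.region, f = data$.f), mean)
    ctr <- do.call(rbind, lapply(lv[-1], function(l) {
      a <- rm_$y[rm_$f == l]; b <- rm_$y[rm_$f == lv[1]]
      data.frame(level = l, reference = lv[1],
                 estimate = mean(a) - mean(b), se = NA_real_,
                 df = NA_real_, statistic = NA_real_,
                 p = suppressWarnings(wilcox.test(a, b)$p.value))
    }))
    fit <- NULL
  }
  ctr$p_adj <- p_adjust_holm_sidak(ctr$p)
  rownames(ctr) <- NULL
  list(contrasts = ctr, model = fit, flags = flags)
}
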