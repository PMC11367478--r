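#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and nA + nB - 2 degrees of freedom,
#' computable either from raw samples or from per-group summary statistics
#' (mean, sd, n) as printed in demographic tables.
#'
#' @param x,y raw samples for the two groups (alternative interface).
#' @param meanA,sdA,nA,meanB,sdB,nB per-group summary statistics.
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @examples
#' ttest_two_sample(meanA = 59.63, sdA = 11.80, nA = 62,
#'                  meanB = 59.59, sdB = 12.57, nB = 56)$t  # 0.018
#' @export
ttest_two_sample <- function(x = NULL, y = NULL,
                             meanA = NULL, sdA = NULL, nA = NULL,
                             meanB = NULL, sdB = NULL, nB = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2L || length(y) < 2L) stopf("both samples need n >= 2")
    meanA <- mean(x); sdA <- stats::sd(x); nA <- length(x)
    meanB <- mean(y); sdB <- stats::sd(y); nB <- length(y)
  }
  if (is.null(meanA) || is.null(sdA) || is.null(nA) ||
      is.null(meanB) || is.null(sdB) || is.null(nB)) {
    stopf("provide either raw samples (x, y) or full summary statistics")
  }
  if (nA < 2L || nB < 2L) stopf("both groups need n >= 2")
  if (sdA < 0 || sdB < 0) stopf("standard deviations must be >= 0")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  if (sp2 == 0) {
    t_stat <- if (meanA == meanB) 0 else sign(meanA - meanB) * Inf
  } else {
    t_stat <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), df) else 0
  if (t_stat == 0) p <- 1
  list(t = t_stat, df = df, p = p)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Chi-square statistic without continuity correction, 1 degree of freedom:
#' \code{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}.
#'
#' @param a,b,c,d cell counts of the 2 x 2 table (rows = groups,
#'   columns = categories).
#' @return list with \code{statistic}, \code{df = 1}, \code{p}.
#' @examples
#' chi_square_2x2(40, 22, 36, 20)$statistic  # ~0.001
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) stopf("counts must be nonnegative integers")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("a marginal of the 2 x 2 table is zero")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' GLM comparison of a measure between two groups with covariates
#'
#' Ordinary least squares of the measure on an intercept, a binary group
#' indicator and the covariates; reports the t statistic and two-sided p of
#' the group coefficient (residual degrees of freedom n - p). With no
#' covariates this reduces exactly to the pooled two-sample t-test. A
#' measure with zero variance yields t = 0, p = 1 with a warning rather
#' than aborting a whole family of tests.
#'
#' @param measure numeric vector of per-subject values.
#' @param group factor/character vector of group labels (exactly 2 levels
#'   after subsetting, first level is the reference).
#' @param covariates optional data.frame of per-subject covariates (e.g.
#'   age, sex, education, mean FD).
#' @param groups optional length-2 character vector selecting and ordering
#'   the two groups to compare; the t is for (second group - first group).
#' @return list with \code{t}, \code{p}, \code{df}, \code{estimate}.
#' @export
glm_group_compare <- function(measure, group, covariates = NULL, groups = NULL) {
  group <- as.character(group)
  if (is.null(groups)) {
    groups <- unique(group)
    if (length(groups) != 2L) stopf("need exactly 2 groups (got %d); use 'groups='",
                                    length(groups))
  }
  keep <- group %in% groups
  measure <- measure[keep]
  gi <- as.numeric(group[keep] == groups[2L])
  if (sum(gi == 0) < 3L || sum(gi == 1) < 3L) stopf("both groups need >= 3 subjects")
  design <- data.frame(gi = gi)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(keep)) {
      stopf("covariates have %d rows but there are %d subjects",
            nrow(covariates), length(keep))
    }
    covariates <- covariates[keep, , drop = FALSE]
    constant <- vapply(covariates, function(v) stats::var(as.numeric(v)) == 0,
                       logical(1L))
    if (any(constant)) {
      warnf("dropping constant covariate(s): %s",
            paste(names(covariates)[constant], collapse = ", "))
      covariates <- covariates[!constant]
    }
    if (ncol(covariates)) design <- cbind(design, covariates)
  }
  if (stats::var(measure) == 0) {
    warnf("measure has zero variance; returning t = 0, p = 1")
    return(list(t = 0, p = 1, df = length(measure) - ncol(design) - 1L, estimate = 0))
  }
  x <- stats::model.matrix(~ ., data = design)
  if (qr(x)$rank < ncol(x)) stopf("design matrix is rank deficient")
  fit <- stats::lm.fit(x, measure)
  df <- length(measure) - ncol(x)
  if (df < 1L) {
    stopf("no residual degrees of freedom: %d subjects for %d design columns",
          length(measure), ncol(x))
  }
  res_var <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(res_var * xtx_inv[2L, 2L])
  est <- fit$coefficients[["gi"]]
  t_stat <- if (se == 0) 0 else est / se
  p <- if (t_stat == 0 && se == 0) 1 else 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, p = p, df = df, estimate = est)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, applied within one
#' declared family of tests.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param family optional family identifier carried through as the
#'   \code{"family"} attribute of the result (e.g. "sfnc", "RF").
#' @return adjusted p-values (same length/order as \code{p}).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_bh <- function(p, family = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  out <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, both nonconstant).
#' @return list with \code{r}, \code{p} (two-sided, n - 2 df), \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stopf("need paired vectors with n >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
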