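#' Agreement statistics between two foci-counting methods
#'
#' Utilities for method-comparison of per-nucleus foci counts: Pearson
#' correlation, Lin's concordance correlation coefficient, linear and
#' linear-quadratic regression, and the relative-difference summary.
#' Regression direction matters and is not symmetric: by convention the
#' reference/automated counts go on the ordinate (\code{y}) and the
#' comparator on the abscissa (\code{x}).
#'
#' @name agreement
NULL

.checkPaired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired counts are required")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

#' @describeIn agreement product-moment correlation (errors on zero
#'   variance).
#' @param x,y equal-length vectors of per-nucleus counts from two methods.
#' @export
pearsonR <- function(x, y) {
  .checkPaired(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' @describeIn agreement Lin's concordance correlation coefficient,
#'   \code{2*sxy / (sx^2 + sy^2 + (mx - my)^2)} with population (1/n)
#'   moments; penalizes scatter and systematic offset alike, so
#'   \code{|ccc| <= |r|} always.
#' @export
concordanceCCC <- function(x, y) {
  .checkPaired(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' @describeIn agreement ordinary least squares of \code{y} on \code{x};
#'   degree 1 returns intercept/slope with the slope standard error, degree
#'   2 adds a quadratic term (the upward curvature seen when one method
#'   undercounts dense nuclei).
#' @param degree 1 (linear) or 2 (linear-quadratic).
#' @export
agreementFit <- function(x, y, degree = 1) {
  .checkPaired(x, y)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  fit <- if (degree == 1) stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(coefficients = unname(cf), slope = unname(cf[2]),
       slopeSE = unname(se[2]), degree = degree, fit = fit)
}

#' @describeIn agreement relative difference of a count against a reference
#'   count, \code{(fn - fnRef)/fnRef * 100} percent.
#' @param fn count from the compared method.
#' @param fnRef reference count (> 0).
#' @export
relDiff <- function(fn, fnRef) {
  if (any(fnRef <= 0)) stop("reference count must be positive")
  (fn - fnRef) / fnRef * 100
}

#' One-row agreement report
#'
#' @param x comparator counts (abscissa).
#' @param y reference counts (ordinate).
#' @param labels method names \code{c(x, y)}.
#' @return data.frame with \code{r}, \code{ccc}, \code{slope},
#'   \code{slopeSE} and the mean relative difference of \code{x} vs
#'   \code{y} (percent).
#' @export
agreementReport <- function(x, y, labels = c("comparator", "reference")) {
  f <- agreementFit(x, y, 1)
  data.frame(methodX = labels[1], methodY = labels[2],
             n = length(x), r = pearsonR(x, y), ccc = concordanceCCC(x, y),
             slope = f$slope, slopeSE = f$slopeSE,
             meanRelDiffPct = mean(relDiff(sum(x), sum(y))))
}
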