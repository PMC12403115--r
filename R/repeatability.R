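#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Quantifies how closely two parallel measurement series of the same units
#' agree in value (not merely in rank): the two-way, single-measure,
#' absolute-agreement intraclass correlation computed from the mean squares
#' of a units x measurements two-way ANOVA,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n units and k = 2 measurement columns. Unlike a Pearson or
#' consistency coefficient, a constant offset between the columns lowers
#' the value. The p value tests ICC = 0 with F = MS_R / MS_E on
#' (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @param x,y paired measurements of the same n >= 3 units (e.g. the same
#'   trees measured by two cameras, or the same visits counted from two
#'   traps). Missing cells are rejected.
#' @param variant `"agreement"` (default) or `"consistency"` (two-way
#'   consistency ICC, exposed for comparison; not the default because a
#'   systematic offset between instruments should count against them).
#' @return list of class `icc_result`: `r`, `p`, `n`, `model`.
#' @examples
#' set.seed(1)
#' a <- rnorm(25, 2, 0.5); b <- a + rnorm(25, 0, 0.2)
#' icc_absolute(a, b)
#' @export
icc_absolute <- function(x, y, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  if (length(x) != length(y))
    stop("paired measurements must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing cells are not allowed; supply complete pairs", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired units", call. = FALSE)
  if (stats::var(c(x, y)) <= 0)
    stop("zero total variance: ICC undefined for constant data", call. = FALSE)
  k <- 2L
  d <- data.frame(value = c(x, y),
                  unit = factor(rep(seq_len(n), 2L)),
                  meas = factor(rep(1:2, each = n)))
  # our own F test follows; suppress anova's perfect-fit grumbling
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ unit + meas, data = d))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  denom_a <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom_a) || denom_a <= 0)
    stop("zero total variance: ICC undefined for constant data", call. = FALSE)
  r <- if (variant == "agreement") (msr - mse) / denom_a
       else (msr - mse) / (msr + (k - 1) * mse)
  fv <- msr / mse
  p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(r = r, p = p, n = n,
                 model = sprintf("two-way, single measures, %s", variant)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): r = %.3f, p = %.3g, n = %d units\n",
              x$model, x$r, x$p, x$n))
  invisible(x)
}
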