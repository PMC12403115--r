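#' @keywords internal
"_PACKAGE"

#' Squeeze unit-interval values off the boundary
#'
#' Beta likelihoods are supported on the open interval (0,1); observed
#' proportions can sit exactly on the boundary. The standard remedy is the
#' compression y' = (y (n - 1) + 0.5) / n, where n is the number of points
#' in the series, which is applied immediately before any Beta fit so that
#' normalized series themselves keep their exact 0s and 1s.
#'
#' @param y numeric vector in [0, 1].
#' @param n number of observations backing the squeeze (default `length(y)`).
#' @return numeric vector in (0, 1).
#' @export
squeeze_unit <- function(y, n = length(y)) {
  stopifnot(is.numeric(y), all(is.finite(y)), all(y >= 0 & y <= 1), n >= 1)
  (y * (n - 1) + 0.5) / n
}

# round-half-up to nearest integer; documented convention for the
# gram -> centigram conversion (base round() would go half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# assert a scalar is a finite number; used by config validation
chk_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
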