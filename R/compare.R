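## Cross-metric and cross-trophic analysis layer: Spearman matrices,
## variance decomposition, predictive models, ELPD comparison, Moran's I.

# all permutations of 1..n as an n!-row matrix (insertion construction)
perm_matrix <- function(n) {
  P <- matrix(1L, 1, 1)
  if (n == 1) return(P)
  for (k in 2:n) {
    m <- nrow(P)
    Pk <- cbind(P, k)
    blocks <- vector("list", k)
    for (pos in 1:k) {
      cols <- if (pos == 1) c(k, 1:(k - 1))
              else if (pos == k) 1:k
              else c(1:(pos - 1), k, pos:(k - 1))
      blocks[[pos]] <- Pk[, cols, drop = FALSE]
    }
    P <- do.call(rbind, blocks)
  }
  P
}

# two-sided exact permutation p for Spearman's rho (average ranks for ties)
spearman_exact_p <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  ra_c <- ra - mean(ra); rb_c <- rb - mean(rb)
  den <- sqrt(sum(ra_c^2) * sum(rb_c^2))
  if (den == 0) return(NA_real_)
  obs <- sum(ra_c * rb_c) / den
  P <- perm_matrix(n)
  M <- matrix(rb_c[P], nrow = nrow(P))
  rho_perm <- drop(M %*% ra_c) / den
  mean(abs(rho_perm) >= abs(obs) - 1e-12)
}

#' Spearman correlation matrix over phenological metrics
#'
#' Pairwise-complete Spearman correlations between metric columns, with
#' average ranks for ties. Two-sided p values are exact (full permutation
#' enumeration) for n <= 9 pairs and use the t approximation otherwise;
#' each entry reports its own pairwise-complete n, since trees missing a
#' metric (e.g. no caterpillars caught) drop out pair by pair. A
#' Benjamini-Hochberg adjusted column is included for reference but raw p
#' values drive the default significance stars.
#'
#' @param metrics data.frame, one row per tree.
#' @param vars metric column names to correlate (>= 2).
#' @param min_n minimum pairwise-complete observations per pair (default 4);
#'   sparser pairs are returned with NA.
#' @return data.frame of class `spearman_matrix` with one row per unordered
#'   pair: `metric_a`, `metric_b`, `rho`, `p`, `p_adj`, `n`. The full
#'   symmetric matrix is available via `as.matrix()`.
#' @export
spearman_matrix <- function(metrics, vars, min_n = 4) {
  stopifnot(length(vars) >= 2, all(vars %in% names(metrics)))
  pairs <- utils::combn(vars, 2)
  out <- data.frame(metric_a = pairs[1, ], metric_b = pairs[2, ],
                    rho = NA_real_, p = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- metrics[[pairs[1, j]]]; b <- metrics[[pairs[2, j]]]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    out$n[j] <- n
    if (n < min_n) next
    a <- a[ok]; b <- b[ok]
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next  # all tied
    rho <- stats::cor(a, b, method = "spearman")
    out$rho[j] <- rho
    if (n <= 9) {
      out$p[j] <- spearman_exact_p(a, b)
    } else {
      tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
      out$p[j] <- 2 * stats::pt(-abs(tt), n - 2)
    }
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("metric_a", "metric_b", "rho", "p", "p_adj", "n")]
  attr(out, "vars") <- vars
  class(out) <- c("spearman_matrix", class(out))
  out
}

#' @export
as.matrix.spearman_matrix <- function(x, ...) {
  vars <- attr(x, "vars")
  M <- diag(1, length(vars))
  dimnames(M) <- list(vars, vars)
  for (j in seq_len(nrow(x))) {
    M[x$metric_a[j], x$metric_b[j]] <- M[x$metric_b[j], x$metric_a[j]] <- x$rho[j]
  }
  M
}

# R^2 as used throughout the model layer: variance of the model-implied
# mean over (that + residual variance); equals classical R^2 for lm
r2_fitted <- function(fitted, y) {
  vf <- stats::var(fitted); vr <- stats::var(y - fitted)
  if (vf + vr <= 0) return(NA_real_)
  vf / (vf + vr)
}

#' Change in explained variance when adding a factor
#'
#' Fits the response on the base predictors with and without an added
#' factor (same least-squares machinery as [fit_cross_trophic_model()])
#' and returns the gain in explained variance, with R^2 defined as
#' var(fitted) / (var(fitted) + var(residual)). This is how "species
#' explains X% of the variance beyond sampling area" style statements are
#' computed.
#'
#' @param response numeric response (metric values).
#' @param factor factor (or coercible) whose contribution is assessed;
#'   must have >= 2 levels present.
#' @param base optional data.frame of base predictors (e.g. sampling area).
#' @return list: `delta_r2`, `r2_full`, `r2_reduced`.
#' @export
variance_explained_delta <- function(response, factor, base = NULL) {
  factor <- droplevels(as.factor(factor))
  if (nlevels(factor) < 2)
    stop("added factor must have at least 2 levels present", call. = FALSE)
  df <- data.frame(.y = response)
  if (!is.null(base)) df <- cbind(df, base)
  ok <- stats::complete.cases(df) & !is.na(factor)
  df <- df[ok, , drop = FALSE]; factor <- factor[ok]
  f_red <- if (is.null(base)) .y ~ 1 else
    stats::reformulate(names(base), response = ".y")
  m_red <- stats::lm(f_red, data = df)
  df$.factor <- factor
  f_full <- stats::update(f_red, . ~ . + .factor)
  m_full <- stats::lm(f_full, data = df)
  if (m_full$rank < length(stats::coef(m_full)))
    stop("singular design: added factor is confounded with base predictors",
         call. = FALSE)
  r2f <- r2_fitted(stats::fitted(m_full), df$.y)
  r2r <- r2_fitted(stats::fitted(m_red), df$.y)
  list(delta_r2 = r2f - r2r, r2_full = r2f, r2_reduced = r2r)
}

# fold assignment: exhaustive LOO for small n, K-fold otherwise
make_folds <- function(n, K = 10, seed = NULL) {
  if (n <= 30) return(seq_len(n))
  if (!is.null(seed)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  sample(rep_len(seq_len(K), n))
}

# cross-validated log predictive density for an lm specification
elpd_gaussian <- function(df, formula, K = 10, seed = NULL) {
  n <- nrow(df)
  folds <- make_folds(n, K, seed)
  lpd <- numeric(n)
  for (f in unique(folds)) {
    test <- folds == f
    fit <- stats::lm(formula, data = df[!test, , drop = FALSE])
    mu <- stats::predict(fit, newdata = df[test, , drop = FALSE])
    sig <- sqrt(sum(stats::resid(fit)^2) / length(stats::resid(fit)))
    yv <- stats::model.response(stats::model.frame(formula, df[test, , drop = FALSE]))
    lpd[test] <- stats::dnorm(yv, mu, sig, log = TRUE)
  }
  sum(lpd)
}

# cross-validated log predictive density for a glmmTMB beta specification
elpd_beta <- function(df, formula, K = 10, seed = NULL) {
  n <- nrow(df)
  folds <- make_folds(n, K, seed)
  lpd <- numeric(n)
  yname <- all.vars(formula)[1]
  for (f in unique(folds)) {
    test <- folds == f
    fit <- glmmTMB::glmmTMB(formula, data = df[!test, , drop = FALSE],
                            family = glmmTMB::beta_family())
    mu <- stats::predict(fit, newdata = df[test, , drop = FALSE],
                         type = "response", allow.new.levels = TRUE)
    phi <- stats::sigma(fit)
    yv <- df[[yname]][test]
    lpd[test] <- stats::dbeta(yv, mu * phi, (1 - mu) * phi, log = TRUE)
  }
  sum(lpd)
}

new_pheno_model <- function(...) structure(list(...), class = "pheno_model")

#' @export
print.pheno_model <- function(x, ...) {
  cat(sprintf("%s model: %s ~ %s + %s  (n = %d)\n", x$family, x$response,
              x$predictor %||% "1", paste(x$controls, collapse = " + "), x$n))
  cf <- x$coefficients
  cf$sig <- ifelse(cf$significant, "*", "")
  print(cf, digits = 3, row.names = FALSE)
  cat(sprintf("variance explained = %.3f, elpd = %.2f\n",
              x$variance_explained, x$elpd))
  if (!is.null(x$moran))
    cat(sprintf("Moran's I on residuals = %.4f (expected %.4f, p = %.3f)\n",
                x$moran$I, x$moran$expected, x$moran$p))
  invisible(x)
}

#' Model caterpillar phenology as a function of tree phenology
#'
#' Fits a Gaussian linear model of one caterpillar metric on one tree
#' metric plus the fixed effect of sampling area (reference level: Great
#' Wood), mirroring the standard cross-trophic design. Coefficient 95%
#' intervals are t-based by default (exactly calibrated under the Gaussian
#' model, and identical to flat-prior credible intervals); a case-resampling
#' percentile bootstrap is available via `ci_method = "boot"`. An effect is
#' reported significant when its interval excludes zero. The model also reports explained variance
#' (var(fitted) / (var(fitted) + var(residual))), a cross-validated ELPD
#' predictive score (exhaustive leave-one-out for n <= 30, 10-fold
#' otherwise) and, when coordinates are available, Moran's I on the
#' residuals.
#'
#' @param metrics metrics table: one row per tree with the metric columns,
#'   `area` and (optionally) coordinates.
#' @param response caterpillar metric column name.
#' @param predictor tree metric column name, or `NULL` for the
#'   intercept-plus-area reference model.
#' @param area area column name; dropped with a warning if only one level.
#' @param ref_area reference area level for the intercept.
#' @param coords length-2 vector of coordinate column names, or `NULL` to
#'   skip the spatial diagnostic.
#' @param ci_method `"wald"` (t intervals) or `"boot"` (percentile
#'   bootstrap).
#' @param B bootstrap replicates.
#' @param K folds for the ELPD score when n > 30.
#' @param seed seed for bootstrap and fold assignment.
#' @return a `pheno_model`: coefficient table (`estimate`, `ci_low`,
#'   `ci_high`, `significant`), `variance_explained`, `elpd`, `moran`,
#'   `n`, `rows` (tree ids used).
#' @export
fit_cross_trophic_model <- function(metrics, response, predictor,
                                    area = "area", ref_area = "Great Wood",
                                    coords = c("x", "y"),
                                    ci_method = c("wald", "boot"),
                                    B = 1000, K = 10, seed = 1) {
  ci_method <- match.arg(ci_method)
  vars <- c(response, predictor, area)
  stopifnot(all(vars %in% names(metrics)))
  keep <- stats::complete.cases(metrics[vars])
  df <- metrics[keep, , drop = FALSE]
  if (nrow(df) < 10)
    stop("need at least 10 complete rows to fit the model", call. = FALSE)
  df$.area <- stats::relevel(droplevels(factor(df[[area]])), ref = ref_area)
  use_area <- nlevels(df$.area) > 1
  if (!use_area)
    warning("only one sampling area present; area term dropped")
  rhs <- c(predictor, if (use_area) ".area")
  form <- stats::reformulate(if (length(rhs)) rhs else "1", response = response)
  fit <- stats::lm(form, data = df)
  est <- stats::coef(fit)

  if (ci_method == "boot") {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    bs <- matrix(NA_real_, B, length(est))
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(df), replace = TRUE)
      fb <- try(stats::lm(form, data = df[idx, , drop = FALSE]), silent = TRUE)
      if (!inherits(fb, "try-error") && length(stats::coef(fb)) == length(est) &&
          !anyNA(stats::coef(fb)))
        bs[b, ] <- stats::coef(fb)
    }
    bs <- bs[stats::complete.cases(bs), , drop = FALSE]
    ci <- t(apply(bs, 2, stats::quantile, probs = c(0.025, 0.975)))
  } else {
    ci <- stats::confint(fit)
  }
  cf <- data.frame(term = names(est), estimate = unname(est),
                   ci_low = ci[, 1], ci_high = ci[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  cf$significant <- cf$ci_low > 0 | cf$ci_high < 0

  mor <- NULL
  if (!is.null(coords) && all(coords %in% names(df)) &&
      sum(stats::complete.cases(df[coords])) >= 10) {
    okc <- stats::complete.cases(df[coords])
    mor <- tryCatch(
      morans_i(stats::resid(fit)[okc], as.matrix(df[okc, coords]),
               seed = seed),
      error = function(e) NULL, warning = function(w) NULL)
  }
  new_pheno_model(
    response = response, predictor = predictor,
    controls = if (use_area) area else character(),
    family = "gaussian", coefficients = cf,
    variance_explained = r2_fitted(stats::fitted(fit), df[[response]]),
    elpd = elpd_gaussian(df, form, K = K, seed = seed),
    moran = mor, n = nrow(df), rows = df$tree_id %||% rownames(df),
    fit = fit)
}

#' Model herbivory as a function of phenology
#'
#' Beta-likelihood regression (logit link) of per-tree herbivory fractions
#' on one phenology metric, with the fixed effect of sampling area
#' (reference: Great Wood) and a random intercept for the relative canopy
#' level the sampled leaves came from, fitted with glmmTMB. Estimates are
#' on the logit scale. Exact 0/1 fractions are squeezed onto the open
#' interval first. Reports Wald 95% intervals by default (a case bootstrap
#' is available), conditional explained variance (the model-implied mean
#' includes the canopy random effect), cross-validated ELPD, and Moran's I
#' on response residuals.
#'
#' @inheritParams fit_cross_trophic_model
#' @param predictor phenology metric column, or `NULL` for the reference
#'   model without a metric term.
#' @param response herbivory column (fractions in \[0, 1\]).
#' @param canopy canopy-level column used as the grouping (random) effect.
#' @return a `pheno_model` with `family = "beta"`.
#' @export
fit_herbivory_model <- function(metrics, predictor,
                                response = "herbivory_frac",
                                area = "area", ref_area = "Great Wood",
                                canopy = "canopy_level",
                                coords = c("x", "y"),
                                ci_method = c("wald", "boot"),
                                B = 200, K = 10, seed = 1) {
  ci_method <- match.arg(ci_method)
  vars <- c(response, predictor, area, canopy)
  stopifnot(all(vars %in% names(metrics)))
  keep <- stats::complete.cases(metrics[vars])
  df <- metrics[keep, , drop = FALSE]
  if (nrow(df) < 10)
    stop("need at least 10 complete rows to fit the model", call. = FALSE)
  y <- df[[response]]
  if (any(y < 0 | y > 1))
    stop("herbivory must be fractions in [0, 1]", call. = FALSE)
  if (stats::var(y) == 0)
    stop("herbivory values all equal: Beta precision undefined", call. = FALSE)
  if (any(y <= 0 | y >= 1)) y <- squeeze_unit(y)
  df$.herb <- y
  df$.area <- stats::relevel(droplevels(factor(df[[area]])), ref = ref_area)
  use_area <- nlevels(df$.area) > 1
  if (!use_area) warning("only one sampling area present; area term dropped")
  df$.canopy <- factor(df[[canopy]])
  rhs <- c(predictor, if (use_area) ".area", "(1 | .canopy)")
  form <- stats::as.formula(paste(".herb ~", paste(rhs, collapse = " + ")))
  fit <- glmmTMB::glmmTMB(form, data = df, family = glmmTMB::beta_family())
  est <- glmmTMB::fixef(fit)$cond

  if (ci_method == "wald") {
    # a boundary (zero) canopy variance yields harmless NaN warnings for the
    # dispersion rows; only the fixed-effect rows are kept
    ci <- suppressWarnings(
      stats::confint(fit, parm = "beta_")[, 1:2, drop = FALSE])
  } else {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    bs <- matrix(NA_real_, B, length(est))
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(df), replace = TRUE)
      fb <- try(suppressWarnings(
        glmmTMB::glmmTMB(form, data = df[idx, , drop = FALSE],
                         family = glmmTMB::beta_family())), silent = TRUE)
      if (!inherits(fb, "try-error")) {
        cb <- glmmTMB::fixef(fb)$cond
        if (length(cb) == length(est) && !anyNA(cb)) bs[b, ] <- cb
      }
    }
    bs <- bs[stats::complete.cases(bs), , drop = FALSE]
    ci <- t(apply(bs, 2, stats::quantile, probs = c(0.025, 0.975)))
  }
  cf <- data.frame(term = names(est), estimate = unname(est),
                   ci_low = ci[, 1], ci_high = ci[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  cf$significant <- cf$ci_low > 0 | cf$ci_high < 0

  mu <- stats::predict(fit, type = "response")  # conditional on canopy effect
  mor <- NULL
  if (!is.null(coords) && all(coords %in% names(df)) &&
      sum(stats::complete.cases(df[coords])) >= 10) {
    okc <- stats::complete.cases(df[coords])
    mor <- tryCatch(
      morans_i((df$.herb - mu)[okc], as.matrix(df[okc, coords]), seed = seed),
      error = function(e) NULL, warning = function(w) NULL)
  }
  new_pheno_model(
    response = response, predictor = predictor,
    controls = c(if (use_area) area else character(), paste0("(1|", canopy, ")")),
    family = "beta", coefficients = cf,
    variance_explained = r2_fitted(mu, df$.herb),
    elpd = elpd_beta(df, form, K = K, seed = seed),
    moran = mor, n = nrow(df), rows = df$tree_id %||% rownames(df),
    fit = fit)
}

#' Compare models of the same response by predictive fit
#'
#' Tabulates cross-validated ELPD for a set of models sharing a response
#' and the same rows; the best model is anchored at delta_elpd = 0 and the
#' others are negative.
#'
#' @param models named list of `pheno_model` objects.
#' @return data.frame: `model`, `predictor`, `elpd`, `delta_elpd`, sorted
#'   best first.
#' @export
compare_models_elpd <- function(models) {
  stopifnot(length(models) >= 2,
            all(vapply(models, inherits, logical(1), "pheno_model")))
  resp <- unique(vapply(models, `[[`, character(1), "response"))
  if (length(resp) != 1)
    stop("models must share a response", call. = FALSE)
  rowsets <- lapply(models, function(m) sort(as.character(m$rows)))
  if (!all(vapply(rowsets, identical, logical(1), rowsets[[1]])))
    stop("models were fitted to different row sets; refit on common rows",
         call. = FALSE)
  elpd <- vapply(models, `[[`, numeric(1), "elpd")
  out <- data.frame(
    model = names(models) %||% paste0("m", seq_along(models)),
    predictor = vapply(models, function(m) m$predictor %||% "(none)",
                       character(1)),
    elpd = elpd, delta_elpd = elpd - max(elpd),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$elpd), ]
}

#' Moran's I spatial autocorrelation with kNN weights
#'
#' Moran's I of a per-tree variable (typically model residuals) under
#' row-standardized k-nearest-neighbour weights, with its null expectation
#' -1/(n-1) and a two-sided permutation p value. Trees at exactly duplicated
#' coordinates are collapsed into a single site carrying their mean value
#' (with a warning).
#'
#' @param values numeric vector.
#' @param coords n x 2 matrix of coordinates (metres).
#' @param k neighbours per site (default 8).
#' @param nperm permutation replicates for the p value (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `moran_result`: `I`, `expected`, `p`, `n`, `k`.
#' @export
morans_i <- function(values, coords, k = 8, nperm = 999, seed = 1) {
  coords <- as.matrix(coords)
  stopifnot(length(values) == nrow(coords), ncol(coords) == 2,
            all(is.finite(values)), all(is.finite(coords)))
  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key)) {
    warning("duplicate coordinates: collapsing to site means")
    values <- as.numeric(tapply(values, key, mean))
    coords <- coords[!duplicated(key), , drop = FALSE]
    values <- values[match(paste(coords[, 1], coords[, 2]),
                           sort(unique(key)))]
  }
  n <- length(values)
  if (n < 4) stop("need at least 4 distinct sites", call. = FALSE)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    W[i, nb] <- 1 / k     # row-standardized binary kNN
  }
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  if (denom == 0) stop("zero variance: Moran's I undefined", call. = FALSE)
  I <- (n / s0) * sum(z * (W %*% z)) / denom
  expected <- -1 / (n - 1)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  zp <- replicate(nperm, z[sample.int(n)])
  Ip <- (n / s0) * colSums(zp * (W %*% zp)) / denom
  p <- (1 + sum(abs(Ip - expected) >= abs(I - expected) - 1e-15)) / (nperm + 1)
  structure(list(I = I, expected = expected, p = p, n = n, k = k,
                 nperm = nperm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f under no structure), p = %.3f, n = %d, k = %d\n",
              x$I, x$expected, x$p, x$n, x$k))
  invisible(x)
}
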