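#' Settings for sigmoidal trajectory fitting
#'
#' @param basis_k number of B-spline basis functions for the smooth of day
#'   (default 10, set by a simulation calibration of half-date interval
#'   coverage; reduced automatically for short series).
#' @param bs mgcv basis type; `"ps"` gives a B-spline with a
#'   second-difference penalty, the smoothing parameter being chosen by
#'   marginal likelihood (REML).
#' @param B ensemble size (replicate curves used for interval extraction).
#' @param ensemble `"posterior"` (Gaussian draws from the fitted
#'   coefficient posterior, the mgcv Bayesian machinery) or `"bootstrap"`
#'   (parametric bootstrap refits on data resampled from the fitted model).
#' @param engine `"spline"` (penalized Beta-GAM, default) or `"logistic"`
#'   (3-parameter logistic by nonlinear least squares, a fallback for short
#'   series).
#' @param grid_step evaluation grid resolution in days.
#' @param use_observer include a random intercept for observer identity when
#'   the trajectory carries observer labels (bud-score streams).
#' @param shrink weight in \[0, 1) pulling the tree's curve toward a pooled
#'   species-level curve supplied to [fit_sigmoid()] (0 = per-tree fit).
#' @return a list of class `sigmoid_settings`.
#' @export
sigmoid_settings <- function(basis_k = 10, bs = "ps", B = 500,
                             ensemble = c("posterior", "bootstrap"),
                             engine = c("spline", "logistic"),
                             grid_step = 0.1, use_observer = TRUE,
                             shrink = 0) {
  stopifnot(basis_k >= 4, B >= 1, grid_step > 0, shrink >= 0, shrink < 1)
  structure(list(basis_k = basis_k, bs = bs, B = B,
                 ensemble = match.arg(ensemble), engine = match.arg(engine),
                 grid_step = grid_step, use_observer = use_observer,
                 shrink = shrink),
            class = "sigmoid_settings")
}

#' Fit a sigmoidal curve to a normalized trajectory
#'
#' Fits a smooth curve on the proportion scale to a `pheno_trajectory` by
#' maximizing a Beta likelihood with a logit-linked penalized spline of day
#' (free precision, smoothing parameter by REML). Series containing exact
#' boundary values are moved off \{0, 1\} by the squeeze
#' y' = (y (n - 1) + 0.5) / n before fitting; series already inside the
#' open interval are fitted as is.
#' Bud-score trajectories carrying observer labels get a random intercept
#' for observer identity. Uncertainty is represented by an ensemble of B
#' replicate curves: by default Gaussian draws from the coefficient
#' posterior of the fitted GAM; a parametric bootstrap (refitting on Beta
#' resamples from the fitted mean/precision) is available.
#'
#' @param traj a `pheno_trajectory` (flag `"ok"`).
#' @param settings a [sigmoid_settings()].
#' @param pool optional `pheno_curve` for the same metric fitted to pooled
#'   species data; when `settings$shrink > 0` the central curve and ensemble
#'   are blended toward it on the logit scale.
#' @return an object of class `pheno_curve`: evaluation `grid` (0.1-day
#'   resolution), `central` fitted proportions, `ensemble` matrix
#'   (grid x B), `scale = "proportion"`, `converged`, `deviance`.
#' @export
fit_sigmoid <- function(traj, settings = sigmoid_settings(), pool = NULL) {
  stopifnot(inherits(traj, "pheno_trajectory"))
  if (traj$flag != "ok")
    stop(sprintf("tree %s metric %s: trajectory flagged '%s', refusing to fit",
                 traj$tree_id, traj$metric, traj$flag), call. = FALSE)
  if (length(unique(traj$days)) < 5)
    stop(sprintf("tree %s metric %s: need >= 5 distinct visit days",
                 traj$tree_id, traj$metric), call. = FALSE)

  day <- traj$days
  y <- traj$y
  if (any(y <= 0 | y >= 1)) y <- squeeze_unit(y)
  grid <- seq(min(day), max(day), by = settings$grid_step)

  if (settings$engine == "logistic") {
    fitl <- fit_logistic3(day, y, grid, settings$B)
    central <- fitl$central; ens <- fitl$ensemble
    converged <- fitl$converged; dev <- fitl$deviance
  } else {
    res <- try(fit_sigmoid_spline(traj, day, y, grid, settings), silent = TRUE)
    if (inherits(res, "try-error")) {
      # Beta-GAM optimisation can fail on (near-)noiseless series where the
      # precision diverges; the 3-parameter logistic is the documented fallback
      fitl <- fit_logistic3(day, y, grid, settings$B)
      res <- list(central = fitl$central, ens = fitl$ensemble,
                  converged = fitl$converged, dev = fitl$deviance)
    }
    central <- res$central; ens <- res$ens
    converged <- res$converged; dev <- res$dev
  }

  if (settings$shrink > 0 && !is.null(pool)) {
    w <- settings$shrink
    pc <- stats::approx(pool$grid, stats::qlogis(pool$central), xout = grid,
                        rule = 2)$y
    central <- stats::plogis((1 - w) * stats::qlogis(central) + w * pc)
    ens <- stats::plogis((1 - w) * stats::qlogis(ens) + w * pc)
  }

  structure(list(tree_id = traj$tree_id, metric = traj$metric, grid = grid,
                 central = central, ensemble = ens, scale = "proportion",
                 converged = converged, deviance = dev),
            class = "pheno_curve")
}

fit_sigmoid_spline <- function(traj, day, y, grid, settings) {
    k <- min(settings$basis_k, length(unique(day)) - 1L)
    dat <- data.frame(day = day, y = y)
    has_obs <- settings$use_observer && !is.null(traj$observer_id) &&
      length(unique(traj$observer_id)) > 1L
    if (has_obs) {
      dat$observer <- factor(traj$observer_id)
      form <- y ~ s(day, k = k, bs = settings$bs) + s(observer, bs = "re")
    } else {
      form <- y ~ s(day, k = k, bs = settings$bs)
    }
    # betar warns about its saturated likelihood on near-degenerate series;
    # harmless here (only relative likelihoods are used), so muffle it
    fit <- withCallingHandlers(
      mgcv::gam(form, family = mgcv::betar(link = "logit"), data = dat,
                method = "REML"),
      warning = function(w) {
        if (grepl("saturated likelihood", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    nd <- data.frame(day = grid)
    if (has_obs) nd$observer <- factor(dat$observer[1], levels = levels(dat$observer))
    Xp <- stats::predict(fit, newdata = nd, type = "lpmatrix")
    if (has_obs) {  # population-level curve: zero out the observer effect
      oc <- grepl("observer", colnames(Xp))
      Xp[, oc] <- 0
    }
    eta <- drop(Xp %*% stats::coef(fit))
    central <- stats::plogis(eta)
    if (settings$ensemble == "posterior") {
      # smoothing-parameter-uncertainty-corrected covariance: the plain
      # conditional posterior undercovers for quantities like crossing days
      V <- tryCatch(stats::vcov(fit, unconditional = TRUE),
                    error = function(e) fit$Vp)
      br <- mgcv::rmvn(settings$B, stats::coef(fit), V)
      ens <- stats::plogis(Xp %*% t(br))
    } else {
      phi <- fit$family$getTheta(TRUE)
      mu <- stats::fitted(fit)
      ens <- matrix(NA_real_, length(grid), settings$B)
      for (b in seq_len(settings$B)) {
        yb <- stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
        yb <- pmin(pmax(yb, 1e-6), 1 - 1e-6)
        db <- dat; db$y <- yb
        fb <- try(mgcv::gam(form, family = mgcv::betar(link = "logit"),
                            data = db, method = "REML"), silent = TRUE)
        ens[, b] <- if (inherits(fb, "try-error")) central else {
          stats::plogis(drop(Xp %*% stats::coef(fb)))
        }
      }
    }
    list(central = central, ens = ens, converged = isTRUE(fit$converged),
         dev = stats::deviance(fit))
}

# 3-parameter logistic ymax / (1 + exp(-k (t - t0))) by nls; parametric
# bootstrap ensemble. Fallback engine for short series.
fit_logistic3 <- function(day, y, grid, B) {
  start <- list(t0 = stats::approx(y, day, xout = stats::median(range(y)),
                                   ties = "ordered")$y %||% mean(day),
                k = 4 / diff(range(day)) * 4, ymax = max(y))
  if (!is.finite(start$t0)) start$t0 <- mean(day)
  fit <- try(suppressWarnings(
    stats::nls(y ~ ymax * stats::plogis(k * (day - t0)), start = start,
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(central = rep(NA_real_, length(grid)),
                ensemble = matrix(NA_real_, length(grid), B),
                converged = FALSE, deviance = NA_real_))
  cf <- stats::coef(fit)
  pred <- function(cf, t) pmin(1 - 1e-9, pmax(1e-9,
    cf["ymax"] * stats::plogis(cf["k"] * (t - cf["t0"]))))
  central <- pred(cf, grid)
  rss <- sum(stats::resid(fit)^2)
  sig <- sqrt(rss / length(day))
  ens <- matrix(NA_real_, length(grid), B)
  for (b in seq_len(B)) {
    yb <- pred(cf, day) + stats::rnorm(length(day), 0, sig)
    fb <- try(suppressWarnings(
      stats::nls(yb ~ ymax * stats::plogis(k * (day - t0)),
                 start = as.list(cf),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    ens[, b] <- if (inherits(fb, "try-error")) central else
      pred(stats::coef(fb), grid)
  }
  # an (near-)interpolating fit is converged even if nls gives up stepping
  conv <- isTRUE(fit$convInfo$isConv) || sig < 1e-4
  list(central = central, ensemble = ens, converged = conv, deviance = rss)
}

#' @export
print.pheno_curve <- function(x, ...) {
  cat(sprintf("<fitted curve> tree %s, metric %s, %s scale, grid [%.1f, %.1f], B = %d%s\n",
              x$tree_id, x$metric, x$scale, min(x$grid), max(x$grid),
              ncol(x$ensemble), if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# first upward 0.5-crossing of a curve sampled on a grid; linear
# interpolation between the bracketing grid points; NA when none
first_crossing <- function(grid, v, level = 0.5) {
  below <- v < level
  idx <- which(below[-length(v)] & !below[-1])
  if (!length(idx)) {
    if (v[1] >= level) return(structure(grid[1], boundary = TRUE))
    return(NA_real_)
  }
  i <- idx[1]
  grid[i] + (level - v[i]) / (v[i + 1] - v[i]) * (grid[i + 1] - grid[i])
}

#' Extract the half-date from a fitted proportion-scale curve
#'
#' The half-date is the day at which the fitted trajectory first crosses
#' y = 0.5 from below, refined to 0.01-day precision by root finding on a
#' spline interpolant of the central curve. The 95% interval is the
#' 2.5/97.5 percentile of the crossing days of the ensemble curves, and the
#' gradient at the crossing is a centered finite difference of the central
#' curve. Curves that never reach 0.5 are flagged `no_crossing`; curves
#' already above 0.5 at the first grid day (or crossing exactly at the grid
#' edge) are flagged `boundary`. A non-monotone central curve that recrosses
#' 0.5 keeps the first crossing and records the number of upward crossings
#' in `n_crossings`.
#'
#' @param curve a `pheno_curve` on the proportion scale.
#' @return one-row data.frame: `tree_id`, `metric`, `half_day`, `ci_low`,
#'   `ci_high`, `ci_width`, `gradient_at_half`, `flag`, `n_crossings`.
#' @export
extract_half_date <- function(curve) {
  stopifnot(inherits(curve, "pheno_curve"))
  if (curve$scale != "proportion")
    stop("half-dates are defined for proportion-scale curves", call. = FALSE)
  res <- data.frame(tree_id = curve$tree_id, metric = curve$metric,
                    half_day = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    ci_width = NA_real_, gradient_at_half = NA_real_,
                    flag = "ok", n_crossings = 0L,
                    stringsAsFactors = FALSE)
  if (!curve$converged) { res$flag <- "not_converged"; return(res) }
  g <- curve$grid; v <- curve$central
  up <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
  res$n_crossings <- length(up)
  if (v[1] >= 0.5) { res$flag <- "boundary"; return(res) }
  if (!length(up)) { res$flag <- "no_crossing"; return(res) }
  i <- up[1]
  f <- stats::splinefun(g, v)
  half <- stats::uniroot(function(t) f(t) - 0.5, lower = g[i], upper = g[i + 1],
                         tol = 1e-3)$root
  if (half <= g[1] + 1e-9 || half >= g[length(g)] - 1e-9) {
    res$flag <- "boundary"; return(res)
  }
  h <- 0.1
  grad <- (f(half + h) - f(half - h)) / (2 * h)
  cross <- apply(curve$ensemble, 2, function(col) first_crossing(g, col))
  cross <- cross[is.finite(cross)]
  if (length(cross) >= 20) {
    ci <- stats::quantile(cross, c(0.025, 0.975), names = FALSE)
    # the central curve is not itself an ensemble member; keep the interval
    # honest but consistent with the point estimate
    ci[1] <- min(ci[1], half); ci[2] <- max(ci[2], half)
  } else ci <- c(NA_real_, NA_real_)
  res$half_day <- half
  res$ci_low <- ci[1]; res$ci_high <- ci[2]; res$ci_width <- ci[2] - ci[1]
  res$gradient_at_half <- grad
  res
}

#' Summarize half-date credible-interval widths by group
#'
#' Mean and sd of the 95%-interval widths of `ok`-flagged half-date
#' estimates, grouped by arbitrary columns (typically species x metric).
#' Groups with no usable estimates are absent from the output rather than
#' reported as zero.
#'
#' @param estimates data.frame of half-date estimates (rows from
#'   [extract_half_date()], possibly merged with metadata).
#' @param by character vector of grouping column names present in
#'   `estimates`.
#' @return data.frame with the grouping columns, `n`, `mean_width`,
#'   `sd_width` (NA when n = 1).
#' @export
summarize_ci_widths <- function(estimates, by = "metric") {
  stopifnot(all(by %in% names(estimates)), "ci_width" %in% names(estimates))
  ok <- estimates[estimates$flag == "ok" & is.finite(estimates$ci_width), ,
                  drop = FALSE]
  if (!nrow(ok))
    return(stats::setNames(
      data.frame(matrix(ncol = length(by) + 3, nrow = 0)),
      c(by, "n", "mean_width", "sd_width")))
  agg <- function(f) stats::aggregate(ok$ci_width, ok[by], f)
  out <- agg(length)
  names(out)[ncol(out)] <- "n"
  out$mean_width <- agg(mean)$x
  out$sd_width <- agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)$x
  out
}
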