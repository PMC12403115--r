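#' Convert frass mass in grams to integer centigram counts
#'
#' Frass dry mass is rescaled by a factor of 100 (gram to centigram) and
#' rounded to the nearest integer so that the same Poisson count-intensity
#' machinery used for caterpillar counts applies. Rounding is half-up
#' (0.005 g -> 1 cg), not banker's rounding.
#'
#' @param mass_g nonnegative masses in grams.
#' @return integer vector of centigrams.
#' @export
frass_to_centigrams <- function(mass_g) {
  if (any(!is.finite(mass_g) | mass_g < 0))
    stop("frass masses must be finite and nonnegative", call. = FALSE)
  as.integer(round_half_up(mass_g * 100))
}

#' Settings for count-intensity fitting
#'
#' @param basis_k,bs,B,ensemble,grid_step as in [sigmoid_settings()].
#' @param exposure_offset model counts with log(interval length) as an
#'   offset, since interception traps accumulate between visits; set
#'   `FALSE` to model raw per-visit counts with no exposure adjustment.
#' @param quasi inflate ensemble spread by an estimated overdispersion scale
#'   (quasi-likelihood); default `FALSE` (plain Poisson).
#' @return list of class `count_settings`.
#' @export
count_settings <- function(basis_k = 10, bs = "ps", B = 500,
                           ensemble = c("posterior", "bootstrap"),
                           grid_step = 0.1, exposure_offset = TRUE,
                           quasi = FALSE) {
  stopifnot(basis_k >= 4, B >= 1, grid_step > 0)
  structure(list(basis_k = basis_k, bs = bs, B = B,
                 ensemble = match.arg(ensemble), grid_step = grid_step,
                 exposure_offset = exposure_offset, quasi = quasi),
            class = "count_settings")
}

#' Fit a smooth count-intensity curve to trap counts
#'
#' Fits a Poisson-family GAM (log link, penalized B-spline of day, REML
#' smoothing) to raw per-visit counts and evaluates the expected daily
#' intensity on a 0.1-day grid with an uncertainty ensemble (posterior
#' coefficient draws by default). When `exposure_offset` is on, visit
#' intervals enter as a log offset so the fitted curve is a per-day rate;
#' otherwise it is an expected per-visit count.
#'
#' @param days visit days (>= 5 distinct).
#' @param counts nonnegative integer counts per visit (centigrams for
#'   frass, see [frass_to_centigrams()]).
#' @param settings a [count_settings()].
#' @param tree_id,metric labels carried into the result.
#' @return a `pheno_curve` with `scale = "intensity"`, or a curve flagged via
#'   `converged = FALSE` if the smoother fails; all-zero series are refused.
#' @export
fit_count_curve <- function(days, counts, settings = count_settings(),
                            tree_id = "tree", metric = "count") {
  stopifnot(length(days) == length(counts))
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop(sprintf("tree %s: counts must be nonnegative integers", tree_id),
         call. = FALSE)
  o <- order(days)
  days <- days[o]; counts <- counts[o]
  if (length(unique(days)) < 5)
    stop(sprintf("tree %s metric %s: need >= 5 visits", tree_id, metric),
         call. = FALSE)
  if (sum(counts) == 0)
    stop(sprintf("tree %s metric %s: all-zero series, peak undefined",
                 tree_id, metric), call. = FALSE)
  interval <- c(stats::median(diff(days)), diff(days))
  dat <- data.frame(day = days, count = counts, interval = interval)
  k <- min(settings$basis_k, length(unique(days)) - 1L)
  form <- if (settings$exposure_offset)
    count ~ s(day, k = k, bs = settings$bs) + offset(log(interval))
  else count ~ s(day, k = k, bs = settings$bs)
  fit <- mgcv::gam(form, family = stats::poisson(), data = dat,
                   method = "REML")
  grid <- seq(min(days), max(days), by = settings$grid_step)
  nd <- data.frame(day = grid, interval = 1)
  Xp <- stats::predict(fit, newdata = nd, type = "lpmatrix")
  central <- exp(drop(Xp %*% stats::coef(fit)))
  V <- tryCatch(stats::vcov(fit, unconditional = TRUE),
                error = function(e) fit$Vp)
  if (settings$quasi) {
    ph <- max(1, sum(stats::residuals(fit, "pearson")^2) / stats::df.residual(fit))
    V <- V * ph
  }
  if (settings$ensemble == "posterior") {
    br <- mgcv::rmvn(settings$B, stats::coef(fit), V)
    ens <- exp(Xp %*% t(br))
  } else {
    mu <- stats::fitted(fit)
    ens <- matrix(NA_real_, length(grid), settings$B)
    for (b in seq_len(settings$B)) {
      db <- dat; db$count <- stats::rpois(length(mu), mu)
      fb <- try(mgcv::gam(form, family = stats::poisson(), data = db,
                          method = "REML"), silent = TRUE)
      ens[, b] <- if (inherits(fb, "try-error")) central else
        exp(drop(Xp %*% stats::coef(fb)))
    }
  }
  structure(list(tree_id = tree_id, metric = metric, grid = grid,
                 central = central, ensemble = ens, scale = "intensity",
                 converged = isTRUE(fit$converged),
                 deviance = stats::deviance(fit)),
            class = "pheno_curve")
}

#' Extract peak day and height from an intensity-scale curve
#'
#' The peak day is the grid argmax of the central fitted intensity (ties
#' broken toward the earliest day) and the peak height is the intensity
#' there. The height interval is the 2.5/97.5 percentile of each ensemble
#' curve's own maximum. An argmax at the first or last observed day raises
#' the `boundary` flag (the true peak may lie outside the sampled window).
#'
#' @param curve a `pheno_curve` with `scale = "intensity"`.
#' @return one-row data.frame: `tree_id`, `metric`, `peak_day`,
#'   `peak_height`, `height_ci_low`, `height_ci_high`, `flag`.
#' @export
extract_peak <- function(curve) {
  stopifnot(inherits(curve, "pheno_curve"))
  if (curve$scale != "intensity")
    stop("peaks are defined for intensity-scale curves", call. = FALSE)
  res <- data.frame(tree_id = curve$tree_id, metric = curve$metric,
                    peak_day = NA_real_, peak_height = NA_real_,
                    height_ci_low = NA_real_, height_ci_high = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  if (!curve$converged) { res$flag <- "not_converged"; return(res) }
  i <- which.max(curve$central)           # which.max takes the earliest tie
  res$peak_day <- curve$grid[i]
  res$peak_height <- curve$central[i]
  hmax <- apply(curve$ensemble, 2, max)
  ci <- stats::quantile(hmax, c(0.025, 0.975), names = FALSE)
  res$height_ci_low <- ci[1]; res$height_ci_high <- ci[2]
  if (i == 1L || i == length(curve$grid)) res$flag <- "boundary"
  res
}
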