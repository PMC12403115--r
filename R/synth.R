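#' Configure a synthetic woodland
#'
#' Builds the parameter set for [generate_woodland()]. The defaults emulate a
#' temperate deciduous woodland monitored over one spring: six tree species
#' whose mean budburst days span roughly 32 days, per-tree timing deviations
#' around the species mean, three sampling areas with small timing offsets,
#' three observation streams of each tree's leaf-out trajectory (ordinal bud
#' scores, effective LAI, crown NDVI) with stream-specific lag and noise,
#' water-trap caterpillar counts around a Gaussian-shaped seasonal intensity
#' whose timing depends linearly on the host tree's half-date, frass biomass
#' peaking a few days before the count peak, and a per-tree herbivory fraction
#' that declines with later phenology.
#'
#' @param species data.frame with columns `species`, `n_trees`,
#'   `mean_budburst` (day of year of the species-average latent half-date),
#'   `max_stage` (5 or 7, top of the ordinal bud-scoring key) and
#'   `peak_abundance` (expected caterpillars per day at the seasonal peak
#'   under an average tree of that species).
#' @param within_species_sd sd (days) of per-tree half-date deviations.
#' @param rate_mean,rate_sd latent leaf-out rate (logit units/day) mean and
#'   between-tree sd.
#' @param areas data.frame with columns `area`, `tree_offset` (days added to
#'   tree half-dates), `cat_offset` (days added to caterpillar timing),
#'   `herb_offset` (logit-scale shift of herbivory) and `prob` (tree
#'   assignment probability).
#' @param cross_trophic list with `a` (days), `b` (dimensionless slope of
#'   caterpillar peak day on tree half-date) and `sd` (residual sd, days).
#' @param sigma_peak sd (days) of the Gaussian seasonal count intensity.
#' @param frass_lead days by which the frass biomass peak precedes the
#'   caterpillar count peak.
#' @param frass_mass_scale grams of daily frass at the peak per unit of count
#'   intensity.
#' @param fwm list controlling the final-instar winter moth substream:
#'   `retention0` (retention probability at the count peak), `shift` (days by
#'   which the thinned stream's peak trails the total-count peak) and `cap`
#'   (upper bound on the retention probability).
#' @param visit_interval days between scheduled visits.
#' @param missed_visit_prob probability that a scheduled visit is missed.
#' @param season integer day-of-year range covered by the simulation grid.
#' @param windows list of per-method first/last visit days (day of year).
#' @param lags list with `lai` and `ndvi`: days by which those streams trail
#'   the latent bud trajectory.
#' @param lai_range,ndvi_range low/high asymptotes of the LAI and NDVI
#'   trajectories on their native scales.
#' @param noise list of observation-noise controls: `bud_section_sd` (days,
#'   persistent timing spread among the 12 scored crown sections),
#'   `observer_sd` (days, observer-specific bias in bud scoring), `lai_sd`
#'   and `ndvi_sd` (additive sd on the native scales), `outlier_prob` and
#'   `outlier_sd` (occasional gross errors on LAI/NDVI), `frass_cv`
#'   (lognormal coefficient of variation on frass mass).
#' @param herbivory list with logit-scale `intercept` and `slope` (per day of
#'   tree half-date), Beta `precision`, `canopy_sd` (sd of canopy-level
#'   random intercepts) and `species` (which species get herbivory samples).
#' @param n_observers number of rotating bud-score observers.
#' @param seed integer RNG seed; identical configs and seeds reproduce
#'   identical woodlands byte for byte.
#' @return an object of class `woodland_config`.
#' @seealso [generate_woodland()]
#' @export
woodland_config <- function(
    species = data.frame(
      species        = c("ash", "beech", "birch", "hazel", "oak", "sycamore"),
      n_trees        = c(23L, 5L, 17L, 30L, 77L, 18L),
      mean_budburst  = c(131.9, 112, 104, 100, 115, 108),
      max_stage      = c(5L, 5L, 5L, 5L, 7L, 5L),
      peak_abundance = c(10, 8, 10, 12, 30, 10)),
    within_species_sd = 5,
    rate_mean = 0.30, rate_sd = 0.04,
    areas = data.frame(
      area        = c("Great Wood", "ForestGEO", "Marley"),
      tree_offset = c(0, 1.0, -0.8),
      cat_offset  = c(0, 2.3, -1.2),
      herb_offset = c(0, -0.55, -0.69),
      prob        = c(0.45, 0.15, 0.40)),
    cross_trophic = list(a = 129, b = 0.20, sd = 3),
    sigma_peak = 6,
    frass_lead = 4,
    frass_mass_scale = 0.01,
    fwm = list(retention0 = 0.45, shift = 1, cap = 0.9),
    visit_interval = 3,
    missed_visit_prob = 0.05,
    season = c(80L, 180L),
    windows = list(bud = c(84, 145), lai = c(84, 159), ndvi = c(80, 160),
                   trap = c(120, 174), frass = c(126, 168)),
    lags = list(lai = 3, ndvi = 1),
    lai_range = c(0.6, 3.6),
    ndvi_range = c(0.45, 0.80),
    noise = list(bud_section_sd = 2, observer_sd = 0.5,
                 lai_sd = 0.12, ndvi_sd = 0.02,
                 outlier_prob = 0.02, outlier_sd = 4,
                 frass_cv = 0.25),
    herbivory = list(intercept = 5.85, slope = -0.07, precision = 30,
                     canopy_sd = 0.3, species = "oak"),
    n_observers = 4L,
    seed = 1L) {
  cfg <- list(species = species, within_species_sd = within_species_sd,
              rate_mean = rate_mean, rate_sd = rate_sd, areas = areas,
              cross_trophic = cross_trophic, sigma_peak = sigma_peak,
              frass_lead = frass_lead, frass_mass_scale = frass_mass_scale,
              fwm = fwm, visit_interval = visit_interval,
              missed_visit_prob = missed_visit_prob, season = season,
              windows = windows, lags = lags, lai_range = lai_range,
              ndvi_range = ndvi_range, noise = noise, herbivory = herbivory,
              n_observers = n_observers, seed = seed)
  validate_woodland_config(cfg)
  class(cfg) <- "woodland_config"
  cfg
}

validate_woodland_config <- function(cfg) {
  sp <- cfg$species
  if (!is.data.frame(sp) || nrow(sp) < 1L)
    stop("species table must have at least one row", call. = FALSE)
  need <- c("species", "n_trees", "mean_budburst", "max_stage", "peak_abundance")
  if (!all(need %in% names(sp)))
    stop("species table missing columns: ",
         paste(setdiff(need, names(sp)), collapse = ", "), call. = FALSE)
  if (!all(sp$max_stage %in% c(5L, 7L)))
    stop("species max_stage must be 5 or 7", call. = FALSE)
  if (!all(is.finite(sp$n_trees)) || any(sp$n_trees < 0) || sum(sp$n_trees) < 1)
    stop("at least one tree must be simulated", call. = FALSE)
  if (!all(is.finite(sp$mean_budburst)) || !all(is.finite(sp$peak_abundance)))
    stop("non-finite species parameters rejected", call. = FALSE)
  chk_num(cfg$within_species_sd, "within_species_sd", lower = 0)
  chk_num(cfg$rate_mean, "rate_mean", lower = 1e-6)
  chk_num(cfg$rate_sd, "rate_sd", lower = 0)
  chk_num(cfg$sigma_peak, "sigma_peak", lower = 1e-6)
  chk_num(cfg$frass_mass_scale, "frass_mass_scale", lower = 1e-12)
  chk_num(cfg$cross_trophic$sd, "cross_trophic$sd", lower = 0)
  chk_num(cfg$cross_trophic$a, "cross_trophic$a")
  chk_num(cfg$cross_trophic$b, "cross_trophic$b")
  chk_num(cfg$missed_visit_prob, "missed_visit_prob", lower = 0, upper = 1)
  chk_num(cfg$visit_interval, "visit_interval", lower = 1)
  chk_num(cfg$noise$outlier_prob, "noise$outlier_prob", lower = 0, upper = 1)
  for (nm in c("bud_section_sd", "observer_sd", "lai_sd", "ndvi_sd", "frass_cv"))
    chk_num(cfg$noise[[nm]], paste0("noise$", nm), lower = 0)
  chk_num(cfg$herbivory$precision, "herbivory$precision", lower = 1e-6)
  chk_num(cfg$fwm$retention0, "fwm$retention0", lower = 0, upper = 1)
  chk_num(cfg$fwm$cap, "fwm$cap", lower = 0, upper = 1)
  if (abs(sum(cfg$areas$prob) - 1) > 1e-8)
    stop("area assignment probabilities must sum to 1", call. = FALSE)
  invisible(cfg)
}

# latent leaf-out proportion for one tree
latent_prop <- function(day, t0, rate) stats::plogis(rate * (day - t0))

# visit schedule for a method window: regular rounds, per-tree random misses
visit_days <- function(window, interval) seq(window[1], window[2], by = interval)

#' Generate a synthetic woodland with known ground truth
#'
#' Simulates tree metadata, long-format multi-method observations and a truth
#' table from a [woodland_config()]. Bud scores are produced by thresholding a
#' latent logistic leaf-out trajectory (midpoint = the tree's half-date,
#' rate = logit units/day) into equal-width ordinal stages, averaged over 12
#' crown sections with persistent section-level timing spread and
#' observer-specific bias. LAI and NDVI are scaled/shifted copies of the
#' latent logistic with stream-specific lag, additive noise and occasional
#' outliers. Water-trap counts are Poisson draws around a Gaussian seasonal
#' intensity centred at `a + b * half_date + area offset + noise`; traps
#' accumulate between visits, so a missed round folds its catch into the next
#' visit. The final-instar winter moth substream is a binomial thinning of
#' totals with a retention curve that rises over the season, shifting the
#' thinned peak later. Frass mass is a noisy integral of a unimodal biomass
#' curve peaking `frass_lead` days before the count peak; missed frass, bud,
#' LAI and NDVI visits are dropped rows. One herbivory fraction per sampled
#' tree is drawn from a Beta distribution whose logit mean declines with the
#' tree's half-date.
#'
#' @param config a [woodland_config()].
#' @return a list of class `woodland` with elements `trees` (metadata:
#'   tree_id, species, area, x, y, max_stage), `observations` (long format:
#'   tree_id, species, area, method, day, value, observer_id), `herbivory`
#'   (tree_id, canopy_level, herbivory_frac), `truth` (per-tree latent
#'   half-date and rate, caterpillar peak day/intensity, frass and winter
#'   moth peak days, herbivory mean) and `config`.
#' @examples
#' w <- generate_woodland(woodland_config(
#'   species = data.frame(species = "oak", n_trees = 5L, mean_budburst = 115,
#'                        max_stage = 7L, peak_abundance = 30),
#'   seed = 42))
#' head(w$observations)
#' @export
generate_woodland <- function(config) {
  if (!inherits(config, "woodland_config")) config <- do.call(woodland_config, config)
  validate_woodland_config(config)
  cfg <- config
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)

  sp <- cfg$species[cfg$species$n_trees > 0, , drop = FALSE]
  n <- sum(sp$n_trees)
  species <- rep(sp$species, sp$n_trees)
  max_stage <- rep(sp$max_stage, sp$n_trees)
  mean_bb <- rep(sp$mean_budburst, sp$n_trees)
  peak_ab <- rep(sp$peak_abundance, sp$n_trees)
  tree_id <- sprintf("T%03d", seq_len(n))

  ar <- cfg$areas
  area_idx <- sample.int(nrow(ar), n, replace = TRUE, prob = ar$prob)
  area <- ar$area[area_idx]

  # coordinates: one cluster of 100 m grid posts per area, trees jittered
  # around a randomly chosen post -> spatially clustered areas for Moran's I
  origins <- cbind(x = c(0, 700, 1400), y = c(0, 700, 0))[
    ((area_idx - 1L) %% 3L) + 1L, , drop = FALSE]
  post <- cbind(100 * sample(0:6, n, replace = TRUE),
                100 * sample(0:6, n, replace = TRUE))
  coords <- origins + post + matrix(stats::runif(2 * n, -30, 30), ncol = 2)

  t0 <- mean_bb + ar$tree_offset[area_idx] + stats::rnorm(n, 0, cfg$within_species_sd)
  rate <- pmax(0.08, stats::rnorm(n, cfg$rate_mean, cfg$rate_sd))

  ct <- cfg$cross_trophic
  mu_cat <- ct$a + ct$b * t0 + ar$cat_offset[area_idx] + stats::rnorm(n, 0, ct$sd)
  peak_int <- peak_ab * exp(stats::rnorm(n, 0, 0.3))

  hb <- cfg$herbivory
  herb_mu <- stats::plogis(hb$intercept + hb$slope * t0 + ar$herb_offset[area_idx])

  trees <- data.frame(tree_id = tree_id, species = species, area = area,
                      x = coords[, 1], y = coords[, 2], max_stage = max_stage,
                      stringsAsFactors = FALSE)
  truth <- data.frame(tree_id = tree_id, species = species, area = area,
                      half_date = t0, rate = rate,
                      cat_peak_day = mu_cat, cat_peak_intensity = peak_int,
                      frass_peak_day = mu_cat - cfg$frass_lead,
                      fwm_peak_day = mu_cat + cfg$fwm$shift,
                      herbivory_mu = herb_mu,
                      stringsAsFactors = FALSE)

  nz <- cfg$noise
  obs <- vector("list", n)
  sched <- lapply(cfg$windows, visit_days, interval = cfg$visit_interval)
  observers <- sprintf("obs%02d", seq_len(cfg$n_observers))
  obs_shift <- stats::rnorm(cfg$n_observers, 0, nz$observer_sd)
  sig2 <- cfg$sigma_peak^2

  for (i in seq_len(n)) {
    rows <- list()

    # (i) ordinal bud scores: threshold latent proportion into equal-width
    # stages 1..M per crown section, average 12 sections
    keep <- stats::runif(length(sched$bud)) >= cfg$missed_visit_prob
    bd <- sched$bud[keep]
    if (length(bd)) {
      M <- max_stage[i]
      sec_dev <- stats::rnorm(12, 0, nz$bud_section_sd)
      oid <- observers[1L + (seq_along(sched$bud)[keep] + i) %% cfg$n_observers]
      score <- vapply(seq_along(bd), function(j) {
        p <- latent_prop(bd[j], t0[i] + sec_dev + obs_shift[match(oid[j], observers)],
                         rate[i])
        mean(pmin(pmax(ceiling(p * M), 1L), M))
      }, numeric(1))
      rows$bud <- data.frame(method = "bud_score", day = bd, value = score,
                             observer_id = oid)
    }

    # (ii) LAI and NDVI: lagged, rescaled latent logistic + noise + outliers
    for (m in c("lai", "ndvi")) {
      keep <- stats::runif(length(sched[[m]])) >= cfg$missed_visit_prob
      dd <- sched[[m]][keep]
      if (!length(dd)) next
      rng <- if (m == "lai") cfg$lai_range else cfg$ndvi_range
      sd_m <- if (m == "lai") nz$lai_sd else nz$ndvi_sd
      v <- rng[1] + diff(rng) * latent_prop(dd, t0[i] + cfg$lags[[m]], rate[i]) +
        stats::rnorm(length(dd), 0, sd_m)
      out <- stats::runif(length(dd)) < nz$outlier_prob
      v[out] <- v[out] + stats::rnorm(sum(out), 0, nz$outlier_sd * sd_m)
      v <- pmax(v, 0)
      rows[[m]] <- data.frame(method = m, day = dd, value = v,
                              observer_id = NA_character_)
    }

    # (iii) water traps: Poisson counts of intensity integrated since the
    # previous serviced visit (missed rounds accumulate into the next)
    keep <- stats::runif(length(sched$trap)) >= cfg$missed_visit_prob
    td <- sched$trap[keep]
    if (length(td)) {
      lam <- function(t) peak_int[i] * exp(-(t - mu_cat[i])^2 / (2 * sig2))
      lo <- c(cfg$windows$trap[1] - cfg$visit_interval, td[-length(td)])
      expo <- vapply(seq_along(td), function(j) {
        days <- seq(lo[j] + 1, td[j])
        sum(lam(days))
      }, numeric(1))
      total <- stats::rpois(length(td), expo)
      ret <- pmin(cfg$fwm$cap,
                  cfg$fwm$retention0 * exp((td - mu_cat[i]) * cfg$fwm$shift / sig2))
      fwm <- stats::rbinom(length(td), total, ret)
      rows$trap <- data.frame(method = rep(c("count_total", "count_fwm"),
                                           each = length(td)),
                              day = c(td, td), value = c(total, fwm),
                              observer_id = NA_character_)
    }

    # (iv) frass: noisy integral of a unimodal biomass curve over the nominal
    # interval; missed visits are dropped rows
    keep <- stats::runif(length(sched$frass)) >= cfg$missed_visit_prob
    fd <- sched$frass[keep]
    if (length(fd)) {
      mu_f <- mu_cat[i] - cfg$frass_lead
      gmass <- vapply(fd, function(t) {
        days <- seq(t - cfg$visit_interval + 1, t)
        cfg$frass_mass_scale * peak_int[i] *
          sum(exp(-(days - mu_f)^2 / (2 * sig2)))
      }, numeric(1))
      cv <- nz$frass_cv
      mult <- if (cv > 0) stats::rlnorm(length(fd), -log(1 + cv^2) / 2,
                                        sqrt(log(1 + cv^2))) else 1
      rows$frass <- data.frame(method = "frass_mass_g", day = fd,
                               value = gmass * mult,
                               observer_id = NA_character_)
    }

    ob <- do.call(rbind, rows)
    if (!is.null(ob)) {
      ob$tree_id <- tree_id[i]; ob$species <- species[i]; ob$area <- area[i]
      obs[[i]] <- ob
    }
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  observations <- observations[, c("tree_id", "species", "area", "method",
                                   "day", "value", "observer_id")]

  # (v) herbivory: one bounded fraction per sampled tree
  hsel <- which(species %in% hb$species)
  canopy <- sample(c("lower", "middle", "upper"), length(hsel), replace = TRUE)
  can_eff <- stats::rnorm(3, 0, hb$canopy_sd)
  names(can_eff) <- c("lower", "middle", "upper")
  mu_h <- stats::plogis(stats::qlogis(herb_mu[hsel]) + can_eff[canopy])
  herb <- data.frame(tree_id = tree_id[hsel], canopy_level = canopy,
                     herbivory_frac = stats::rbeta(length(hsel),
                                                   mu_h * hb$precision,
                                                   (1 - mu_h) * hb$precision),
                     stringsAsFactors = FALSE)

  structure(list(trees = trees, observations = observations,
                 herbivory = herb, truth = truth, config = cfg),
            class = "woodland")
}

# save/restore the global RNG state so generation is a pure function of seed
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.woodland <- function(x, ...) {
  cat("Synthetic woodland:", nrow(x$trees), "trees,",
      nrow(x$observations), "observations,",
      length(unique(x$observations$method)), "methods\n")
  print(table(x$trees$species, x$trees$area))
  invisible(x)
}

#' Write a woodland to plain-text files
#'
#' Writes `observations.csv`, `trees.csv`, `herbivory.csv`, `truth.csv` and a
#' key-value `config.txt` into `dir`.
#'
#' @param w a `woodland`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_woodland <- function(w, dir) {
  stopifnot(inherits(w, "woodland"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("observations.csv", "trees.csv", "herbivory.csv",
                            "truth.csv", "config.txt"))
  utils::write.csv(w$observations, paths[1], row.names = FALSE)
  utils::write.csv(w$trees, paths[2], row.names = FALSE)
  utils::write.csv(w$herbivory, paths[3], row.names = FALSE)
  utils::write.csv(w$truth, paths[4], row.names = FALSE)
  writeLines(deparse_config(w$config), paths[5])
  invisible(paths)
}

# flat key=value serialisation with [section] headers for nested pieces
deparse_config <- function(cfg) {
  out <- character()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.data.frame(v)) {
      out <- c(out, sprintf("[%s]", nm),
               paste(names(v), collapse = ","),
               apply(v, 1, paste, collapse = ","))
    } else if (is.list(v)) {
      out <- c(out, sprintf("[%s]", nm),
               vapply(names(v), function(k)
                 sprintf("%s = %s", k, paste(format(v[[k]], digits = 15),
                                             collapse = " ")), character(1)))
    } else {
      out <- c(out, sprintf("%s = %s", nm,
                            paste(format(v, digits = 15), collapse = " ")))
    }
  }
  out
}
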