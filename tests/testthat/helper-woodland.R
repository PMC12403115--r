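# Shared fixtures, all generated in code.

# a small woodland configuration that keeps test fits cheap
tiny_config <- function(n_oak = 6L, n_birch = 4L, seed = 101L, ...) {
  woodland_config(
    species = data.frame(
      species = c("oak", "birch"), n_trees = c(n_oak, n_birch),
      mean_budburst = c(115, 104), max_stage = c(7L, 5L),
      peak_abundance = c(30, 12)),
    seed = seed, ...)
}

# single-species woodland at a chosen sample size
oak_config <- function(n, seed, ...) {
  woodland_config(
    species = data.frame(species = "oak", n_trees = as.integer(n),
                         mean_budburst = 115, max_stage = 7L,
                         peak_abundance = 30),
    seed = seed, ...)
}

# noiseless, densely-visited configuration: the analytic limit
noiseless_config <- function(n = 3L, seed = 5L) {
  woodland_config(
    species = data.frame(species = "oak", n_trees = n,
                         mean_budburst = 115, max_stage = 7L,
                         peak_abundance = 30),
    within_species_sd = 3,
    visit_interval = 1, missed_visit_prob = 0,
    noise = list(bud_section_sd = 0, observer_sd = 0, lai_sd = 0,
                 ndvi_sd = 0, outlier_prob = 0, outlier_sd = 0,
                 frass_cv = 0),
    cross_trophic = list(a = 129, b = 0.2, sd = 0),
    seed = seed)
}

# exact logistic trajectory on the proportion scale
logistic_traj <- function(t0 = 120, k = 0.3, days = seq(100, 140),
                          tree = "T1", metric = "half_ndvi") {
  phenowood:::new_trajectory(tree, metric, days,
                             plogis(k * (days - t0)), "state")
}

# fast fit settings for tests that only need point estimates
fast_fit <- sigmoid_settings(B = 50)
fast_count <- count_settings(B = 50)

# sigmoid half-date estimate for one method series of one tree
half_date_for <- function(w, id, method, settings = fast_fit) {
  s <- w$observations[w$observations$tree_id == id &
                        w$observations$method == method, ]
  tr <- switch(method,
    bud_score = normalize_bud_scores(
      s$day, s$value, w$trees$max_stage[w$trees$tree_id == id],
      tree_id = id, observer_id = s$observer_id),
    lai = normalize_minmax(s$day, s$value, "half_leaf", tree_id = id),
    ndvi = normalize_minmax(s$day, s$value, "half_ndvi", tree_id = id),
    cumulative_proportion(s$day, s$value, method, tree_id = id))
  if (tr$flag != "ok") return(NULL)
  extract_half_date(fit_sigmoid(tr, settings))
}
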