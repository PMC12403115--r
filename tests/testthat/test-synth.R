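test_that("identical config and seed reproduce the woodland exactly", {
  w1 <- generate_woodland(tiny_config(seed = 77L))
  w2 <- generate_woodland(tiny_config(seed = 77L))
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$trees, w2$trees)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$herbivory, w2$herbivory)
  w3 <- generate_woodland(tiny_config(seed = 78L))
  expect_false(identical(w1$observations, w3$observations))
})

test_that("generated streams respect their supports", {
  w <- generate_woodland(tiny_config(n_oak = 10L, seed = 3L))
  obs <- w$observations
  bud <- merge(obs[obs$method == "bud_score", ], w$trees[c("tree_id", "max_stage")])
  expect_true(all(bud$value >= 1 & bud$value <= bud$max_stage))
  cnt <- obs$value[obs$method %in% c("count_total", "count_fwm")]
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_true(all(obs$value[obs$method == "frass_mass_g"] >= 0))
  expect_true(all(w$truth$cat_peak_intensity >= 0))
  expect_true(all(w$truth$herbivory_mu > 0 & w$truth$herbivory_mu < 1))
  # FWM counts are a thinning of totals: never more moths than caterpillars
  tc <- obs[obs$method == "count_total", c("tree_id", "day", "value")]
  fwm <- obs[obs$method == "count_fwm", c("tree_id", "day", "value")]
  m <- merge(tc, fwm, by = c("tree_id", "day"))
  expect_true(all(m$value.y <= m$value.x))
})

test_that("bud scores rise with the season within each tree", {
  w <- generate_woodland(tiny_config(n_oak = 12L, seed = 9L))
  bud <- w$observations[w$observations$method == "bud_score", ]
  slopes <- vapply(split(bud, bud$tree_id), function(s)
    unname(coef(lm(value ~ day, s))[2]), numeric(1))
  expect_true(all(slopes > 0))
})

test_that("wider within-species spread produces more variable half-dates", {
  vars <- vapply(c(2, 5, 9), function(sd) {
    w <- generate_woodland(tiny_config(n_oak = 40L, n_birch = 0L, seed = 21L,
                                       within_species_sd = sd))
    var(w$truth$half_date)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(within_species_sd = -1), "within_species_sd")
  expect_error(tiny_config(missed_visit_prob = 1.2), "missed_visit_prob")
  expect_error(tiny_config(within_species_sd = NaN), "within_species_sd")
  expect_error(woodland_config(species = data.frame(
    species = "oak", n_trees = 0L, mean_budburst = 115, max_stage = 7L,
    peak_abundance = 30)), "at least one tree")
  expect_error(woodland_config(species = data.frame(
    species = "oak", n_trees = 3L, mean_budburst = 115, max_stage = 6L,
    peak_abundance = 30)), "max_stage")
})

test_that("noiseless dense sampling recovers true half-dates downstream", {
  w <- generate_woodland(noiseless_config(n = 3L))
  for (id in w$trees$tree_id) {
    tru <- w$truth$half_date[w$truth$tree_id == id]
    est <- half_date_for(w, id, "ndvi")
    expect_equal(est$half_day, tru + w$config$lags$ndvi, tolerance = 0.15)
    est_lai <- half_date_for(w, id, "lai")
    expect_equal(est_lai$half_day, tru + w$config$lags$lai, tolerance = 0.15)
  }
})

test_that("woodland round-trips through plain-text files", {
  w <- generate_woodland(tiny_config(seed = 31L))
  dir <- withr::local_tempdir()
  write_woodland(w, dir)
  obs <- read_observations(file.path(dir, "observations.csv"),
                           trees = w$trees)
  expect_equal(nrow(obs), nrow(w$observations))
  expect_equal(obs$value, w$observations$value, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "config.txt")))
})
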