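test_that("monotone pairs reach the Spearman extremes", {
  d <- data.frame(a = 1:8, b = (1:8)^2, c = -(1:8)^3)
  cm <- spearman_matrix(d, c("a", "b", "c"))
  expect_equal(cm$rho[cm$metric_a == "a" & cm$metric_b == "b"], 1)
  expect_equal(cm$rho[cm$metric_a == "a" & cm$metric_b == "c"], -1)
  M <- as.matrix(cm)
  expect_equal(M, t(M))
  expect_equal(diag(M), c(a = 1, b = 1, c = 1))
  expect_true(all(abs(cm$rho) <= 1))
})

test_that("tied data match the rank-then-Pearson oracle", {
  # fixed 10-row fixture with ties in both columns
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  b <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  cm <- spearman_matrix(data.frame(a = a, b = b), c("a", "b"))
  oracle <- cor(rank(a), rank(b))   # average ranks, then Pearson
  expect_equal(cm$rho, oracle, tolerance = 1e-12)
})

test_that("small-sample p values agree with explicit permutation enumeration", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 1, 4, 3, 6, 7)
  cm <- spearman_matrix(data.frame(a = a, b = b), c("a", "b"))
  # independent check: enumerate permutations of b by repeated sampling of
  # the full factorial via recursion-free expand over indices
  perms <- phenowood:::perm_matrix(6)
  rho_obs <- cor(a, b, method = "spearman")
  rho_all <- apply(perms, 1, function(p) cor(rank(a), rank(b)[p]))
  expect_equal(cm$p, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
  # pairwise-complete n is reported
  d <- data.frame(a = c(a, NA), b = c(b, 1))
  expect_equal(spearman_matrix(d, c("a", "b"))$n, 6L)
})

test_that("explained-variance gain saturates and recovers constructed effects", {
  set.seed(11)
  f <- factor(rep(letters[1:4], each = 25))
  mu <- c(a = 0, b = 2, c = 4, d = 6)[f]
  # response exactly determined by factor levels
  v <- variance_explained_delta(as.numeric(mu), f)
  expect_equal(v$r2_full, 1, tolerance = 1e-12)
  expect_equal(v$delta_r2, 1 - v$r2_reduced, tolerance = 1e-12)
  # constructed 70% species variance is recovered within 10 points
  eff <- scale(as.numeric(mu))[, 1] * sqrt(0.7)
  noise <- scale(rnorm(100))[, 1] * sqrt(0.3)
  v2 <- variance_explained_delta(eff + noise, f)
  expect_lt(abs(v2$delta_r2 - 0.7), 0.10)
  # pure-noise labels add nothing
  d3 <- replicate(20, {
    y <- rnorm(100)
    variance_explained_delta(y, factor(sample(letters[1:3], 100, TRUE)))$delta_r2
  })
  expect_lt(median(d3), 0.05)
  expect_true(all(d3 > -0.02))
  expect_error(variance_explained_delta(rnorm(10), factor(rep("a", 10))),
               "2 levels")
})

test_that("a noise-free linear linkage is recovered exactly", {
  x <- seq(100, 130, length.out = 20)
  d <- data.frame(tree_id = paste0("t", 1:20), tc_half_fall = 2 + 0.2 * x,
                  budburst = x, area = "Great Wood")
  expect_warning(
    m <- fit_cross_trophic_model(d, "tc_half_fall", "budburst",
                                 coords = NULL, ci_method = "wald"),
    "one sampling area")
  cf <- m$coefficients
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 2, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "budburst"], 0.2, tolerance = 1e-8)
  expect_equal(m$variance_explained, 1, tolerance = 1e-8)
})

test_that("duplicated models tie at zero delta elpd and mismatches are caught", {
  set.seed(12)
  d <- data.frame(tree_id = paste0("t", 1:24),
                  y = rnorm(24, 120, 3), x = rnorm(24, 115, 5),
                  area = rep(c("Great Wood", "Marley"), 12))
  m1 <- fit_cross_trophic_model(d, "y", "x", coords = NULL, ci_method = "wald")
  tab <- compare_models_elpd(list(a = m1, b = m1))
  expect_equal(tab$delta_elpd, c(0, 0))
  expect_true(all(compare_models_elpd(list(a = m1, b = m1))$delta_elpd <= 0))
  m2 <- fit_cross_trophic_model(d[1:20, ], "y", "x", coords = NULL,
                                ci_method = "wald")
  expect_error(compare_models_elpd(list(m1, m2)), "different row sets")
})

test_that("predictive comparison prefers the true predictor", {
  set.seed(13)
  wins <- replicate(10, {
    x <- rnorm(40, 115, 5)
    d <- data.frame(tree_id = paste0("t", 1:40), y = 100 + 0.8 * x + rnorm(40, 0, 1.5),
                    x = x, area = rep(c("Great Wood", "Marley"), 20))
    m1 <- fit_cross_trophic_model(d, "y", "x", coords = NULL, ci_method = "wald")
    m0 <- fit_cross_trophic_model(d, "y", NULL, coords = NULL, ci_method = "wald")
    tab <- compare_models_elpd(list(true = m1, null = m0))
    tab$model[1] == "true"
  })
  expect_gte(mean(wins), 0.9)
})

test_that("Moran's I matches the brute-force double-sum formula", {
  set.seed(14)
  n <- 12
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  z <- rnorm(n)
  res <- morans_i(z, coords, k = 4)
  # independent oracle: rebuild the kNN weights and evaluate the double sum
  D <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    nb <- others[order(D[i, others])][1:4]
    W[i, nb] <- 1 / 4
  }
  zc <- z - mean(z)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * zc[i] * zc[j]
  I_oracle <- (n / sum(W)) * num / sum(zc^2)
  expect_equal(res$I, I_oracle, tolerance = 1e-12)
  expect_equal(res$expected, -1 / (n - 1), tolerance = 1e-12)
})

test_that("Moran's I null mean and clustered alternative behave as expected", {
  set.seed(15)
  coords <- cbind(runif(50, 0, 1000), runif(50, 0, 1000))
  Is <- replicate(400, morans_i(rnorm(50), coords, nperm = 9)$I)
  expect_lt(abs(mean(Is) - (-1 / 49)), 0.015)
  # area-level constants on clustered coordinates: strong positive I
  cl <- rbind(cbind(rnorm(20, 0, 50), rnorm(20, 0, 50)),
              cbind(rnorm(20, 1000, 50), rnorm(20, 1000, 50)))
  v <- rep(c(0, 5), each = 20) + rnorm(40, 0, 0.1)
  res <- morans_i(v, cl)
  expect_gt(res$I, 0.5)
  expect_lte(res$p, 0.05)
})

test_that("duplicate coordinates collapse into averaged sites with a warning", {
  set.seed(16)
  coords <- cbind(c(0, 0, 100, 200, 300, 400, 500, 600, 700, 800, 900, 1000),
                  rep(0, 12))
  z <- rnorm(12)
  expect_warning(res <- morans_i(z, coords, k = 3), "duplicate")
  expect_equal(res$n, 11)
})

test_that("herbivory model recovers strong area effects and a null metric", {
  set.seed(17)
  n <- 60
  area <- rep(c("Great Wood", "ForestGEO", "Marley"), each = n / 3)
  x <- rnorm(n, 120, 5)
  eta <- -2 + c("Great Wood" = 0, "ForestGEO" = -1.2, "Marley" = 1)[area]
  y <- rbeta(n, plogis(eta) * 60, (1 - plogis(eta)) * 60)
  d <- data.frame(tree_id = paste0("t", 1:n), herbivory_frac = y,
                  half_leaf = x, area = area,
                  canopy_level = sample(c("lower", "middle", "upper"), n, TRUE))
  m <- fit_herbivory_model(d, "half_leaf", coords = NULL)
  cf <- m$coefficients
  expect_false(cf$significant[cf$term == "half_leaf"])
  expect_true(cf$significant[cf$term == ".areaMarley"])
  expect_equal(cf$estimate[cf$term == ".areaForestGEO"], -1.2, tolerance = 0.5)
  expect_true(m$variance_explained >= 0 && m$variance_explained <= 1)
  expect_error(
    fit_herbivory_model(within(d, herbivory_frac <- 0.2), "half_leaf",
                        coords = NULL),
    "all equal")
})
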