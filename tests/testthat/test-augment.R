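test_that("sigmoid neighborhood law matches its closed forms", {
  expect_identical(neighborhood_probability(1, 1), 0.5)
  expect_equal(neighborhood_probability(0, 1), 1 - 1 / (1 + exp(10)),
               tolerance = 1e-15)
  expect_equal(neighborhood_probability(2, 1), 1 - 1 / (1 + exp(-10)),
               tolerance = 1e-15)
  d <- seq(0, 3, by = 0.01)
  expect_true(all(diff(neighborhood_probability(d, 1.3)) < 0))
  expect_error(neighborhood_probability(1, 0), "positive")
  expect_error(neighborhood_probability(-1, 1), "non-negative")
})

test_that("engineered controls preserve marginals and fill the map", {
  d <- make_blobs(15, J = 4, seed = 20)
  e <- engineer_controls(d, seed = 20)
  expect_equal(ncol(e$values), 8)
  expect_equal(sum(e$provenance == "engineered"), 4)
  for (j in colnames(d$values)) {
    expect_equal(sort(e$values[, paste0(j, "_perm")]),
                 sort(e$values[, j]))
  }
  expect_equal(as.character(e$labels), as.character(d$labels))
  # constant column: permutation is the identity
  v <- cbind(a = rep(2, 10), b = rnorm(10))
  ec <- engineer_controls(tabular_dataset(v, rep(c(1, 2), 5)), seed = 1)
  expect_equal(ec$values[, "a_perm"], ec$values[, "a"])
  expect_error(engineer_controls(e), "already")
})

test_that("generation returns n*k labeled rows within 2c of their seeds", {
  d <- make_blobs(25, J = 3, seed = 21)
  cfg <- generator_config(c = 0.8, k = 4, seed = 21)
  s <- generate_points(d, cfg)
  expect_equal(nrow(s$values), 25 * 2 * 4)
  diag <- attr(s, "diagnostics")
  expect_equal(as.character(s$labels),
               as.character(d$labels[diag$seed_row]))
  expect_true(all(diag$distance <= 2 * 0.8 + 1e-12))
  # distances recomputed in standardized space match the diagnostics
  z <- scale(d$values)
  zs <- scale(s$values, center = attr(z, "scaled:center"),
              scale = attr(z, "scaled:scale"))
  dists <- sqrt(rowSums((zs - z[diag$seed_row, ])^2))
  expect_equal(dists, diag$distance, tolerance = 1e-8)
})

test_that("stratum bands map to the correct probability ranges", {
  d <- make_blobs(5, J = 2, seed = 22)
  cfg <- generator_config(c = 1.5, k = 200, seed = 22)
  s <- generate_points(d, cfg)
  diag <- attr(s, "diagnostics")
  p <- neighborhood_probability(diag$distance, 1.5)
  expect_true(all(p[diag$stratum == "core"] > 0.95))
  expect_true(all(p[diag$stratum == "intermediate"] > 0.10 &
                    p[diag$stratum == "intermediate"] < 0.95))
  expect_true(all(p[diag$stratum == "outer"] <= 0.10))
  expect_true(all(diag$distance[diag$stratum == "outer"] <= 2 * 1.5 + 1e-12))
})

test_that("generation is seed-deterministic and c-monotone", {
  d <- make_blobs(10, J = 3, seed = 23)
  s1 <- generate_points(d, generator_config(c = 1, k = 3, seed = 5))
  s2 <- generate_points(d, generator_config(c = 1, k = 3, seed = 5))
  expect_identical(s1$values, s2$values)
  # mean seed-to-synthetic distance grows with c
  means <- sapply(c(0.5, 1, 2, 4), function(cc) {
    s <- generate_points(d, generator_config(c = cc, k = 20, seed = 5))
    mean(attr(s, "diagnostics")$distance)
  })
  expect_true(all(diff(means) > 0))
})

test_that("augmentation preserves class proportions and round-trips", {
  d <- make_blobs(12, J = 2, seed = 24)
  cfg <- generator_config(c = 1, k = 3, seed = 24)
  aug <- augment_dataset(d, cfg)
  expect_equal(nrow(aug$values), 24 * (1 + 3))
  expect_equal(as.numeric(prop.table(table(aug$labels))),
               as.numeric(prop.table(table(d$labels))))
  expect_equal(sum(aug$row_origin == "generated"), 24 * 3)
  expect_equal(drop_generated(aug)$values, d$values)
  expect_error(generator_config(c = 1, k = 0), "k must be")
})
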