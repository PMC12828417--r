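test_that("gabriel graph handles the canonical small configurations", {
  # two points: always one edge
  g2 <- gabriel_graph(rbind(c(0, 0), c(3, 4)))
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$lengths, 5)

  # three collinear points: the middle point blocks the long edge
  g3 <- gabriel_graph(matrix(c(0, 1, 2), 3, 1))
  expect_equal(g3$edges, rbind(c(1, 2), c(2, 3)))

  # unit square: 4 sides, no diagonals
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  g4 <- gabriel_graph(sq)
  expect_equal(nrow(g4$edges), 4)
  expect_equal(sort(g4$lengths), rep(1, 4))

  # duplicates are removed, <2 distinct points error
  gd <- gabriel_graph(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_equal(nrow(gd$points), 2)
  expect_error(gabriel_graph(rbind(c(1, 1), c(1, 1))), "2 distinct")
})

test_that("gabriel graph equals the brute-force definition on random points", {
  set.seed(123)
  for (J in c(2, 4)) {
    pts <- matrix(runif(60 * J), 60, J)
    got <- gabriel_graph(pts)$edges
    want <- gabriel_bruteforce(pts)
    expect_equal(got[order(got[, 1], got[, 2]), ],
                 want[order(want[, 1], want[, 2]), ])
  }
})

test_that("bimodal gmm recovers well-separated components", {
  set.seed(7)
  h <- c(rnorm(2500, 0, 0.5), rnorm(2500, 8, 0.5))
  fit <- fit_bimodal_gmm(h, seed = 7)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$mu[1] - 0), 0.1)
  expect_lt(abs(fit$mu[2] - 8), 0.1)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
})

test_that("degenerate height distributions are flagged or rejected", {
  expect_error(fit_bimodal_gmm(rep(2, 50)), "zero variance")
  expect_error(fit_bimodal_gmm(c(1, 2)), "at least 10")
  set.seed(8)
  fit <- fit_bimodal_gmm(rnorm(400, 5, 1), seed = 8)
  expect_true(fit$degenerate)
})

test_that("bayes boundary matches symmetry and responds to weights", {
  expect_equal(bayes_boundary(list(pi = c(0.5, 0.5), mu = c(0, 10),
                                   sigma = c(1, 1))), 5, tolerance = 1e-9)
  # heavier left component pushes the boundary right
  t_skew <- bayes_boundary(list(pi = c(0.9, 0.1), mu = c(0, 10),
                                sigma = c(1, 1)))
  expect_gt(t_skew, 5)
  expect_error(bayes_boundary(list(pi = c(0.5, 0.5), mu = c(10, 0),
                                   sigma = c(1, 1))), "mu1 < mu2")
})

test_that("bayes boundary agrees with a dense grid-search oracle", {
  cases <- list(
    list(pi = c(0.5, 0.5), mu = c(0, 10), sigma = c(1, 2)),
    list(pi = c(0.3, 0.7), mu = c(-2, 3), sigma = c(0.5, 1.5)),
    list(pi = c(0.8, 0.2), mu = c(1, 4), sigma = c(0.7, 0.7)))
  for (gmm in cases) {
    expect_equal(bayes_boundary(gmm),
                 bayes_boundary_grid(gmm$pi, gmm$mu, gmm$sigma),
                 tolerance = 1e-6)
  }
})

test_that("critical radius separates two prototype scales", {
  # two parallel prototype chains: within-cluster edge lengths ~0.1,
  # between-cluster edges ~5; the boundary must fall between the scales
  set.seed(9)
  x <- seq(0, 2, by = 0.1) + rnorm(21, 0, 0.005)
  protos <- rbind(cbind(x, rnorm(21, 0, 0.01)),
                  cbind(x, rnorm(21, 5, 0.01)))
  g <- new_esom_grid(protos, rows = 6, cols = 7)
  g$bmu <- seq_len(42)
  est <- critical_radius(g, seed = 9)
  expect_false(est$degenerate)
  expect_gt(est$r, 0.2)
  expect_lt(est$r, 5)
})

test_that("critical radius falls back to the median height when unimodal", {
  set.seed(10)
  protos <- matrix(rnorm(60, 0, 1), 30, 2)
  g <- new_esom_grid(protos, rows = 5, cols = 6)
  g$bmu <- seq_len(30)
  est <- critical_radius(g, seed = 10)
  if (est$degenerate) {
    expect_equal(est$r, median(est$au_heights))
  }
  expect_gt(est$r, 0)
})

test_that("critical radius errors without occupied structure", {
  g <- new_esom_grid(matrix(rnorm(20), 10, 2), rows = 2, cols = 5)
  expect_error(critical_radius(g), "BMU")
  g$bmu <- rep(1L, 5)
  expect_error(critical_radius(g), "fewer than 2")
})

test_that("estimates scale linearly with the data scale", {
  set.seed(11)
  protos <- rbind(matrix(rnorm(30, 0, 0.1), 15, 2),
                  matrix(rnorm(30, 4, 0.1), 15, 2))
  for (s in c(1, 3.5)) {
    g <- new_esom_grid(protos * s, rows = 5, cols = 6)
    g$bmu <- seq_len(30)
    est <- critical_radius(g, seed = 11)
    if (s == 1) {
      base <- est
    } else {
      expect_equal(est$au_heights, base$au_heights * s, tolerance = 1e-9)
      expect_equal(est$r, base$r * s, tolerance = 1e-4)
    }
  }
})

test_that("chainlink radius lies below the inter-ring gap", {
  d <- make_chainlink(n_per_class = 250, seed = 12)
  g <- train_esom(d, rows = 12, cols = 18, epochs = 10, seed = 12)
  est <- critical_radius(g, seed = 12)
  # min distance between points of different classes, in the grid's
  # standardized space (the space the heights live in)
  Z <- sweep(sweep(d$values, 2, g$center, "-"), 2, g$scale, "/")
  D <- as.matrix(dist(Z))
  cross <- D[d$labels == 1, d$labels == 2]
  expect_gt(est$r, 0)
  expect_lt(est$r, min(cross) * 2)
})
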