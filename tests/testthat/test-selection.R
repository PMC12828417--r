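# selection tests run at reduced forest size; the decision logic is
# identical at any num_trees
test_that("a perfectly separating feature is confirmed, shadows never leak", {
  set.seed(30)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  v <- cbind(signal = y + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  d <- tabular_dataset(v, y)
  res <- boruta_select(d, max_iter = 25, seed = 30, num_trees = 100)
  expect_equal(as.character(res$decision["signal"]), "confirmed")
  expect_false(any(startsWith(names(res$decision), ".shadow.")))
  expect_setequal(names(res$decision), colnames(v))
})

test_that("pure-noise features are confirmed at most at a false-positive rate", {
  # at n = 20 some noise features carry real chance correlation with the
  # labels, so occasional confirmations are expected; the null requirement
  # is that the per-feature false-confirmation rate stays far below chance
  confirmed <- vapply(1:6, function(s) {
    set.seed(s)
    v <- matrix(rnorm(20 * 50), 20, 50)
    d <- tabular_dataset(v, rep(c(0, 1), each = 10))
    res <- boruta_select(d, max_iter = 25, seed = s, num_trees = 100)
    sum(res$decision == "confirmed")
  }, numeric(1))
  expect_lte(mean(confirmed) / 50, 0.05)
  expect_gte(mean(confirmed == 0), 0.5)
})

test_that("single-class labels are rejected", {
  d <- tabular_dataset(matrix(rnorm(20), 10, 2), rep("a", 10))
  expect_error(boruta_select(d), "classes")
})

test_that("selection frequencies are deterministic and bounded by runs", {
  set.seed(31)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  v <- cbind(signal = y + rnorm(n, 0, 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n))
  d <- tabular_dataset(v, y)
  p1 <- selection_frequencies(d, runs = 3, seed = 31, max_iter = 20,
                              num_trees = 100)
  p2 <- selection_frequencies(d, runs = 3, seed = 31, max_iter = 20,
                              num_trees = 100)
  expect_identical(p1$table, p2$table)
  expect_true(all(p1$table$selection_count >= 0 &
                    p1$table$selection_count <= 3))
  expect_equal(p1$table$selection_count[p1$table$feature == "signal"], 3L)
})

test_that("importance differences subtract counterpart counts", {
  profile <- structure(list(
    table = data.frame(
      feature = c("A", "B", "A_perm", "B_perm"),
      provenance = c("original", "original", "engineered", "engineered"),
      importance = c(5, 2, 1, 1),
      selection_count = c(100L, 40L, 0L, 40L)),
    runs = 100,
    counterpart_map = c(A = "A_perm", B = "B_perm")),
    class = "selection_profile")
  di <- delta_importance(profile)
  expect_equal(di, c(A = 100, B = 0))
  expect_error(delta_importance(profile, c(A = "missing_col")), "missing")
})

test_that("selection counts ignore column order", {
  set.seed(32)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  v <- cbind(s1 = y + rnorm(n, 0, 0.05), n1 = rnorm(n), n2 = rnorm(n))
  d1 <- tabular_dataset(v, y)
  d2 <- tabular_dataset(v[, c(3, 1, 2)], y)
  r1 <- selection_frequencies(d1, runs = 2, seed = 32, max_iter = 15,
                              num_trees = 100)
  r2 <- selection_frequencies(d2, runs = 2, seed = 32, max_iter = 15,
                              num_trees = 100)
  c1 <- setNames(r1$table$selection_count, r1$table$feature)
  c2 <- setNames(r2$table$selection_count, r2$table$feature)
  expect_equal(c1[c("s1", "n1", "n2")], c2[c("s1", "n1", "n2")])
})
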