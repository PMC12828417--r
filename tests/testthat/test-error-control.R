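test_that("bootstrap threshold reproduces degenerate cases exactly", {
  t0 <- bootstrap_threshold(a = rep(3, 5), b = rep(3, 5),
                            n_bootstrap = 2000, seed = 1)
  expect_equal(t0$l_delta, 0)
  t1 <- bootstrap_threshold(a = rep(0, 4), b = rep(1, 4),
                            n_bootstrap = 2000, seed = 1)
  expect_equal(t1$l_delta, 1)
  expect_error(bootstrap_threshold(numeric(0), 1), "non-empty")
  expect_error(bootstrap_threshold(1, 1, q = 1.2), "q must be")
})

test_that("bootstrap quantile matches exhaustive enumeration", {
  cases <- list(list(a = c(0, 1, 2), b = c(3, 4, 5)),
                list(a = c(0, 0, 1, 5), b = c(0, 2, 2, 7)),
                list(a = c(2, 2, 2, 3), b = c(1, 2, 8, 9)))
  for (cs in cases) {
    for (q in c(0.5, 0.95)) {
      got <- bootstrap_threshold(cs$a, cs$b, n_bootstrap = 1e5, q = q,
                                 seed = 99)$l_delta
      want <- exact_diff_quantile(cs$a, cs$b, q)
      # discrete distribution: the empirical quantile can land one support
      # point away only when q sits near a cdf jump; allow the adjacent value
      diffs <- sort(unique(as.vector(outer(cs$b, cs$a, "-"))))
      idx <- which(diffs == want)
      expect_true(got %in% diffs[max(1, idx - 1):min(length(diffs), idx + 1)])
      # and the cdf at the returned value covers q within Monte Carlo error
      cdf <- ecdf(as.vector(outer(cs$b, cs$a, "-")))
      expect_gte(cdf(got) + 3 * sqrt(q * (1 - q) / 1e5), q)
    }
  }
})

test_that("the threshold is monotone in the quantile level", {
  a <- c(0, 1, 1, 2, 4)
  b <- c(1, 3, 5, 6, 8)
  ls <- sapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(q) {
    bootstrap_threshold(a, b, n_bootstrap = 2e4, q = q, seed = 5)$l_delta
  })
  expect_true(all(diff(ls) >= 0))
})

test_that("stopping search honors threshold semantics on small data", {
  # strong-signal data: importance differences exceed a tiny threshold
  # already at level 1 -> recommendation 0, do not augment
  asc <- make_ascending_significance(n_v = 6, n_per_class = 10, seed = 40)
  eng <- engineer_controls(asc, seed = 40)
  tiny <- bootstrap_threshold(a = 0, b = 0.5, n_bootstrap = 1000, seed = 40)
  res0 <- find_stopping(eng, r = 1, threshold = tiny, runs = 3,
                        max_level = 3, seed = 40, max_iter = 15,
                        num_trees = 100)
  expect_equal(res0$n_gen_per_data, 0L)
  expect_false(res0$capped)
  expect_true(res0$trace$exceeded[1])

  # unreachable threshold -> capped at max_level
  huge <- bootstrap_threshold(a = 0, b = 1000, n_bootstrap = 1000, seed = 40)
  res_cap <- find_stopping(eng, r = 1, threshold = huge, runs = 2,
                           max_level = 2, seed = 40, max_iter = 10,
                           num_trees = 100)
  expect_equal(res_cap$n_gen_per_data, 2L)
  expect_true(res_cap$capped)
  expect_equal(res_cap$trace$level, c(1, 2))
})

test_that("a larger threshold never shortens the recommendation", {
  ne <- make_no_effect(n_v = 8, n_per_class = 10, seed = 41)
  eng <- engineer_controls(ne, seed = 41)
  thr_lo <- bootstrap_threshold(a = 0, b = 0.5, n_bootstrap = 1000, seed = 41)
  thr_hi <- bootstrap_threshold(a = 0, b = 1000, n_bootstrap = 1000, seed = 41)
  lo <- find_stopping(eng, r = 1, threshold = thr_lo, runs = 2,
                      max_level = 2, seed = 41, max_iter = 10,
                      num_trees = 100)
  hi <- find_stopping(eng, r = 1, threshold = thr_hi, runs = 2,
                      max_level = 2, seed = 41, max_iter = 10,
                      num_trees = 100)
  expect_gte(hi$n_gen_per_data, lo$n_gen_per_data)
})

test_that("safe_augment runs end to end and keeps its output contract", {
  asc <- make_ascending_significance(n_v = 8, n_per_class = 10, seed = 42)
  cfg <- guard_config(rows = 6, cols = 8, epochs = 4, runs = 3,
                      n_bootstrap = 2000, max_level = 1, max_iter = 12,
                      num_trees = 100, seed = 42)
  out <- safe_augment(asc, cfg)
  expect_s3_class(out$report, "run_report")
  # engineered columns never reach the output
  expect_false(any(out$data$provenance == "engineered"))
  expect_false(any(grepl("_perm$", colnames(out$data$values))))
  g <- out$report$stopping$n_gen_per_data
  if (g >= 1) {
    expect_equal(nrow(out$data$values), 20 * (1 + g))
    expect_equal(as.numeric(prop.table(table(out$data$labels))),
                 as.numeric(prop.table(table(asc$labels))))
  } else {
    expect_true(out$report$do_not_augment)
    expect_identical(out$data$values, asc$values)
  }
  expect_true(out$report$threshold$l_delta >=
                min(out$report$threshold$b_summary$Min. -
                      out$report$threshold$a_summary$Max.))
})
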