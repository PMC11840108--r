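test_that("every estimator matches literal enumeration on the 8-effect tables", {
  tabs <- make_oracle_tables()
  full <- tabs$full; rep <- tabs$rep
  alpha <- 0.05
  # frozen hand-computed expectations (critical r at n=30 is ~0.361;
  # full-significant: effects 1,2,3,8; replicated same-sign: effect 8)
  expect_equal(estimate_false_negative_rate(full, rep, alpha), 1 / 4)
  expect_equal(estimate_power(full, rep, alpha), 3 / 4)
  expect_equal(estimate_sign_error_rate(full, rep, alpha), 2 / 4)
  expect_equal(estimate_inflation_rate(full, rep, alpha, 0), 1)
  expect_equal(estimate_inflation_rate(full, rep, alpha, 1), 1)
  expect_equal(estimate_inflation_rate(full, rep, alpha, 1.5), 0)
  expect_equal(estimate_false_positive_rate(full, rep, alpha), 2 / 4)
  # and against the independent enumeration loop at several alphas
  for (a in c(0.05, 0.01, 0.001)) {
    for (m in c(0, 0.4, 1)) {
      ref <- enumerate_estimates(full, rep, a, m)
      expect_equal(estimate_false_negative_rate(full, rep, a), ref$fnr)
      expect_equal(estimate_power(full, rep, a), ref$power)
      expect_equal(estimate_sign_error_rate(full, rep, a), ref$sign_error)
      expect_equal(estimate_inflation_rate(full, rep, a, m), ref$inflation)
      expect_equal(estimate_false_positive_rate(full, rep, a), ref$fpr)
    }
  }
})

test_that("self-replication and empty denominators behave", {
  tabs <- make_oracle_tables()
  full <- tabs$full
  expect_equal(estimate_false_negative_rate(full, full, 0.05), 0)
  expect_equal(estimate_power(full, full, 0.05), 1)
  expect_equal(estimate_sign_error_rate(full, full, 0.05), 0)
  expect_equal(estimate_inflation_rate(full, full, 0.05, 0), 0) # strict >
  expect_equal(estimate_false_positive_rate(full, full, 0.05), 0)
  # no full-sample effect passes an extreme threshold: missing, not zero
  expect_true(is.na(estimate_power(full, tabs$rep, 1e-12)))
  expect_true(is.na(estimate_sign_error_rate(full, tabs$rep, 1e-12)))
  # misaligned tables are rejected
  short <- effect_table(full$r[1:4], as.numeric(full$p)[1:4], 30,
                        "resample")
  expect_error(estimate_power(full, short, 0.05), "same effects")
})

test_that("an exactly-zero replication correlation counts as a sign error", {
  r_full <- c(0.9, -0.9)
  full <- effect_table(r_full, p_two_tailed(r_full, 30), 30, "full_sample")
  rep <- effect_table(c(0, 0), c(1, 1), 30, "resample")
  expect_equal(estimate_sign_error_rate(full, rep, 0.05), 1)
})

test_that("resample_subjects keeps rows paired and is deterministic", {
  s <- make_small_sample()
  rs <- resample_subjects(s, 10, seed = 5)
  idx <- attr(rs, "indices")
  expect_length(idx, 10)
  expect_identical(rs$edges, s$edges[idx, ])
  expect_identical(rs$behaviour, s$behaviour[idx])
  expect_identical(attr(resample_subjects(s, 10, seed = 5), "indices"), idx)
  expect_identical(resample_subjects(s, 4, 1)$n_subjects, 4L)
  expect_error(resample_subjects(s, 3, 1), "size")
  expect_error(resample_subjects(s, 61, 1), "size")
})

test_that("bootstrap draws include ~63.2% distinct subjects at full size", {
  s <- make_small_sample(n_subjects = 100, n_nodes = 4, ts_length = 10)
  frac <- vapply(1:200, function(sd) {
    length(unique(attr(resample_subjects(s, 100, sd), "indices"))) / 100
  }, numeric(1))
  expected <- 1 - (1 - 1 / 100)^100
  expect_lt(abs(mean(frac) - expected), 3 * sd(frac) / sqrt(200))
})

test_that("summary-level resampling has the stated Fisher-z spread", {
  for (size in c(25, 100, 1000)) {
    r <- as.vector(resample_summary_effect(0, size, seed = size,
                                           n_draws = 1e5))
    expect_lt(abs(sd(atanh(r)) - 1 / sqrt(size - 3)) * sqrt(size - 3), 0.01)
  }
  # centred on the large-sample correlation, variance ~ 1/(size-3)
  r <- as.vector(resample_summary_effect(0.11, 1000, seed = 1,
                                         n_draws = 1e5))
  expect_equal(mean(atanh(r)), atanh(0.11), tolerance = 1e-3)
  expect_equal(var(atanh(r)) * 997, 1, tolerance = 0.02)
  # vectorised shape and input checks
  m <- resample_summary_effect(c(0, 0.1, 0.2), 50, seed = 2, n_draws = 7)
  expect_identical(dim(m), c(3L, 7L))
  expect_error(resample_summary_effect(1, 50), "r_star")
  expect_error(resample_summary_effect(0.5, 3), "size")
})

test_that("resample significance via critical r equals significance via p", {
  set.seed(21)
  r <- runif(500, -0.5, 0.5)
  for (alpha in c(0.05, 1e-3)) {
    for (n in c(25, 400)) {
      expect_identical(abs(r) > critical_r(n, alpha),
                       as.numeric(p_two_tailed(r, n)) < alpha)
    }
  }
})

test_that("probability of replication detects forced identity and rejects bad sizes", {
  s <- make_small_sample()
  v <- estimate_prob_replication(s, 30, 0.5, seed = 9)
  expect_true(is.na(v) || (v >= 0 && v <= 1))
  expect_error(estimate_prob_replication(s, 2, 0.05), "size")
  # degenerate overlap: identical in/out tables replicate perfectly
  tabs <- make_oracle_tables()
  pr <- rwrbias:::prob_replication_from_tables(tabs$full, tabs$full, 0.05)
  expect_equal(pr, 1)
})

test_that("the resampling sweep aggregates records with the stated schema", {
  s <- make_small_sample(n_subjects = 60, n_nodes = 8)
  cfg <- resampling_config(sizes = c(15, 60), n_iterations = 5,
                           alphas = c(0.05, 0.01),
                           inflation_magnitudes = c(0, 0.5), seed = 2)
  rec <- run_resampling_sweep(s, cfg)
  expect_setequal(unique(rec$estimator),
                  c("false_negative_rate", "power", "sign_error_rate",
                    "inflation_rate", "false_positive_rate",
                    "prob_replication"))
  expect_true(all(is.na(rec$value) | (rec$value >= 0 & rec$value <= 1)))
  # complementarity holds cell-by-cell
  pw <- rec[rec$estimator == "power", ]
  fnr <- rec[rec$estimator == "false_negative_rate", ]
  key <- function(d) order(d$size, d$alpha)
  expect_equal(pw$value[key(pw)], 1 - fnr$value[key(fnr)])
  # determinism under the same config
  rec2 <- run_resampling_sweep(s, cfg)
  expect_identical(rec, rec2)
  expect_error(run_resampling_sweep(s, resampling_config(sizes = 100)),
               "n_subjects")
})

test_that("config validation enforces ranges and sorts alphas descending", {
  cfg <- resampling_config(alphas = c(0.01, 0.05))
  expect_identical(cfg$alphas, c(0.05, 0.01))
  expect_error(resampling_config(sizes = 2), ">= 4")
  expect_error(resampling_config(alphas = 1.2))
  expect_error(resampling_config(inflation_magnitudes = -1))
})
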