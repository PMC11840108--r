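test_that("subject-level generator produces choose(n_nodes, 2) edges in [-1, 1]", {
  s <- make_small_sample()
  expect_s3_class(s, "subject_sample")
  expect_identical(dim(s$edges), c(60L, 28L))
  expect_length(s$behaviour, 60)
  expect_true(all(abs(s$edges) <= 1))
  # minimal configuration: 2 nodes -> a single edge
  tiny <- generate_subject_null_sample(4, 2, 3, seed = 0)
  expect_identical(dim(tiny$edges), c(4L, 1L))
  for (k in c(3, 5, 12)) {
    expect_identical(ncol(generate_subject_null_sample(4, k, 5, 1)$edges),
                     as.integer(choose(k, 2)))
  }
})

test_that("subject-level generator is deterministic and validates input", {
  a <- make_small_sample(seed = 3)
  b <- make_small_sample(seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$edges, make_small_sample(seed = 4)$edges))
  expect_error(generate_subject_null_sample(3, 5, 10, 1), "n_subjects")
  expect_error(generate_subject_null_sample(10, 1, 10, 1), "n_nodes")
  expect_error(generate_subject_null_sample(10, 5, 2, 1), "ts_length")
})

test_that("edges and behaviour are independent across regenerations", {
  # mean edge-behaviour correlation over many small regenerations ~ 0
  rs <- unlist(lapply(1:40, function(sd) {
    s <- generate_subject_null_sample(40, 6, 20, seed = sd)
    compute_brain_behaviour_effects(s)$r
  }))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 1e-3)
})

test_that("null brain-behaviour correlations have variance ~ 1/(n-3)", {
  n <- 200
  rs <- unlist(lapply(1:30, function(sd) {
    s <- generate_subject_null_sample(n, 10, 30, seed = sd)
    compute_brain_behaviour_effects(s)$r
  }))
  expect_lt(abs(var(rs) - 1 / (n - 3)) / (1 / (n - 3)), 0.1)
})

test_that("full-sample P values are uniform under the null", {
  passes <- vapply(1:20, function(sd) {
    s <- generate_subject_null_sample(100, 15, 40, seed = sd)
    tab <- compute_brain_behaviour_effects(s)
    suppressWarnings(ks.test(tab$p, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("effect computation flags degenerate columns and self-correlation", {
  s <- make_small_sample(n_subjects = 20)
  # a constant edge column has no defined correlation: excluded + warning
  s$edges[, 5] <- 0.3
  expect_warning(tab <- compute_brain_behaviour_effects(s),
                 "zero-variance")
  expect_identical(length(tab$r), 27L)
  expect_false(5L %in% tab$effect_id)
  # behaviour duplicated as an edge correlates perfectly with itself
  s2 <- make_small_sample(n_subjects = 20)
  s2$edges[, 1] <- s2$behaviour
  tab2 <- compute_brain_behaviour_effects(s2)
  expect_equal(tab2$r[1], 1)
})

test_that("scenario specs round-trip through the power machinery", {
  sp <- scenario_spec(0.5)
  expect_equal(sp$rho_true, r_critical_for_power(1000, sp$alpha, 0.5))
  expect_equal(analytical_power(sp$rho_true, 1000, sp$alpha), 0.5,
               tolerance = 1e-9)
  expect_error(scenario_spec(0.5, n_true_effects = 100,
                             n_total_effects = 100), "smaller")
})

test_that("summary-level generator honours counts, ground truth and seed", {
  sp <- scenario_spec(0.5)
  tab <- generate_summary_effects(sp, seed = 1)
  expect_identical(length(tab$r), 55278L)
  expect_identical(sum(tab$is_true_effect), 500L)
  expect_identical(sum(!tab$is_true_effect), 54778L)
  expect_identical(tab$n, 1000L)
  expect_identical(tab$r, generate_summary_effects(sp, seed = 1)$r)
  # true-effect draws centre on atanh(rho_true)
  zbar <- vapply(1:30, function(sd) {
    t2 <- generate_summary_effects(scenario_spec(0.5, n_full = 200,
                                                 n_total_effects = 2000,
                                                 n_true_effects = 200),
                                   seed = sd)
    mean(atanh(t2$r[t2$is_true_effect]))
  }, numeric(1))
  sp2 <- scenario_spec(0.5, n_full = 200, n_total_effects = 2000,
                       n_true_effects = 200)
  se <- (1 / sqrt(197)) / sqrt(30 * 200)
  expect_lt(abs(mean(zbar) - atanh(sp2$rho_true)), 3 * se)
})

test_that("pure null summary draws match subject-level null correlations", {
  # two-sample KS between the two generators' r distributions at matched n
  n <- 200
  sp <- scenario_spec(0.5, n_full = n, n_total_effects = 1000,
                      n_true_effects = 1)
  passes <- vapply(1:10, function(sd) {
    summ <- generate_summary_effects(sp, seed = sd)
    r1 <- summ$r[!summ$is_true_effect]
    subj <- generate_subject_null_sample(n, 10, 30, seed = sd + 500)
    r2 <- compute_brain_behaviour_effects(subj)$r
    suppressWarnings(ks.test(r1, r2)$p.value) > 0.05
  }, logical(1))
  expect_gt(mean(passes), 0.5)
  # null case: mean scaled Fisher z ~ 0
  znull <- atanh(generate_summary_effects(sp, seed = 3)$r) * sqrt(n - 3)
  expect_lt(abs(mean(znull)), 3 / sqrt(length(znull)) + 0.01)
})

test_that("effect tables validate their fields and serialise to CSV", {
  expect_error(effect_table(c(0.1, 0.2), 0.5, 10, "full_sample"), "length")
  expect_error(effect_table(0.1, 0.5, 10, "nope"), "label")
  expect_error(effect_table(1.5, 0.5, 10, "full_sample"), "correlations")
  expect_error(effect_table(0.1, 0, 10, "full_sample"), "p values")

  tab <- effect_table(c(0.3, -0.2), p_two_tailed(c(0.3, -0.2), 25), 25,
                      "full_sample", is_true_effect = c(TRUE, FALSE))
  path <- tempfile(fileext = ".csv")
  write_effect_table(tab, path, meta = list(seed = 7, n_nodes = 5))
  back <- read_effect_table(path)
  expect_equal(back$r, tab$r)
  expect_equal(back$p, as.numeric(tab$p))
  expect_identical(back$n, tab$n)
  expect_identical(back$is_true_effect, tab$is_true_effect)
  expect_identical(attr(back, "meta")[["seed"]], "7")
})
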