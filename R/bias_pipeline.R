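#' Default configuration of the simulation study
#'
#' Bundles every tunable of the three experiments (null resampling,
#' fresh-sample baseline, ground-truth power scenarios) with the
#' reference defaults: a large sample of 1,000 subjects with 50 nodes
#' (1,225 edges), 10 log-spaced resample sizes 25..1,000, 100
#' subject-level and 1,000 summary-level iterations, alphas from 0.05
#' down to 1e-7 for the null arm, and 11 power scenarios (1%..99%) of
#' 55,278 effects (500 true) at Bonferroni alpha = 0.05/55,278.
#'
#' @param scaled_down Use a reduced preset (200 subjects, 20 nodes,
#'   6 sizes 10..200, 20/100 iterations, 2,000 effects) that preserves
#'   the qualitative contrasts at a fraction of the cost.
#' @param seed Master seed.
#' @return A named list; see the fields in the source for the schema.
#' @export
default_config <- function(scaled_down = FALSE, seed = 1L) {
  cfg <- list(
    n_subjects = 1000L, n_nodes = 50L, ts_length = 100L,
    sizes = resample_sizes(25, 1000, 10),
    alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
    n_iterations_subject = 100L, n_iterations_summary = 1000L,
    inflation_magnitudes = seq(0, 1, by = 0.2),
    power_levels = c(0.01, seq(0.1, 0.9, by = 0.1), 0.99),
    n_total_effects = 55278L, n_true_effects = 500L, n_full = 1000L,
    scenario_alpha = 0.05 / 55278,
    prob_replication_mode = "independent",
    seed = as.integer(seed)
  )
  if (scaled_down) {
    cfg$n_subjects <- 200L
    cfg$n_nodes <- 20L
    cfg$ts_length <- 50L
    cfg$sizes <- resample_sizes(10, 200, 6)
    cfg$alphas <- c(0.05, 0.01)
    cfg$n_iterations_subject <- 20L
    cfg$n_iterations_summary <- 100L
    cfg$power_levels <- c(0.1, 0.5, 0.9)
    cfg$n_total_effects <- 2000L
    cfg$n_true_effects <- 50L
    cfg$n_full <- 200L
    cfg$scenario_alpha <- 0.05 / 2000
  }
  cfg
}

validate_config <- function(config) {
  needed <- c("n_subjects", "n_nodes", "ts_length", "sizes", "alphas",
              "n_iterations_subject", "n_iterations_summary",
              "inflation_magnitudes", "power_levels", "n_total_effects",
              "n_true_effects", "n_full", "scenario_alpha",
              "prob_replication_mode", "seed")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(config$sizes >= 4),
            max(config$sizes) <= config$n_subjects,
            all(config$alphas > 0), all(config$alphas < 1),
            all(config$power_levels > 0), all(config$power_levels < 1),
            config$n_true_effects < config$n_total_effects)
  invisible(config)
}

#' Run the null experiment: resampling sweep vs fresh-sample baseline
#'
#' Generates the large null sample, runs the resampling sweep
#' ([run_resampling_sweep()]) and the infinite-population baseline
#' ([run_fresh_sample_sweep()]) under the same configuration, and
#' optionally writes the record tables (the machine-readable versions of
#' the estimator-vs-size figures) to CSV.
#'
#' @param config A configuration list, see [default_config()].
#' @param out_dir Optional output directory for CSVs
#'   (\code{resampling_errors.csv}, \code{fresh_baseline_errors.csv},
#'   \code{analytic_expectations.csv}).
#' @param include_prob_replication Passed to both sweeps' baseline arm.
#' @return List with \code{sample}, \code{full} (effect table),
#'   \code{resampling}, \code{fresh}, \code{analytic} record data frames.
#' @export
run_null_experiment <- function(config = default_config(), out_dir = NULL,
                                include_prob_replication = TRUE) {
  validate_config(config)
  sample <- generate_subject_null_sample(
    config$n_subjects, config$n_nodes, config$ts_length,
    seed = derive_seed(config$seed, 10L))
  full <- compute_brain_behaviour_effects(sample)
  rc <- resampling_config(
    sizes = config$sizes, n_iterations = config$n_iterations_subject,
    alphas = config$alphas,
    inflation_magnitudes = config$inflation_magnitudes,
    seed = config$seed,
    prob_replication_mode = config$prob_replication_mode)
  resampling <- run_resampling_sweep(sample, rc)
  resampling$source <- "resample"
  fresh <- run_fresh_sample_sweep(
    full, rc, n_nodes = config$n_nodes, ts_length = config$ts_length,
    include_prob_replication = include_prob_replication)
  analytic <- analytic_null_expectations(config$alphas)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_records_csv(resampling,
                      file.path(out_dir, "resampling_errors.csv"), config)
    write_records_csv(fresh,
                      file.path(out_dir, "fresh_baseline_errors.csv"),
                      config)
    write_records_csv(analytic,
                      file.path(out_dir, "analytic_expectations.csv"),
                      config)
  }
  list(sample = sample, full = full, resampling = resampling,
       fresh = fresh, analytic = analytic)
}

#' Ground-truth power scenarios: estimated vs analytical power
#'
#' For each requested power level, builds the scenario's summary-level
#' large sample ([generate_summary_effects()]), takes the
#' full-sample-significant effects as replication targets, and estimates
#' power by summary-level resampling ([resample_summary_effect()]) at
#' every resample size: the proportion of targets significant again in
#' the resample (P values at the resample size), averaged over
#' iterations. Only the target effects are resampled — resampled values
#' of non-significant effects cannot enter the power estimate. The
#' estimates are compared with the analytical power curve of the
#' scenario's true effect size to give the bias.
#'
#' @param config See [default_config()].
#' @param out_dir Optional output directory (\code{power_bias.csv}).
#' @return List with \code{bias} (one record per scenario x size:
#'   estimated, analytical, bias, Monte-Carlo SE), \code{iterations}
#'   (iteration-level estimates), and \code{scenarios} (per-scenario
#'   rho_true, number of significant targets, and the empirical
#'   full-sample power over the true effects).
#' @export
run_power_bias_experiment <- function(config = default_config(),
                                      out_dir = NULL) {
  validate_config(config)
  alpha <- config$scenario_alpha
  iter_rows <- list()
  scen_rows <- list()
  for (level in config$power_levels) {
    spec <- scenario_spec(level, n_full = config$n_full, alpha = alpha,
                          n_total_effects = config$n_total_effects,
                          n_true_effects = config$n_true_effects)
    tab <- generate_summary_effects(
      spec, seed = derive_seed(config$seed, 301L, round(level * 1000)))
    sig <- tab$p < alpha
    scen_rows[[length(scen_rows) + 1L]] <- data.frame(
      power_level = level, rho_true = spec$rho_true,
      n_significant_full = sum(sig),
      empirical_full_power = mean(tab$p[tab$is_true_effect] < alpha)
    )
    if (!any(sig)) next
    r_sig <- tab$r[sig]
    for (size in config$sizes) {
      r_crit <- critical_r(size, alpha)
      set.seed(derive_seed(config$seed, 302L, round(level * 1000), size))
      # significant in the resample <=> |r| > critical r at the
      # resample size <=> p_two_tailed(r, size) < alpha
      r_res <- resample_summary_effect(r_sig, size,
                                       n_draws = config$n_iterations_summary)
      est <- colMeans(abs(r_res) > r_crit)
      iter_rows[[length(iter_rows) + 1L]] <- data.frame(
        scenario_power_level = level, rho_true = spec$rho_true,
        size = size, alpha = alpha,
        iteration = seq_along(est), estimated_power = est,
        analytical_power = analytical_power(spec$rho_true, size, alpha)
      )
    }
  }
  iterations <- do.call(rbind, iter_rows)
  bias <- summarise_bias(iterations)
  scenarios <- do.call(rbind, scen_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_records_csv(bias, file.path(out_dir, "power_bias.csv"), config)
    write_records_csv(scenarios, file.path(out_dir, "scenarios.csv"),
                      config)
  }
  list(bias = bias, iterations = iterations, scenarios = scenarios)
}

#' Aggregate iteration-level power estimates into bias records
#'
#' Averages estimated power over iterations within each
#' (scenario, size) cell, attaches the analytical power and the bias
#' (estimated minus analytical) and the Monte-Carlo standard error of
#' the mean. Deterministic given its input.
#'
#' @param iterations Data frame with columns
#'   \code{scenario_power_level}, \code{rho_true}, \code{size},
#'   \code{alpha}, \code{iteration}, \code{estimated_power},
#'   \code{analytical_power}; \code{NULL} or empty input yields an empty
#'   frame with the output schema.
#' @return One row per (scenario, size): \code{estimated_power} (mean),
#'   \code{analytical_power}, \code{bias}, \code{se},
#'   \code{n_iterations}.
#' @export
summarise_bias <- function(iterations) {
  empty <- data.frame(
    scenario_power_level = numeric(), rho_true = numeric(),
    size = integer(), alpha = numeric(), estimated_power = numeric(),
    analytical_power = numeric(), bias = numeric(), se = numeric(),
    n_iterations = integer())
  if (is.null(iterations) || nrow(iterations) == 0) return(empty)
  parts <- split(iterations,
                 interaction(iterations$scenario_power_level,
                             iterations$size, drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- !is.na(d$estimated_power)
    k <- sum(ok)
    est <- if (k) mean(d$estimated_power[ok]) else NA_real_
    data.frame(
      scenario_power_level = d$scenario_power_level[1],
      rho_true = d$rho_true[1], size = d$size[1], alpha = d$alpha[1],
      estimated_power = est,
      analytical_power = d$analytical_power[1],
      bias = est - d$analytical_power[1],
      se = if (k > 1) stats::sd(d$estimated_power[ok]) / sqrt(k)
           else NA_real_,
      n_iterations = k)
  }))
  rownames(out) <- NULL
  out[order(out$scenario_power_level, out$size), ]
}

#' Variance-convolution diagnostic of the resampling bias
#'
#' Quantifies the mechanism behind the null bias: the full-sample
#' correlations are already random (variance \eqn{\sigma_1^2 \approx
#' 1/(n-3)}), and resampling adds a second layer of sampling variability
#' (\eqn{\sigma_2^2 = 1/(size-3)}), so the pooled distribution of
#' resampled correlations has variance \eqn{\sigma_1^2 + \sigma_2^2} —
#' about 0.002 instead of 0.001 at n = size = 1,000. The widened tails
#' inflate the share of P values below 0.05. The effect with the largest
#' full-sample |r| is tracked across iterations to show its resampled
#' values centring on the full-sample value rather than on zero.
#'
#' @param sample The full \code{subject_sample}.
#' @param size Resample size (default: the full sample size).
#' @param n_iterations Resampling iterations to pool (default 100).
#' @param seed Master seed.
#' @return A \code{variance_diagnostic}: \code{sigma1_sq} (empirical
#'   variance of full-sample correlations), \code{sigma2_sq}
#'   (\eqn{1/(size-3)}), \code{predicted_var} (their sum),
#'   \code{empirical_var} (pooled resampled correlations),
#'   \code{share_p_below_05}, and \code{tracked} (effect id, full-sample
#'   r, per-iteration resampled r).
#' @export
run_variance_diagnostic <- function(sample, size = sample$n_subjects,
                                    n_iterations = 100L, seed = 1L) {
  stopifnot(inherits(sample, "subject_sample"),
            size >= 4, size <= sample$n_subjects)
  full <- compute_brain_behaviour_effects(sample)
  track_pos <- which.max(abs(full$r))
  pooled_r <- vector("list", n_iterations)
  pooled_p <- vector("list", n_iterations)
  tracked_r <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    rs <- resample_subjects(sample, size, derive_seed(seed, 401L, it))
    tab <- compute_brain_behaviour_effects(rs, label = "resample")
    al <- align_tables(full, tab)
    pooled_r[[it]] <- al$rep$r
    pooled_p[[it]] <- al$rep$p
    k <- match(full$effect_id[track_pos], al$rep$effect_id)
    tracked_r[it] <- if (is.na(k)) NA_real_ else al$rep$r[k]
  }
  pr <- unlist(pooled_r)
  pp <- unlist(pooled_p)
  s1 <- stats::var(full$r)
  s2 <- 1 / (size - 3)
  structure(
    list(sigma1_sq = s1, sigma2_sq = s2, predicted_var = s1 + s2,
         empirical_var = stats::var(pr),
         share_p_below_05 = mean(pp < 0.05),
         n_pooled = length(pr), size = as.integer(size),
         n_iterations = as.integer(n_iterations),
         tracked = list(effect_id = full$effect_id[track_pos],
                        r_full = full$r[track_pos],
                        r_resampled = tracked_r)),
    class = "variance_diagnostic"
  )
}

#' @export
print.variance_diagnostic <- function(x, ...) {
  cat(sprintf(
    paste0("variance_diagnostic (resample size %d, %d iterations)\n",
           "  sigma1^2 (full sample)   %.5f\n",
           "  sigma2^2 = 1/(size-3)    %.5f\n",
           "  predicted sigma1^2+sigma2^2  %.5f\n",
           "  empirical pooled variance    %.5f\n",
           "  share of resampled P < 0.05  %.3f\n",
           "  tracked effect %d: r_full = %.3f, mean resampled r = %.3f\n"),
    x$size, x$n_iterations, x$sigma1_sq, x$sigma2_sq, x$predicted_var,
    x$empirical_var, x$share_p_below_05, x$tracked$effect_id,
    x$tracked$r_full, mean(x$tracked$r_resampled, na.rm = TRUE)))
  invisible(x)
}
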