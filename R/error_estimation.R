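#' Configure a resampling sweep
#'
#' @param sizes Resample sizes (log-spaced by default, 25..1000).
#' @param n_iterations Iterations per size (default 100, the subject-level
#'   convention; summary-level runs use 1,000).
#' @param alphas Two-tailed significance thresholds in (0, 1); stored
#'   sorted descending.
#' @param inflation_magnitudes Relative inflation thresholds m: an effect
#'   counts as inflated when \eqn{|r_{rep}| > (1+m)|r_{full}|}.
#' @param seed Master seed for the sweep.
#' @param prob_replication_mode \code{"independent"} (two independent
#'   with-replacement draws, the default) or \code{"split"} (two disjoint
#'   halves drawn without replacement).
#' @return A \code{resampling_config} list.
#' @export
resampling_config <- function(sizes = resample_sizes(),
                              n_iterations = 100L,
                              alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-5,
                                         1e-6, 1e-7),
                              inflation_magnitudes = seq(0, 1, by = 0.2),
                              seed = 1L,
                              prob_replication_mode = c("independent",
                                                        "split")) {
  stopifnot(all(sizes >= 4), n_iterations >= 1,
            all(alphas > 0), all(alphas < 1),
            all(inflation_magnitudes >= 0))
  structure(
    list(sizes = as.integer(sort(unique(sizes))),
         n_iterations = as.integer(n_iterations),
         alphas = sort(unique(alphas), decreasing = TRUE),
         inflation_magnitudes = sort(unique(inflation_magnitudes)),
         seed = as.integer(seed),
         prob_replication_mode = match.arg(prob_replication_mode)),
    class = "resampling_config"
  )
}

#' Resample subjects with replacement
#'
#' Draws \code{size} subject indices uniformly with replacement and
#' returns the corresponding rows of the edge matrix paired with the same
#' subjects' behaviour values — the pseudo replication sample of data-driven replicability analyses.
#'
#' @param sample A \code{subject_sample}.
#' @param size Resample size, 4 <= size <= n_subjects.
#' @param seed Seed for the draw.
#' @return A \code{subject_sample} of \code{size} (possibly repeated)
#'   subjects; the drawn indices are attached as attribute
#'   \code{"indices"}.
#' @export
resample_subjects <- function(sample, size, seed = 1L) {
  stopifnot(inherits(sample, "subject_sample"))
  if (size < 4 || size > sample$n_subjects) {
    stop("size must satisfy 4 <= size <= n_subjects")
  }
  set.seed(seed)
  idx <- sample.int(sample$n_subjects, size, replace = TRUE)
  out <- structure(
    list(edges = sample$edges[idx, , drop = FALSE],
         behaviour = sample$behaviour[idx],
         n_subjects = as.integer(size), n_nodes = sample$n_nodes,
         ts_length = sample$ts_length, seed = as.integer(seed)),
    class = "subject_sample"
  )
  attr(out, "indices") <- idx
  out
}

#' Simulate resampling a summary-level effect
#'
#' Summary-statistic analogue of resampling subjects: treating the
#' large-sample correlation \code{r_star} as the population value, a
#' resampled correlation is \eqn{\tanh(z)} with
#' \eqn{z \sim N(\mathrm{atanh}(r^*), 1/\sqrt{size-3})}. P values for the
#' result are computed at \code{n = size} (degrees of freedom relative to
#' the resample size).
#'
#' @param r_star Large-sample correlation(s), \eqn{|r^*| < 1}. Vectorised.
#' @param size Resample size (>= 4).
#' @param seed Optional seed; when \code{NULL} the current RNG state is
#'   used (so callers can draw many iterations from one stream).
#' @param n_draws Number of independent draws per element of
#'   \code{r_star}.
#' @return If \code{n_draws == 1}, a vector aligned with \code{r_star};
#'   otherwise a \code{length(r_star) x n_draws} matrix.
#' @export
resample_summary_effect <- function(r_star, size, seed = NULL, n_draws = 1L) {
  if (any(abs(r_star) >= 1)) stop("|r_star| must be < 1")
  if (size < 4) stop("size must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  k <- length(r_star)
  z <- stats::rnorm(k * n_draws, mean = atanh(r_star),
                    sd = 1 / sqrt(size - 3))
  r <- tanh(z)
  if (n_draws == 1L) r else matrix(r, nrow = k, ncol = n_draws)
}

check_aligned <- function(full, rep) {
  stopifnot(inherits(full, "effect_table"), inherits(rep, "effect_table"))
  if (length(full$r) != length(rep$r) ||
      any(full$effect_id != rep$effect_id)) {
    stop("full and replication tables must describe the same effects in the same order")
  }
  invisible(TRUE)
}

# Restrict two tables to their shared effect_ids (zero-variance exclusions
# can drop effects from degenerate replication samples).
align_tables <- function(full, rep) {
  common <- intersect(full$effect_id, rep$effect_id)
  sub <- function(tab) {
    k <- match(common, tab$effect_id)
    effect_table(r = tab$r[k], p = tab$p[k], n = tab$n, label = tab$label,
                 effect_id = common,
                 is_true_effect = tab$is_true_effect[k])
  }
  list(full = sub(full), rep = sub(rep))
}

# sign with the package's convention: an exactly-zero correlation
# mismatches any sign, including zero
sign_mismatch <- function(r1, r2) sign(r1) != sign(r2) | r1 == 0 | r2 == 0

#' False negative rate of a replication sample
#'
#' Among effects significant in the full sample (\eqn{p < \alpha}), the
#' proportion that are non-significant in the replication sample. Sign
#' consistency is not required (sign errors are a separate estimator).
#'
#' @param full,rep [effect_table()]s describing the same effects in the
#'   same order.
#' @param alpha Two-tailed significance threshold.
#' @return Proportion in \[0, 1\], or \code{NA} if no full-sample effect
#'   is significant (empty denominator, never reported as 0).
#' @export
estimate_false_negative_rate <- function(full, rep, alpha) {
  check_aligned(full, rep)
  sig <- full$p < alpha
  if (!any(sig)) return(NA_real_)
  mean(rep$p[sig] >= alpha)
}

#' Statistical power estimated from a replication sample
#'
#' The complement of [estimate_false_negative_rate()]: among effects
#' significant in the full sample, the proportion significant again in
#' the replication sample.
#'
#' @inheritParams estimate_false_negative_rate
#' @return Proportion in \[0, 1\] or \code{NA} (empty denominator).
#' @export
estimate_power <- function(full, rep, alpha) {
  1 - estimate_false_negative_rate(full, rep, alpha)
}

#' Sign error rate of a replication sample
#'
#' Among effects significant in the full sample, the proportion whose
#' replication correlation has the opposite sign. An exactly-zero
#' correlation counts as a sign mismatch against any sign.
#'
#' @inheritParams estimate_false_negative_rate
#' @return Proportion in \[0, 1\] or \code{NA} (empty denominator).
#' @export
estimate_sign_error_rate <- function(full, rep, alpha) {
  check_aligned(full, rep)
  sig <- full$p < alpha
  if (!any(sig)) return(NA_real_)
  mean(sign_mismatch(full$r[sig], rep$r[sig]))
}

#' Effect-size inflation rate among replicated effects
#'
#' Among replicated effects — significant in both samples with the same
#' sign — the proportion whose replication magnitude exceeds the
#' full-sample magnitude by more than a relative margin:
#' \eqn{|r_{rep}| > (1 + m)|r_{full}|}.
#'
#' @inheritParams estimate_false_negative_rate
#' @param magnitude Relative inflation threshold m >= 0.
#' @return Proportion in \[0, 1\] or \code{NA} if no effect replicated.
#' @export
estimate_inflation_rate <- function(full, rep, alpha, magnitude = 0) {
  check_aligned(full, rep)
  stopifnot(magnitude >= 0)
  repl <- full$p < alpha & rep$p < alpha &
    !sign_mismatch(full$r, rep$r)
  if (!any(repl)) return(NA_real_)
  mean(abs(rep$r[repl]) > (1 + magnitude) * abs(full$r[repl]))
}

#' False positive rate of a replication sample
#'
#' Among effects NOT significant in the full sample, the proportion that
#' are significant in the replication sample.
#'
#' @inheritParams estimate_false_negative_rate
#' @return Proportion in \[0, 1\] or \code{NA} (empty denominator).
#' @export
estimate_false_positive_rate <- function(full, rep, alpha) {
  check_aligned(full, rep)
  nonsig <- full$p >= alpha
  if (!any(nonsig)) return(NA_real_)
  mean(rep$p[nonsig] < alpha)
}

# Draw the in-/out-of-sample pair for probability of replication.
draw_subsample_pair <- function(sample, size, seed,
                                mode = c("independent", "split")) {
  mode <- match.arg(mode)
  n <- sample$n_subjects
  set.seed(seed)
  if (mode == "independent") {
    idx_in <- sample.int(n, size, replace = TRUE)
    idx_out <- sample.int(n, size, replace = TRUE)
  } else {
    if (2 * size > n) stop("split mode requires 2*size <= n_subjects")
    perm <- sample.int(n, 2 * size, replace = FALSE)
    idx_in <- perm[seq_len(size)]
    idx_out <- perm[size + seq_len(size)]
  }
  list(idx_in = idx_in, idx_out = idx_out)
}

subset_sample <- function(sample, idx) {
  structure(
    list(edges = sample$edges[idx, , drop = FALSE],
         behaviour = sample$behaviour[idx],
         n_subjects = length(idx), n_nodes = sample$n_nodes,
         ts_length = sample$ts_length, seed = sample$seed),
    class = "subject_sample"
  )
}

# Multi-alpha probability of replication from a given pair of tables.
prob_replication_from_tables <- function(tab_in, tab_out, alphas) {
  al <- align_tables(tab_in, tab_out)
  vapply(alphas, function(alpha) {
    sig <- al$full$p < alpha
    if (!any(sig)) return(NA_real_)
    mean(al$rep$p[sig] < alpha &
           !sign_mismatch(al$full$r[sig], al$rep$r[sig]))
  }, numeric(1))
}

#' Probability of replication between two subsamples
#'
#' Draws an "in-sample" and an equally sized "out-of-sample" subsample
#' from the full dataset (each with replacement, independently, by
#' default) and returns, among effects significant in the in-sample, the
#' proportion significant with the same sign in the out-of-sample.
#' P values in both subsamples use the subsample size.
#'
#' @param full_sample A \code{subject_sample}.
#' @param size Subsample size, 4 <= size <= n_subjects.
#' @param alpha Two-tailed significance threshold.
#' @param seed Seed for the two draws.
#' @param mode See [resampling_config()].
#' @return Proportion in \[0, 1\] or \code{NA} (no significant in-sample
#'   effect).
#' @export
estimate_prob_replication <- function(full_sample, size, alpha, seed = 1L,
                                      mode = c("independent", "split")) {
  stopifnot(inherits(full_sample, "subject_sample"))
  if (size < 4 || size > full_sample$n_subjects) {
    stop("size must satisfy 4 <= size <= n_subjects")
  }
  pair <- draw_subsample_pair(full_sample, size, seed, match.arg(mode))
  tab_in <- compute_brain_behaviour_effects(
    subset_sample(full_sample, pair$idx_in), label = "in_sample")
  tab_out <- compute_brain_behaviour_effects(
    subset_sample(full_sample, pair$idx_out), label = "out_of_sample")
  prob_replication_from_tables(tab_in, tab_out, alpha)
}

# One iteration's estimates for every estimator x alpha (x magnitude),
# returned as a long data frame with the denominator sizes.
evaluate_estimators <- function(full, rep, alphas, magnitudes) {
  al <- align_tables(full, rep)
  f <- al$full
  rp <- al$rep
  rows <- vector("list", length(alphas))
  for (j in seq_along(alphas)) {
    alpha <- alphas[j]
    sig <- f$p < alpha
    nsig <- sum(sig)
    fnr <- if (nsig) mean(rp$p[sig] >= alpha) else NA_real_
    sgn <- if (nsig) mean(sign_mismatch(f$r[sig], rp$r[sig])) else NA_real_
    nonsig <- !sig
    fpr <- if (any(nonsig)) mean(rp$p[nonsig] < alpha) else NA_real_
    repl <- sig & rp$p < alpha & !sign_mismatch(f$r, rp$r)
    nrepl <- sum(repl)
    infl <- vapply(magnitudes, function(m) {
      if (nrepl) mean(abs(rp$r[repl]) > (1 + m) * abs(f$r[repl]))
      else NA_real_
    }, numeric(1))
    rows[[j]] <- data.frame(
      estimator = c("false_negative_rate", "power", "sign_error_rate",
                    "false_positive_rate",
                    rep("inflation_rate", length(magnitudes))),
      alpha = alpha,
      magnitude = c(NA, NA, NA, NA, magnitudes),
      value = c(fnr, if (nsig) 1 - fnr else NA_real_, sgn, fpr, infl),
      n_eligible = c(nsig, nsig, nsig, sum(nonsig),
                     rep(nrepl, length(magnitudes)))
    )
  }
  do.call(rbind, rows)
}

# Average iteration-level estimates into one record per
# (estimator, size, alpha, magnitude) cell, with Monte-Carlo SEs.
aggregate_records <- function(iter_df) {
  if (nrow(iter_df) == 0) {
    return(data.frame(estimator = character(), size = integer(),
                      alpha = numeric(), magnitude = numeric(),
                      value = numeric(), se = numeric(),
                      n_iterations = integer(), n_eligible = numeric()))
  }
  key <- interaction(iter_df$estimator, iter_df$size, iter_df$alpha,
                     ifelse(is.na(iter_df$magnitude), -1,
                            iter_df$magnitude), drop = TRUE)
  parts <- split(iter_df, key)
  out <- lapply(parts, function(d) {
    ok <- !is.na(d$value)
    k <- sum(ok)
    data.frame(
      estimator = d$estimator[1], size = d$size[1], alpha = d$alpha[1],
      magnitude = d$magnitude[1],
      value = if (k) mean(d$value[ok]) else NA_real_,
      se = if (k > 1) stats::sd(d$value[ok]) / sqrt(k) else NA_real_,
      n_iterations = k, n_eligible = mean(d$n_eligible)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$estimator, out$size, -out$alpha, out$magnitude), ]
}

#' Run the full resampling sweep over sizes, iterations and thresholds
#'
#' For every (size, iteration) cell: resample subjects with replacement,
#' recompute brain-behaviour correlations (P values at the resample
#' size), and evaluate every estimator at every alpha (and inflation
#' magnitude); probability of replication draws its own subsample pair.
#' Cells whose denominator is empty (e.g. no full-sample effect passes a
#' strict alpha) yield missing values, never zeros. Each cell uses a
#' child seed derived from the master seed, so results are reproducible
#' and independent of loop order.
#'
#' @param sample The full \code{subject_sample}.
#' @param config A [resampling_config()].
#' @return A data frame of iteration-averaged records: \code{estimator},
#'   \code{size}, \code{alpha}, \code{magnitude}, \code{value},
#'   \code{se} (Monte-Carlo standard error), \code{n_iterations}
#'   (non-missing iterations), \code{n_eligible} (mean denominator).
#' @export
run_resampling_sweep <- function(sample, config = resampling_config()) {
  stopifnot(inherits(sample, "subject_sample"),
            inherits(config, "resampling_config"))
  if (max(config$sizes) > sample$n_subjects) {
    stop("all resample sizes must be <= n_subjects")
  }
  full <- compute_brain_behaviour_effects(sample)
  iter_rows <- list()
  for (size in config$sizes) {
    for (it in seq_len(config$n_iterations)) {
      rs <- resample_subjects(sample, size,
                              derive_seed(config$seed, 101L, size, it))
      rep_tab <- compute_brain_behaviour_effects(rs, label = "resample")
      est <- evaluate_estimators(full, rep_tab, config$alphas,
                                 config$inflation_magnitudes)
      pr <- estimate_prob_replication(
        sample, size, config$alphas,
        seed = derive_seed(config$seed, 102L, size, it),
        mode = config$prob_replication_mode)
      est <- rbind(est, data.frame(
        estimator = "prob_replication", alpha = config$alphas,
        magnitude = NA_real_, value = pr,
        n_eligible = NA_real_))
      est$size <- size
      est$iteration <- it
      iter_rows[[length(iter_rows) + 1L]] <- est
    }
  }
  aggregate_records(do.call(rbind, iter_rows))
}
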