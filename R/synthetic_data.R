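#' Simulate a subject-level null sample
#'
#' Generates the "large sample" of a simulated brain-wide association
#' study in which the null hypothesis is true for every effect. Each
#' subject gets \code{n_nodes} independent standard-normal time series of
#' length \code{ts_length}; the subject's edges are all pairwise Pearson
#' correlations between those series (functional-connectivity style, so
#' \code{choose(n_nodes, 2)} edges, each in \[-1, 1\]). The behavioural
#' factor is an independent standard-normal draw per subject, generated
#' from a separate random stream, so every edge-behaviour population
#' correlation is exactly zero.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_nodes Number of node time series per subject (>= 2); 50 nodes
#'   give the 1,225 edges of the reference configuration.
#' @param ts_length Length of each node time series (>= 3). Immaterial
#'   under the null (any length leaves the edge-behaviour correlations
#'   null); exposed for completeness.
#' @param seed Master seed; edge and behaviour streams are derived from it.
#' @return A \code{subject_sample}: list with \code{edges}
#'   (\code{n_subjects} x \code{n_edges} matrix), \code{behaviour}
#'   (length-\code{n_subjects} vector), and the generating parameters.
#' @export
#' @examples
#' s <- generate_subject_null_sample(50, n_nodes = 10, ts_length = 20, seed = 1)
#' dim(s$edges) # 50 x 45
generate_subject_null_sample <- function(n_subjects, n_nodes = 50,
                                         ts_length = 100, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 4) {
    stop("n_subjects must be a single integer >= 4")
  }
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 2) {
    stop("n_nodes must be a single integer >= 2")
  }
  if (!is.numeric(ts_length) || length(ts_length) != 1 || ts_length < 3) {
    stop("ts_length must be a single integer >= 3")
  }
  n_subjects <- as.integer(n_subjects)
  n_nodes <- as.integer(n_nodes)
  ts_length <- as.integer(ts_length)
  n_edges <- choose(n_nodes, 2)
  ut <- upper.tri(diag(n_nodes))

  set.seed(derive_seed(seed, 1L))
  edges <- matrix(NA_real_, n_subjects, n_edges)
  for (i in seq_len(n_subjects)) {
    ts <- matrix(stats::rnorm(ts_length * n_nodes), ts_length, n_nodes)
    edges[i, ] <- stats::cor(ts)[ut]
  }
  set.seed(derive_seed(seed, 2L))
  behaviour <- stats::rnorm(n_subjects)

  structure(
    list(edges = edges, behaviour = behaviour, n_subjects = n_subjects,
         n_nodes = n_nodes, ts_length = ts_length, seed = as.integer(seed)),
    class = "subject_sample"
  )
}

#' @export
print.subject_sample <- function(x, ...) {
  cat(sprintf(
    "subject_sample: %d subjects x %d edges (%d nodes, ts length %d), seed %d\n",
    x$n_subjects, ncol(x$edges), x$n_nodes, x$ts_length, x$seed))
  invisible(x)
}

#' Construct an effect table
#'
#' An effect table holds one row per brain-behaviour effect: the Pearson
#' correlation \code{r}, its two-tailed parametric P value at sample size
#' \code{n}, and a label saying which kind of sample the effects came
#' from. P values must be consistent with \code{r} and \code{n} under
#' [p_two_tailed()].
#'
#' @param r Correlations in \[-1, 1\].
#' @param p Two-tailed P values in (0, 1], same length as \code{r}.
#' @param n Sample size the correlations were computed at.
#' @param label One of \code{"full_sample"}, \code{"resample"},
#'   \code{"fresh_sample"}, \code{"in_sample"}, \code{"out_of_sample"}.
#' @param effect_id Integer identifiers (default sequential).
#' @param is_true_effect Optional logical ground-truth mask, carried as
#'   metadata only — estimators never see it.
#' @return An \code{effect_table} object.
#' @export
effect_table <- function(r, p, n, label, effect_id = seq_along(r),
                         is_true_effect = NULL) {
  labels <- c("full_sample", "resample", "fresh_sample", "in_sample",
              "out_of_sample")
  if (!is.character(label) || length(label) != 1 || !label %in% labels) {
    stop("label must be one of: ", paste(labels, collapse = ", "))
  }
  if (length(r) != length(p)) stop("r and p must have equal length")
  if (length(effect_id) != length(r)) stop("effect_id length mismatch")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(p <= 0) || any(p > 1)) stop("p values must lie in (0, 1]")
  if (!is.null(is_true_effect) && length(is_true_effect) != length(r)) {
    stop("is_true_effect length mismatch")
  }
  structure(
    list(effect_id = as.integer(effect_id), r = as.numeric(r),
         p = as.numeric(p), n = as.integer(n), label = label,
         is_true_effect = is_true_effect),
    class = "effect_table"
  )
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("effect_table (%s): %d effects at n = %d\n",
              x$label, length(x$r), x$n))
  if (!is.null(x$is_true_effect)) {
    cat(sprintf("  ground truth: %d true, %d null\n",
                sum(x$is_true_effect), sum(!x$is_true_effect)))
  }
  invisible(x)
}

#' @export
as.data.frame.effect_table <- function(x, ...) {
  data.frame(
    effect_id = x$effect_id, r = x$r, p = as.numeric(x$p), n = x$n,
    label = x$label,
    is_true_effect = if (is.null(x$is_true_effect)) NA else x$is_true_effect
  )
}

#' Brain-behaviour correlations of a subject sample
#'
#' Correlates every edge column with the behavioural factor across
#' subjects and attaches two-tailed parametric P values at the sample's
#' size. Edge columns with zero variance (possible only in degenerate
#' resamples, e.g. the same subject drawn repeatedly) yield an undefined
#' correlation and are excluded with a warning; remaining effects keep
#' their original \code{effect_id}.
#'
#' @param sample A \code{subject_sample} with >= 4 subjects.
#' @param label Label for the resulting table (default
#'   \code{"full_sample"}).
#' @return An [effect_table()] with one effect per retained edge.
#' @export
compute_brain_behaviour_effects <- function(sample, label = "full_sample") {
  stopifnot(inherits(sample, "subject_sample"))
  n <- sample$n_subjects
  if (n < 4) stop("sample must contain at least 4 subjects")
  r <- suppressWarnings(as.vector(stats::cor(sample$edges, sample$behaviour)))
  keep <- is.finite(r)
  if (!all(keep)) {
    warning(sprintf("excluding %d zero-variance edge(s) of %d",
                    sum(!keep), length(r)))
  }
  id <- which(keep)
  effect_table(r = r[keep], p = p_two_tailed(r[keep], n), n = n,
               label = label, effect_id = id)
}

#' Define a ground-truth power scenario
#'
#' A scenario fixes a population of summary-level effects: mostly null,
#' plus a block of true effects whose common effect size is derived by
#' inverse power analysis so that the full-sample significance test has
#' the requested power at \code{(n_full, alpha)}.
#'
#' @param power_level Target power of the true effects at the full sample
#'   size, in (0, 1).
#' @param n_full Full (large) sample size (default 1000).
#' @param alpha Significance threshold; default Bonferroni-corrected
#'   \code{0.05 / 55278}.
#' @param n_total_effects Total number of effects (default 55,278, i.e.
#'   \code{choose(333, 2)}).
#' @param n_true_effects Number of true effects (default 500, ~1%).
#' @return A \code{scenario_spec} with the derived \code{rho_true}.
#' @export
#' @examples
#' scenario_spec(0.5)$rho_true
scenario_spec <- function(power_level, n_full = 1000L,
                          alpha = 0.05 / 55278,
                          n_total_effects = 55278L,
                          n_true_effects = 500L) {
  stopifnot(power_level > 0, power_level < 1, n_full >= 4,
            alpha > 0, alpha < 1)
  if (n_true_effects >= n_total_effects) {
    stop("n_true_effects must be smaller than n_total_effects")
  }
  structure(
    list(power_level = power_level,
         rho_true = r_critical_for_power(n_full, alpha, power_level),
         n_total_effects = as.integer(n_total_effects),
         n_true_effects = as.integer(n_true_effects),
         n_full = as.integer(n_full), alpha = alpha),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario_spec: power %.3g at n = %d, alpha = %.3g -> rho_true = %.4f (%d/%d true effects)\n",
    x$power_level, x$n_full, x$alpha, x$rho_true, x$n_true_effects,
    x$n_total_effects))
  invisible(x)
}

#' Simulate a summary-statistic large sample with known ground truth
#'
#' Draws a large sample of Pearson correlations directly on the Fisher z
#' scale: each effect's z is normal with standard deviation
#' \eqn{1/\sqrt{n_{full}-3}} and mean 0 (null effects) or
#' \eqn{\mathrm{atanh}(\rho_{true})} (true effects), then mapped back by
#' \eqn{\tanh}. The null effects are drawn first and the last
#' \code{n_true_effects} of them replaced by true-effect draws; the
#' ground-truth mask is carried as metadata only.
#'
#' @param spec A [scenario_spec()].
#' @param seed Master seed.
#' @return An [effect_table()] at \code{n = n_full} with
#'   \code{is_true_effect} set.
#' @export
generate_summary_effects <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (abs(spec$rho_true) >= 1) stop("rho_true must lie in (-1, 1)")
  n_null <- spec$n_total_effects - spec$n_true_effects
  mask <- c(rep(FALSE, n_null), rep(TRUE, spec$n_true_effects))
  set.seed(derive_seed(seed, 3L))
  z <- stats::rnorm(spec$n_total_effects,
                    mean = ifelse(mask, atanh(spec$rho_true), 0),
                    sd = 1 / sqrt(spec$n_full - 3))
  r <- tanh(z)
  effect_table(r = r, p = p_two_tailed(r, spec$n_full), n = spec$n_full,
               label = "full_sample", is_true_effect = mask)
}
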