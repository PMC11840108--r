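#' Fresh-sample (infinite population) baseline sweep
#'
#' The ground-truth comparator for the resampling sweep: for every
#' (size, iteration) cell a brand-new null sample of that size is
#' generated — never resampled — and every estimator is evaluated against
#' the fixed full-sample table. This corresponds to drawing replication
#' samples from an infinite population in which the null is true, so the
#' estimates have known analytic values ([analytic_null_expectations()]).
#'
#' @param full The reference full-sample [effect_table()].
#' @param config A [resampling_config()]; its sizes/iterations/alphas are
#'   reused.
#' @param n_nodes,ts_length Generator settings for the fresh samples;
#'   match the reference sample's.
#' @param include_prob_replication Also estimate probability of
#'   replication from a second independent fresh sample per cell
#'   (doubles generation cost; default TRUE).
#' @return A data frame with the same record schema as
#'   [run_resampling_sweep()] plus \code{source = "fresh_sample"}.
#' @export
run_fresh_sample_sweep <- function(full, config = resampling_config(),
                                   n_nodes = 50, ts_length = 100,
                                   include_prob_replication = TRUE) {
  stopifnot(inherits(full, "effect_table"),
            inherits(config, "resampling_config"))
  iter_rows <- list()
  for (size in config$sizes) {
    for (it in seq_len(config$n_iterations)) {
      fresh <- generate_subject_null_sample(
        size, n_nodes = n_nodes, ts_length = ts_length,
        seed = derive_seed(config$seed, 201L, size, it))
      rep_tab <- compute_brain_behaviour_effects(fresh,
                                                 label = "fresh_sample")
      est <- evaluate_estimators(full, rep_tab, config$alphas,
                                 config$inflation_magnitudes)
      if (include_prob_replication) {
        fresh2 <- generate_subject_null_sample(
          size, n_nodes = n_nodes, ts_length = ts_length,
          seed = derive_seed(config$seed, 202L, size, it))
        out_tab <- compute_brain_behaviour_effects(fresh2,
                                                   label = "out_of_sample")
        pr <- prob_replication_from_tables(rep_tab, out_tab, config$alphas)
        est <- rbind(est, data.frame(
          estimator = "prob_replication", alpha = config$alphas,
          magnitude = NA_real_, value = pr, n_eligible = NA_real_))
      }
      est$size <- size
      est$iteration <- it
      iter_rows[[length(iter_rows) + 1L]] <- est
    }
  }
  rec <- aggregate_records(do.call(rbind, iter_rows))
  rec$source <- "fresh_sample"
  rec
}

#' Analytic expectations of the error estimators under the null
#'
#' When replication samples are true fresh draws from a null population,
#' every estimator has a closed-form expectation determined by the
#' significance threshold alone: the false negative rate is
#' \eqn{1-\alpha}, power and the false positive rate are \eqn{\alpha},
#' the sign error rate is 1/2 (the replication sign is random), the
#' magnitude-0 inflation rate is 1/2 (the replication magnitude is
#' exchangeable with the original), and the probability of replication
#' is \eqn{\alpha} (or \eqn{\alpha/2} when sign consistency is
#' required of the definition — it is, by default, so see
#' \code{sign_required}).
#'
#' @param alpha Significance threshold(s) in (0, 1).
#' @param sign_required Whether the probability-of-replication definition
#'   requires the replicated sign to match. The package's estimator does
#'   require it, making its fresh-sample expectation \eqn{\alpha/2};
#'   with \code{FALSE} the comparator is \eqn{\alpha}.
#' @return A data frame of analytic records (\code{source = "analytic"}).
#' @export
#' @examples
#' analytic_null_expectations(0.05)
analytic_null_expectations <- function(alpha, sign_required = TRUE) {
  stopifnot(all(alpha > 0), all(alpha < 1))
  out <- do.call(rbind, lapply(alpha, function(a) {
    data.frame(
      estimator = c("false_negative_rate", "power", "sign_error_rate",
                    "inflation_rate", "prob_replication",
                    "false_positive_rate"),
      alpha = a,
      magnitude = c(NA, NA, NA, 0, NA, NA),
      value = c(1 - a, a, 0.5, 0.5, if (sign_required) a / 2 else a, a)
    )
  }))
  out$source <- "analytic"
  out
}
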