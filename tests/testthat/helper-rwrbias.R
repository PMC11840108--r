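# Shared fixtures, built in code at test time.

# A small subject-level null sample (60 subjects, 8 nodes -> 28 edges),
# regenerated deterministically where needed.
make_small_sample <- function(n_subjects = 60, n_nodes = 8, ts_length = 30,
                              seed = 42) {
  generate_subject_null_sample(n_subjects, n_nodes, ts_length, seed)
}

# Hand-built 8-effect full/replication pair covering every
# significance/sign combination at alpha = 0.05, n = 30
# (critical r ~ 0.361).
make_oracle_tables <- function() {
  r_full <- c(0.5, -0.6, 0.7, 0.1, -0.2, 0.3, 0.05, -0.4)
  r_rep <- c(0.1, 0.6, -0.65, 0.5, -0.05, 0.0, 0.6, -0.9)
  list(
    full = effect_table(r_full, p_two_tailed(r_full, 30), 30, "full_sample"),
    rep = effect_table(r_rep, p_two_tailed(r_rep, 30), 30, "resample")
  )
}

# Literal per-effect enumeration of every estimator definition,
# independent of the package's vectorised code paths.
enumerate_estimates <- function(full, rep, alpha, magnitude = 0) {
  n_sig <- 0; n_fn <- 0; n_sign <- 0
  n_nonsig <- 0; n_fp <- 0
  n_repl <- 0; n_infl <- 0
  for (i in seq_along(full$r)) {
    fsig <- full$p[i] < alpha
    rsig <- rep$p[i] < alpha
    same_sign <- sign(full$r[i]) == sign(rep$r[i]) &&
      full$r[i] != 0 && rep$r[i] != 0
    if (fsig) {
      n_sig <- n_sig + 1
      if (!rsig) n_fn <- n_fn + 1
      if (!same_sign) n_sign <- n_sign + 1
      if (rsig && same_sign) {
        n_repl <- n_repl + 1
        if (abs(rep$r[i]) > (1 + magnitude) * abs(full$r[i])) {
          n_infl <- n_infl + 1
        }
      }
    } else {
      n_nonsig <- n_nonsig + 1
      if (rsig) n_fp <- n_fp + 1
    }
  }
  list(
    fnr = if (n_sig) n_fn / n_sig else NA_real_,
    power = if (n_sig) 1 - n_fn / n_sig else NA_real_,
    sign_error = if (n_sig) n_sign / n_sig else NA_real_,
    inflation = if (n_repl) n_infl / n_repl else NA_real_,
    fpr = if (n_nonsig) n_fp / n_nonsig else NA_real_
  )
}
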