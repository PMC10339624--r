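# Shared fixture builders. Everything is generated in code at test time;
# scales are kept small so the whole suite stays quick.

# a planted cohort whose single causal CpG is calibrated to a target
# univariate R^2
planted_cohort <- function(n = 300, p = 500, target_r2 = 0.5, seed = 1,
                           n_linear = 1, n_nonlinear = 0, ...) {
  base <- cohort_config(n_samples = n, n_cpgs = p,
                        n_causal_linear = n_linear,
                        n_causal_nonlinear = n_nonlinear,
                        seed = seed, ...)
  es <- calibrate_effect_scale(target_r2, config = base)
  generate_cohort(cohort_config(n_samples = n, n_cpgs = p,
                                n_causal_linear = n_linear,
                                n_causal_nonlinear = n_nonlinear,
                                effect_scale = es, seed = seed, ...))
}

null_cohort <- function(n = 300, p = 500, seed = 1, ...) {
  generate_cohort(cohort_config(n_samples = n, n_cpgs = p,
                                n_causal_linear = 0, n_causal_nonlinear = 0,
                                seed = seed, ...))
}

# tiny deterministic regression matrix with named columns
toy_matrix <- function(n, p, seed = 1, prefix = "f") {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.05, 0.95), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("%s%03d", prefix, seq_len(p))))
  X
}
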