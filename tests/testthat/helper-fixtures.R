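# Shared fixtures, built in code.

# exact logistic curve at the phosphate truths, one replicate, no noise
noiseless_curve <- function(substrate = "phosphate", days = 0:28) {
  cfg <- sim_config(noise_cv = 0, seed = 1)
  dplyr::filter(
    simulate_growth_curves(cfg, n_rep = 1, sampling = days),
    .data$substrate == !!substrate
  )
}

# closed-form logistic, independent of the generator internals
logistic_ref <- function(t, mu, K, N0) {
  K * N0 * exp(mu * t) / (K + N0 * (exp(mu * t) - 1))
}

# group-value table mimicking per-cell formate across the four P sources:
# reference-level means for phosphate/phosphite, elevated for MPn/HMPn
formate_groups <- function() {
  tibble::tibble(
    group = rep(c("phosphate", "phosphite", "MPn", "HMPn"), each = 3),
    value = c(
      27.1, 26.8, 27.3,
      26.5, 27.4, 27.0,
      48.0, 47.8, 48.2,
      47.9, 48.1, 48.0
    )
  )
}

# 3x3 one-way layout small enough to hand-check the sums of squares:
# group means 2, 3, 7; grand mean 4; SSB = 3*(4+1+9) = 42; SSW = 2*3 = 6
anova_fixture <- function() {
  tibble::tibble(
    group = rep(c("a", "b", "c"), each = 3),
    value = c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  )
}
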