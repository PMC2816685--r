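# Shared fixtures: a small battery of parameter sets covering every model
# family, and a numeric differentiator for slope checks.

param_battery <- function() {
  list(
    asym      = asymptote_params(alpha = 0.5, d = 0.02),
    asym_tau  = asymptote_params(alpha = 0.3, d = 0.05, tau = 2),
    twopop    = multipop_params(alpha = c(0.5, 0.0095), p = c(0.001, 1)),
    twopop_z  = multipop_params(alpha = c(0.4, 0.3), p = c(0, 0.05)),
    gamma_sk  = gamma_params(pbar = 0.01, k = 0.3),
    gamma_1   = gamma_params(pbar = 0.01, k = 1),
    gamma_big = gamma_params(pbar = 0.01, k = 50, alpha = 0.8),
    expo      = exponential_params(pbar_sub = 0.02, alpha = 0.5),
    expo_full = exponential_params(pbar_sub = 0.01),
    tgam      = trunc_gamma_params(pbar = 0.01, k = 0.3, pmax = 1)
  )
}

num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x)) / h

noiseless_dataset <- function(params, T_label, subject = "s1") {
  generate_dataset(synthetic_config(params, T_label, noise_sd = 0,
                                    subject = subject))
}
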