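# Shared fixtures, built in code.

debye_params <- function(eps_inf = 5, delta_eps = 70, tau_ps = 8) {
  cc_parameters(eps_inf = eps_inf, delta_eps = delta_eps, tau_ps = tau_ps,
                alpha = 1, sigma_dc = 0)
}

milk_params <- function() {
  cc_parameters(eps_inf = 5.5, delta_eps = 68, tau_ps = 9,
                alpha = 0.985, sigma_dc = 0.9)
}

# latent classifier features for one reproductive stage
latent_features <- function(n, stage, seed) {
  solids_to_params(sample_milk_solids(n, seed = seed), stage,
                   seed = seed + 1)[, c("delta_eps", "tau_ps",
                                        "alpha", "sigma_dc")]
}

# seeded label shuffle for permutation-null checks
with_seed_shuffle <- function(labels, seed) {
  set.seed(seed)
  sample(labels)
}

# two-class latent feature pool mimicking the pooled measurement sets
latent_pool <- function(n_per_class, seed) {
  f_non <- latent_features(n_per_class, "before", seed)
  f_pre <- latent_features(n_per_class, "stage3", seed + 1000)
  list(features = rbind(f_non, f_pre),
       labels = rep(c(FALSE, TRUE), each = n_per_class))
}
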