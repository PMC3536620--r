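# Small builders shared across tests.

tiny_table <- function(values, group = "g", regions = NULL) {
  if (!is.null(regions)) rownames(values) <- regions
  activity_table(values, group)
}

# Two-condition cohort with a planted mean shift on `shifted` regions in
# condition 2 and no correlation structure.
shifted_cohort <- function(n_regions, n_per = 8, shift = 3,
                           shifted = seq_len(min(4, n_regions)),
                           seed = 1) {
  eff <- matrix(0, 2, n_regions)
  eff[2, shifted] <- shift
  spec <- synthetic_spec(
    n_regions = n_regions, groups = c(ctrl = n_per, trained = n_per),
    module_membership = rep(0L, n_regions),
    factor_loadings = rep(0, n_regions),
    noise_sd = 1, baseline_mean = 20, group_effects = eff,
    rng_seed = seed)
  generate_cohort(spec)
}

# Metadata table matching spec_modular-style region names, labelling the
# first module's regions as thalamus and the rest round-robin.
modular_metadata <- function(spec) {
  subdiv <- ifelse(spec$module_membership == 1L, "thalamus",
                   c("neocortex", "hippocampus",
                     "cerebral nuclei")[1 + seq_len(spec$n_regions) %% 3])
  region_metadata(spec$region_names, seq_len(spec$n_regions), subdiv)
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s close to %s",
                              paste(round(object, 6), collapse = ","),
                              paste(round(expected, 6), collapse = ",")))
}

# An Erdos-Renyi random graph wrapped as a functional network.
with_seed_graph <- function(seed, n = 40, p = 0.12) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  functional_network(g)
}
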