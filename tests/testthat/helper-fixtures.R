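# Small fixture builders shared across test files. Everything is
# generated in code at test time; nothing is read from disk.

random_symmetric <- function(n, seed = NULL) {
  gen <- function() {
    v <- rnorm(n_edges(n))
    devectorize(v, n)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# a small two-group covariate table with exactly balanced groups
tiny_covariates <- function(n_rel = 20, n_ctl = 12, seed = 42) {
  withr::with_seed(seed, {
    S <- n_rel + n_ctl
    tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(S)),
      age = rnorm(S, 58, 7),
      sex = sample(c("M", "F"), S, replace = TRUE),
      apoe_e4 = sample(c("carrier", "noncarrier"), S, replace = TRUE,
                       prob = c(0.3, 0.7)),
      education = rnorm(S, 15, 3),
      moca = rnorm(S, 26, 2.5),
      tpa = rnorm(S, 1.5, 1.1),
      cortical_thickness = rnorm(S, 2.37, 0.07),
      hippocampi_volume = rnorm(S, 3800, 380),
      family_history = c(rep("relative", n_rel), rep("control", n_ctl)))
  })
}

# small fast simulation config for pipeline-level tests
small_sim_config <- function(n_nodes = 40, d = c(1, 0), noise_sd = 0.5,
                             seed = 7L) {
  sizes <- default_network_sizes(n_nodes)
  sim_config(
    S_group1 = 60, S_group2 = 30, n_nodes = n_nodes,
    block_spec = list(
      list(trait_block("visual", "visual", sign = -1, amplitude = 4),
           trait_block("default_mode", "default_mode", sign = 1,
                       amplitude = 2)),
      list(trait_block("somatomotor", "somatomotor", sign = 1,
                       amplitude = 3))),
    group_effect_d = d, noise_sd = noise_sd, seed = seed)
}

small_extraction_params <- function(n_runs = 20, n_components = 8,
                                    base_seed = 11L) {
  extraction_params(n_runs = n_runs, n_components = n_components,
                    base_seed = base_seed)
}
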