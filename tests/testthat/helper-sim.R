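# small simulation configurations used across test files

quick_config <- function(seed = 1, n_markers = 120, noise_sd = 0,
                         biotype_rate = 0,
                         deletions = list(true_deletion("6B", 2e7, 2.6e7)),
                         n_panel = 4, ...) {
  sim_config(n_markers = n_markers, noise_sd = noise_sd,
             biotype_rate = biotype_rate, deletions = deletions,
             n_panel = n_panel, seed = seed, ...)
}

call_mutant <- function(sim, sample = "mut_6B", f1 = NULL, parent_bc = NULL,
                        config = caller_config()) {
  call_deletions(sim$intensities, sim$markers, parent = "Chara",
                 sample = sample, f1 = f1, panel_prefix = "HIB_",
                 parent_bc = parent_bc, config = config)
}
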