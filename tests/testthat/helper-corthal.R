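# shared fixtures, all generated in code

small_connectome <- function(n = 8, seed = 5, gc = 1e-4) {
  generate_connectome(connectome_sim_config(n_regions = n, seed = seed),
                      global_coupling = gc)
}

# a fast parameter set for tests that only exercise plumbing, not the
# alpha regime: short run, coarse-but-valid resolution
quick_params <- function(...) {
  args <- utils::modifyList(list(duration = 3, transient = 0.5), list(...))
  do.call(ct_params, args)
}

# deterministic sinusoid matrix (time x regions)
tone_matrix <- function(freq, fs, n_s, n_regions = 2, phase = 0) {
  tt <- seq_len(round(n_s * fs)) / fs
  sapply(seq_len(n_regions), function(j) sin(2 * pi * freq * tt + phase * (j - 1)))
}
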