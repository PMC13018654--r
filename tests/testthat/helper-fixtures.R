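# shared fixtures: small code tables and generator configs keep the unit
# tests fast while exercising the full pipeline

tiny_codes <- function(flickers = 1:4, fixations = c("down", "up")) {
  tab <- build_code_table(fixations)
  tab[tab$flicker_index %in% flickers, , drop = FALSE]
}

tiny_cfg <- function(montage = load_configuration("9/64"),
                     codes = tiny_codes(), seed = 1, ...) {
  sim_config(montage, codes, fs = 250, seed = seed, ...)
}

# noiseless dataset: every trial of a code is the exact deterministic
# response, so decoders must be perfect on it
clean_dataset <- function(n_blocks = 2, codes = tiny_codes(),
                          duration = 0.52, seed = 1, ...) {
  cfg <- tiny_cfg(codes = codes, seed = seed, noise_scale = 0, ...)
  synth_dataset(n_blocks, codes, duration, cfg)
}

noisy_dataset <- function(n_blocks = 3, codes = tiny_codes(),
                          duration = 0.52, seed = 1, snr = 8, ...) {
  cfg <- tiny_cfg(codes = codes, seed = seed, target_snr_db = snr, ...)
  synth_dataset(n_blocks, codes, duration, cfg)
}
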