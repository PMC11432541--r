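# The desk-scale collapse ensemble is expensive (about 20 s per
# replicate); compute it once per test run and share across blocks.
.ensemble_cache <- new.env(parent = emptyenv())

desk_ensemble_cached <- function() {
  if (is.null(.ensemble_cache$ens)) {
    preset <- desk_preset(replicates = 50, seed = 1)
    .ensemble_cache$ens <- simulate_ensemble(preset)
  }
  .ensemble_cache$ens
}
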