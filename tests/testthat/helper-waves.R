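# orbit cache: several test files reuse the same shooting orbits
.wave_cache <- new.env(parent = emptyenv())

cached_wave <- function(c, r, i_minus_inf, ...) {
  key <- paste(c, r, i_minus_inf, sep = "_")
  if (is.null(.wave_cache[[key]]))
    .wave_cache[[key]] <- shoot_wave(c, r, i_minus_inf, ...)
  .wave_cache[[key]]
}

params2 <- model_params(2, 0)
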