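# Shared, lazily computed simulation results. The full 30-cycle reference
# run takes a few seconds, so acceptance-style tests share one instance.

.ref_cache <- new.env(parent = emptyenv())

reference_trace <- function(seed = 1L) {
  key <- paste0("trace_", seed)
  if (is.null(.ref_cache[[key]])) {
    .ref_cache[[key]] <- run_protocol(config = simulation_config(seed = seed))
  }
  .ref_cache[[key]]
}

# A short noiseless run used by several structural tests.
small_trace <- function() {
  if (is.null(.ref_cache$small)) {
    prot <- pcr_protocol(
      initial_denaturation = protocol_stage("initial_denaturation", 95, 20),
      cycles = 1L,
      final_extension = protocol_stage("final_extension", 72, 20)
    )
    .ref_cache$small <- run_protocol(
      prot, config = simulation_config(noise_sd_C = 0)
    )
  }
  .ref_cache$small
}
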