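# Full-size (180 x 40) protocol runs shared between acceptance tests.
# Adaptations are expensive (1000 learning steps), so they are computed once
# per intensity and cached for the duration of the test run.

.full_env <- new.env(parent = emptyenv())

full_cfg <- function() {
  if (is.null(.full_env$cfg)) .full_env$cfg <- network_config()
  .full_env$cfg
}

full_syn <- function() {
  if (is.null(.full_env$syn)) .full_env$syn <- basal_synapses(full_cfg())
  .full_env$syn
}

adapt_stim <- function(E0) {
  stimulus(visual_azimuth = 100, auditory_azimuth = 80,
           auditory_freq_hz = 1100, auditory_intensity = E0)
}

full_adaptation <- function(E0) {
  key <- paste0("ad", E0)
  if (is.null(.full_env[[key]])) {
    .full_env[[key]] <- adapt_network(full_syn(), adapt_stim(E0), full_cfg())
  }
  .full_env[[key]]
}

# aftereffect of a unimodal test tone at the adaptation position
test_tone_shift <- function(adaptation, E0_test, freq_index) {
  st <- run_to_steady_state(adaptation$synapses,
                            stimulus(auditory_azimuth = 80,
                                     auditory_freq_index = freq_index,
                                     auditory_intensity = E0_test),
                            full_cfg())
  stopifnot(st$converged)
  barycenter_auditory(st$y_a) - 80
}
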