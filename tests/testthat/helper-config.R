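# Small synthetic grids for fast unit tests. Kernel and receptive-field
# widths are scaled down with the grid so that activation bubbles stay
# confined; dynamics are qualitatively comparable to the full network but
# none of these configurations reproduces its quantitative behaviour.

tiny_cfg <- function(...) {
  network_config(
    n_azimuth_visual = 60, n_azimuth_auditory = 60, n_freq_auditory = 20,
    sigma_p_v = 2, sigma_p_a = 10, sigma_f_a = 7,
    sigma_in_p_v = 8, sigma_in_p_a = 4, sigma_in_f_a = 2.5,
    freq_anchor_index = 9L,
    ...)
}

# canonical small bimodal pair scaled to the tiny grid
tiny_bimodal <- function(intensity = 20, v_az = 40, a_az = 30, jf = 9) {
  stimulus(visual_azimuth = v_az, auditory_azimuth = a_az,
           auditory_freq_index = jf, auditory_intensity = intensity)
}

tiny_tone <- function(intensity = 20, a_az = 30, jf = 9) {
  stimulus(auditory_azimuth = a_az, auditory_freq_index = jf,
           auditory_intensity = intensity)
}

expect_equal_matrix <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
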