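cfg <- network_config()

test_that("the barycenter decodes positions of simple activity patterns", {
  # a single active neuron decodes to its own azimuth
  y <- matrix(0, 180, 40)
  y[81, 18] <- 0.7
  expect_equal(barycenter_auditory(y), 80)
  # a pattern symmetric about 80 deg (away from the seam) decodes to 80
  d <- circular_distance(0:179, 80, 180)
  blob <- exp(-d^2 / (2 * 6^2))
  expect_equal(barycenter_visual(blob, floor_frac = 0), 80, tolerance = 1e-9)
  ya <- outer(blob, exp(-(0:39 - 17)^2 / 18))
  expect_equal(barycenter_auditory(ya, floor_frac = 0), 80, tolerance = 1e-9)
  # zero activity has no defined location
  expect_error(barycenter_auditory(matrix(0, 10, 4)), "undefined location")
})

test_that("the barycenter is equivariant under translation away from the seam", {
  d <- circular_distance(0:179, 60, 180)
  blob <- exp(-d^2 / (2 * 5^2))
  b0 <- barycenter_visual(blob)
  for (shift in c(5, 17, 30)) {
    shifted <- blob[(0:179 - shift) %% 180 + 1]
    expect_equal(barycenter_visual(shifted), b0 + shift, tolerance = 1e-9)
  }
})

test_that("activity mass near the wrap seam triggers a warning", {
  y <- numeric(180)
  y[c(1, 180)] <- 1
  y[90] <- 5
  expect_warning(barycenter_visual(y, floor_frac = 0), "seam")
})

test_that("the decoding floor removes the resting background", {
  # a symmetric blob at 70 plus a uniform resting background:
  # the literal mean is dragged toward the grid midpoint, the floored
  # decoding recovers the blob position exactly
  d <- circular_distance(0:179, 70, 180)
  y <- exp(-d^2 / (2 * 6^2)) + 7e-4
  expect_gt(barycenter_visual(y, floor_frac = 0), 70.05)
  expect_equal(barycenter_visual(y, floor_frac = 0.01), 70)
})

test_that("decode_locations reports shifts with the attraction sign convention", {
  syn <- basal_synapses(cfg)
  stim <- stimulus(visual_azimuth = 100, auditory_azimuth = 80,
                   auditory_freq_index = 17, auditory_intensity = 20)
  st <- run_to_steady_state(syn, stim, cfg)
  dec <- decode_locations(st, stim)
  expect_setequal(dec$layer, c("auditory", "visual"))
  # sound attracted toward the visual stimulus: positive auditory shift
  expect_gt(dec$shift_deg[dec$layer == "auditory"], 0)
  expect_equal(dec$actual_deg, c(80, 100))
})

test_that("half-maximum width interpolates the half crossing", {
  # triangular toy curve: peak 1.0 at 90 deg, falling by 0.05/deg,
  # so it reaches 0.5 exactly at 100 deg
  x <- 0:179
  curve <- pmax(1 - 0.05 * circular_distance(x, 90, 180), 0)
  expect_equal(half_max_width(curve), 10)
  expect_equal(half_max_width(curve, sides = "two"), 20)
  # invariant under uniform scaling
  expect_equal(half_max_width(0.3 * curve), 10)
  # interpolation between grid points: peak 1 at one point, 0.6 and 0.4
  # at the neighbours -> crossing 1.5 points to the right
  c2 <- c(0.1, 0.2, 0.6, 1, 0.6, 0.4, 0.1, 0, 0, 0)
  expect_equal(half_max_width(c2), 1.5)
  # a flat curve never crosses half maximum
  expect_error(half_max_width(rep(1, 10)), "undefined")
})

test_that("azimuth tuning of the untrained network peaks at the neuron position", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t)
  tc <- azimuth_tuning(syn, cfg_t, neuron_azimuth = 30, neuron_freq_index = 9,
                       intensities = 20)
  expect_equal(nrow(tc), cfg_t$n_azimuth_auditory)
  expect_true(all(tc$converged))
  expect_equal(tc$probe_azimuth_deg[which.max(tc$response)], 30)
  # symmetric about the peak
  r <- tc$response
  expect_equal(r[(30 + 5) %% 60 + 1], r[(30 - 5) %% 60 + 1], tolerance = 1e-6)
  # by basal translation symmetry the tuning curve equals the activation
  # profile of a single run read across azimuths
  st <- run_to_steady_state(syn, tiny_tone(), cfg_t)
  expect_equal(r, st$y_a[, 10], tolerance = 1e-5)
})

test_that("frequency tuning of the untrained network peaks at the neuron frequency", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t)
  tc <- frequency_tuning(syn, cfg_t, neuron_azimuth = 30,
                         neuron_freq_index = 9, intensities = 20)
  expect_equal(nrow(tc), cfg_t$n_freq_auditory)
  expect_equal(tc$probe_freq_index[which.max(tc$response)], 9)
  expect_equal(tc$probe_freq_hz,
               freq_index_to_hz(tc$probe_freq_index, cfg_t))
})

test_that("the FRA discretizes the normalized response into four bands", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t)
  m <- fra(syn, cfg_t, neuron_azimuth = 30, neuron_freq_index = 9,
           intensities = c(12, 20))
  expect_equal(levels(m$band), c("<25%", "25-50%", "50-75%", ">75%"))
  expect_true(all(m$band_level %in% 0:3))
  expect_equal(max(m$norm_response), 1)
  expect_equal(m$band_level[which.max(m$norm_response)], 3)
  # band edges at exactly 0.25/0.5/0.75 of peak
  expect_true(all((m$norm_response > 0.75) == (m$band_level == 3)))
  expect_true(all((m$norm_response <= 0.25) == (m$band_level == 0)))
  # the higher intensity elicits the stronger peak response
  peaks <- tapply(m$response, m$intensity, max)
  expect_lt(peaks[["12"]], peaks[["20"]])
})

test_that("response span widens with stimulus intensity on the untrained net", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t)
  t1 <- azimuth_tuning(syn, cfg_t, 30, 9, intensities = 14)
  t2 <- azimuth_tuning(syn, cfg_t, 30, 9, intensities = 24)
  expect_gte(response_span(t2), response_span(t1))
  expect_gt(max(t2$response), max(t1$response))
})

test_that("FRA bands widen monotonically with intensity on the untrained net", {
  cfg_t <- tiny_cfg()
  syn <- basal_synapses(cfg_t)
  m <- fra(syn, cfg_t, neuron_azimuth = 30, neuron_freq_index = 9,
           intensities = c(12, 16, 20, 24))
  area <- tapply(m$band_level >= 1, m$intensity, sum)
  expect_true(all(diff(area[order(as.numeric(names(area)))]) >= 0))
  peak <- tapply(m$response, m$intensity, max)
  expect_true(all(diff(peak[order(as.numeric(names(peak)))]) > 0))
})
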