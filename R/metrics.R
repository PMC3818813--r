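#' Barycenter population decoding
#'
#' The perceived location of a stimulus is read out as the activity-weighted
#' mean azimuth (barycenter) of a layer's population activity, in degrees
#' (azimuth index = degrees). Activity below `floor_frac` times the layer
#' maximum is ignored: unstimulated neurons sit at the sigmoid's small but
#' nonzero resting output, and a literal weighted mean over the whole ring
#' would drag every decoded position toward the grid midpoint. `floor_frac =
#' 0` gives the literal weighted mean.
#'
#' The barycenter is computed on linear indices, not as a circular mean; if
#' more than 1% of the (floored) activity mass lies within 5 indices of the
#' wrap seam a warning is emitted, since the linear mean is then unreliable.
#'
#' @param y_a auditory activity matrix (azimuth x frequency).
#' @param y_v visual activity vector.
#' @param floor_frac activities below `floor_frac * max(y)` are zeroed before
#'   decoding (default 0.01).
#' @return perceived azimuth in degrees.
#' @examples
#' y <- matrix(0, 180, 40); y[81, 18] <- 1
#' barycenter_auditory(y) # 80: single active neuron at azimuth 80
#' @export
barycenter_auditory <- function(y_a, floor_frac = 0.01) {
  bary(floor_mass(y_a, floor_frac))
}

#' @rdname barycenter_auditory
#' @export
barycenter_visual <- function(y_v, floor_frac = 0.01) {
  bary(floor_mass(y_v, floor_frac))
}

floor_mass <- function(y, floor_frac) {
  y[y < floor_frac * max(y)] <- 0
  y
}

bary <- function(y) {
  # y may be a matrix (azimuth x freq): collapse over frequency
  w <- if (is.matrix(y)) rowSums(y) else y
  tot <- sum(w)
  if (tot <= 0) {
    stop("undefined location: no activity above the decoding floor",
         call. = FALSE)
  }
  n <- length(w)
  seam <- c(seq_len(min(5, n)), seq(max(1, n - 4), n))
  if (sum(w[unique(seam)]) > 0.01 * tot) {
    warning("more than 1% of activity mass lies near the wrap seam; ",
            "the linear barycenter may be unreliable", call. = FALSE)
  }
  sum(w * (seq_len(n) - 1)) / tot
}

#' Decode perceived stimulus locations from a network state
#'
#' Applies [barycenter_auditory()] and [barycenter_visual()] to a steady
#' state and, when the stimulus is supplied, reports the perceptual shift
#' (perceived minus actual position) of each modality. A positive auditory
#' shift for the canonical configuration (visual at 100 deg, auditory at
#' 80 deg) means attraction toward the visual stimulus.
#'
#' @param state a `ventnet_state` from [run_to_steady_state()].
#' @param stim the [stimulus()] that produced it (optional; needed for
#'   shifts).
#' @param floor_frac decoding floor, see [barycenter_auditory()].
#' @return a tibble with one row per layer: `layer`, `perceived_deg`,
#'   `actual_deg`, `shift_deg`.
#' @export
decode_locations <- function(state, stim = NULL, floor_frac = 0.01) {
  za <- barycenter_auditory(state$y_a, floor_frac)
  zv <- barycenter_visual(state$y_v, floor_frac)
  actual_a <- actual_v <- NA_real_
  if (!is.null(stim)) {
    if (stim$auditory_present) actual_a <- stim$auditory_azimuth
    if (stim$visual_present) actual_v <- stim$visual_azimuth
  }
  tibble::tibble(
    layer = c("auditory", "visual"),
    perceived_deg = c(za, zv),
    actual_deg = c(actual_a, actual_v),
    shift_deg = c(za - actual_a, zv - actual_v))
}

steady_response <- function(syn, cfg, stim, neuron_azimuth, neuron_freq_index) {
  st <- run_to_steady_state(syn, stim, cfg)
  list(response = st$y_a[neuron_azimuth + 1L, neuron_freq_index + 1L],
       converged = st$converged)
}

#' Azimuthal tuning function of an auditory neuron
#'
#' Steady-state response of one designated neuron to identical unimodal
#' tones placed at every azimuth of the grid, at a fixed frequency (the
#' neuron's own, unless overridden) — one independent steady-state run per
#' probe position. Several probe intensities may be given.
#'
#' @param syn synaptic state (basal or trained).
#' @param cfg a [network_config()].
#' @param neuron_azimuth,neuron_freq_index the recorded neuron (0-based).
#' @param intensities one or more probe intensities `E0_a`.
#' @param probe_freq_index frequency of the probe tones; defaults to the
#'   neuron's own frequency.
#' @return a tibble of class `ventnet_tuning`: `probe_azimuth_deg`,
#'   `intensity`, `response`, `converged`, plus metadata columns `neuron_*`.
#' @export
azimuth_tuning <- function(syn, cfg, neuron_azimuth, neuron_freq_index,
                           intensities, probe_freq_index = neuron_freq_index) {
  grid <- tidyr::expand_grid(intensity = intensities,
                             probe_azimuth_deg = 0:(cfg$n_azimuth_auditory - 1))
  res <- purrr::pmap(grid, function(intensity, probe_azimuth_deg) {
    steady_response(syn, cfg,
                    stimulus(auditory_azimuth = probe_azimuth_deg,
                             auditory_freq_index = probe_freq_index,
                             auditory_intensity = intensity),
                    neuron_azimuth, neuron_freq_index)
  })
  out <- dplyr::mutate(grid,
                       response = purrr::map_dbl(res, "response"),
                       converged = purrr::map_lgl(res, "converged"),
                       neuron_azimuth = neuron_azimuth,
                       neuron_freq_index = neuron_freq_index)
  as_tuning(out, axis = "probe_azimuth_deg")
}

#' Frequency tuning function of an auditory neuron
#'
#' Steady-state response of one neuron to unimodal tones at every frequency
#' of the grid, at a fixed azimuth (the neuron's own unless overridden).
#'
#' @inheritParams azimuth_tuning
#' @param probe_azimuth azimuth of the probe tones (degrees); defaults to
#'   the neuron's own azimuth.
#' @return a tibble of class `ventnet_tuning`: `probe_freq_index`,
#'   `probe_freq_hz`, `intensity`, `response`, `converged`.
#' @export
frequency_tuning <- function(syn, cfg, neuron_azimuth, neuron_freq_index,
                             intensities, probe_azimuth = neuron_azimuth) {
  grid <- tidyr::expand_grid(intensity = intensities,
                             probe_freq_index = 0:(cfg$n_freq_auditory - 1))
  res <- purrr::pmap(grid, function(intensity, probe_freq_index) {
    steady_response(syn, cfg,
                    stimulus(auditory_azimuth = probe_azimuth,
                             auditory_freq_index = probe_freq_index,
                             auditory_intensity = intensity),
                    neuron_azimuth, neuron_freq_index)
  })
  out <- dplyr::mutate(grid,
                       probe_freq_hz = freq_index_to_hz(probe_freq_index, cfg),
                       response = purrr::map_dbl(res, "response"),
                       converged = purrr::map_lgl(res, "converged"),
                       neuron_azimuth = neuron_azimuth,
                       neuron_freq_index = neuron_freq_index)
  as_tuning(out, axis = "probe_freq_index")
}

as_tuning <- function(tbl, axis) {
  attr(tbl, "axis") <- axis
  class(tbl) <- c("ventnet_tuning", class(tbl))
  tbl
}

#' Half-maximum width of a tuning curve
#'
#' The range from the curve's maximum to the point where the response first
#' falls to one-half of the maximum — a one-sided measure, per its standard
#' definition for azimuthal tuning functions. The crossing is located by
#' linear interpolation between grid points; the axis is treated as
#' circular. `sides = "two"` gives the full width at half maximum instead.
#'
#' The width is invariant to uniform scaling of the curve.
#'
#' @param curve either a numeric response vector on a uniformly spaced
#'   circular axis (spacing = 1 unit), or a `ventnet_tuning` tibble for a
#'   single intensity.
#' @param sides `"one"` (default, peak to half-peak) or `"two"` (full
#'   width).
#' @return the width in axis units (degrees for azimuthal curves).
#' @export
half_max_width <- function(curve, sides = c("one", "two")) {
  sides <- match.arg(sides)
  if (inherits(curve, "ventnet_tuning")) {
    if (length(unique(curve$intensity)) > 1) {
      stop("curve contains several intensities; filter to one first",
           call. = FALSE)
    }
    curve <- curve$response
  }
  stopifnot(is.numeric(curve), length(curve) >= 3)
  pk <- which.max(curve)
  if (curve[pk] <= 0) stop("curve has no positive peak", call. = FALSE)
  half <- curve[pk] / 2
  w <- half_cross(curve, pk, half, +1L)
  if (sides == "two") w <- w + half_cross(curve, pk, half, -1L)
  w
}

# distance from index pk to the first half-crossing walking in direction dir
# on a ring, with linear interpolation
half_cross <- function(curve, pk, half, dir) {
  n <- length(curve)
  for (k in seq_len(n - 1)) {
    idx <- (pk - 1 + dir * k) %% n + 1
    if (curve[idx] < half) {
      prev <- (pk - 1 + dir * (k - 1)) %% n + 1
      return(k - 1 + (curve[prev] - half) / (curve[prev] - curve[idx]))
    }
  }
  stop("response never falls below half maximum: width undefined",
       call. = FALSE)
}

#' Span of a tuning curve above a response floor
#'
#' Number of grid points whose response exceeds `floor_frac` of the curve
#' peak — the extent of the responsive region (in degrees for azimuthal
#' curves).
#'
#' @inheritParams half_max_width
#' @param floor_frac fraction of the peak response below which a neuron is
#'   considered unresponsive (default 0.01).
#' @return span in axis units.
#' @export
response_span <- function(curve, floor_frac = 0.01) {
  if (inherits(curve, "ventnet_tuning")) curve <- curve$response
  sum(curve > floor_frac * max(curve))
}

#' Frequency response area of an auditory neuron
#'
#' The neuron's steady-state response on a frequency x intensity grid of
#' unimodal probe tones, normalized to the grid-wide peak and discretized
#' into the four bands used in neurophysiological frequency-response-area
#' maps: <25%, 25-50%, 50-75%, >75% of the peak response.
#'
#' @inheritParams frequency_tuning
#' @param intensities intensity grid (one row of the map per intensity).
#' @return a tibble of class `ventnet_fra`: `intensity`, `probe_freq_index`,
#'   `probe_freq_hz`, `response`, `norm_response`, `band` (ordered factor),
#'   `band_level` (0-3).
#' @export
fra <- function(syn, cfg, neuron_azimuth, neuron_freq_index, intensities,
                probe_azimuth = neuron_azimuth) {
  curves <- frequency_tuning(syn, cfg, neuron_azimuth, neuron_freq_index,
                             intensities, probe_azimuth)
  peak <- max(curves$response)
  bands <- c("<25%", "25-50%", "50-75%", ">75%")
  out <- dplyr::mutate(tibble::as_tibble(curves),
    norm_response = response / peak,
    band_level = findInterval(norm_response, c(0.25, 0.5, 0.75)),
    band = factor(bands[band_level + 1], levels = bands, ordered = TRUE))
  class(out) <- c("ventnet_fra", class(out))
  out
}
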