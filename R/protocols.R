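#' Ventriloquism-effect sweep
#'
#' Runs the immediate (no-learning) ventriloquism protocol over a grid of
#' visual-auditory spatial disparities and tone intensities: for each cell a
#' bimodal steady state is computed from the null condition with the visual
#' stimulus at `visual_azimuth` and the tone `disparity` degrees away, and
#' both perceptual shifts are decoded. Lateral synapses are not trained, so
#' the sweep isolates the shift caused by the conflicting audiovisual input.
#'
#' @param syn a [basal_synapses()] state.
#' @param cfg a [network_config()].
#' @param disparities spatial disparities in degrees (auditory at
#'   `visual_azimuth - disparity`).
#' @param intensities tone intensities `E0_a`.
#' @param visual_azimuth position of the visual stimulus (default 100 deg).
#' @param freq_index tone frequency index (default: the grid index of
#'   1.1 kHz).
#' @param floor_frac decoding floor, see [barycenter_auditory()].
#' @return a tibble of class `ventnet_sweep`: `disparity`, `intensity`,
#'   `shift_auditory`, `shift_visual` (degrees, perceived minus actual),
#'   `converged`.
#' @examples \dontrun{
#' sw <- ventriloquism_sweep(basal_synapses(cfg), cfg,
#'                           disparities = c(10, 20), intensities = c(17, 20))
#' }
#' @export
ventriloquism_sweep <- function(syn, cfg,
                                disparities = c(5, 10, 15, 20, 25, 30),
                                intensities = 17:23,
                                visual_azimuth = 100,
                                freq_index = NULL,
                                floor_frac = 0.01) {
  if (is.null(freq_index)) freq_index <- default_freq_index(cfg)
  grid <- tidyr::expand_grid(disparity = disparities, intensity = intensities)
  rows <- purrr::pmap(grid, function(disparity, intensity) {
    stim <- stimulus(visual_azimuth = visual_azimuth,
                     auditory_azimuth = visual_azimuth - disparity,
                     auditory_freq_index = freq_index,
                     auditory_intensity = intensity)
    st <- run_to_steady_state(syn, stim, cfg)
    dec <- decode_locations(st, stim, floor_frac)
    tibble::tibble(
      shift_auditory = dec$shift_deg[dec$layer == "auditory"],
      shift_visual = dec$shift_deg[dec$layer == "visual"],
      converged = st$converged)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  class(out) <- c("ventnet_sweep", class(out))
  out
}

default_freq_index <- function(cfg) cfg$freq_anchor_index

#' Ventriloquism-aftereffect experiment
#'
#' Adapts the untrained network to a spatially discrepant audiovisual pair
#' (visual at 100 deg, tone at 80 deg / 1.1 kHz by default) for
#' `cfg$n_learning_steps` learning steps, then — with learning off —
#' presents unimodal test tones at the adaptation position across test
#' frequencies and intensities and records the residual auditory shift
#' (the aftereffect) for each.
#'
#' A previously computed [adapt_network()] result can be passed through
#' `adaptation` to reuse a trained synapse state; otherwise the function
#' adapts first. The adaptation object is attached to the result as the
#' `"adaptation"` attribute so it can be cached and reused.
#'
#' @param syn a [basal_synapses()] state (ignored when `adaptation` is
#'   given).
#' @param cfg a [network_config()].
#' @param adapt_intensity tone intensity during adaptation.
#' @param test_intensities tone intensities of the unimodal test stimuli
#'   (default: equal to `adapt_intensity`, the standard psychophysical
#'   protocol).
#' @param test_freq_indices frequency indices of the test tones (default:
#'   the whole grid).
#' @param adaptation optional `ventnet_adaptation` to reuse.
#' @param visual_azimuth,auditory_azimuth,adapt_freq_index geometry of the
#'   adaptation pair; tests are presented at `auditory_azimuth`.
#' @param floor_frac decoding floor, see [barycenter_auditory()].
#' @return a tibble of class `ventnet_aftereffect`: `adapt_intensity`,
#'   `test_intensity`, `freq_index`, `freq_hz`, `octaves_from_adapt`,
#'   `shift_deg`, `converged`; the adaptation object is in
#'   `attr(, "adaptation")`.
#' @export
aftereffect_experiment <- function(syn, cfg, adapt_intensity,
                                   test_intensities = adapt_intensity,
                                   test_freq_indices = NULL,
                                   adaptation = NULL,
                                   visual_azimuth = 100,
                                   auditory_azimuth = 80,
                                   adapt_freq_index = NULL,
                                   floor_frac = 0.01) {
  if (is.null(adapt_freq_index)) adapt_freq_index <- default_freq_index(cfg)
  if (is.null(test_freq_indices)) {
    test_freq_indices <- 0:(cfg$n_freq_auditory - 1)
  }
  if (is.null(adaptation)) {
    adaptation <- adapt_network(
      syn,
      stimulus(visual_azimuth = visual_azimuth,
               auditory_azimuth = auditory_azimuth,
               auditory_freq_index = adapt_freq_index,
               auditory_intensity = adapt_intensity),
      cfg)
  }
  trained <- adaptation$synapses
  grid <- tidyr::expand_grid(test_intensity = test_intensities,
                             freq_index = test_freq_indices)
  rows <- purrr::pmap(grid, function(test_intensity, freq_index) {
    stim <- stimulus(auditory_azimuth = auditory_azimuth,
                     auditory_freq_index = freq_index,
                     auditory_intensity = test_intensity)
    st <- run_to_steady_state(trained, stim, cfg)
    tibble::tibble(
      shift_deg = barycenter_auditory(st$y_a, floor_frac) - auditory_azimuth,
      converged = st$converged)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(adapt_intensity = adapt_intensity),
    grid, dplyr::bind_rows(rows))
  out$freq_hz <- freq_index_to_hz(out$freq_index, cfg)
  out$octaves_from_adapt <-
    (out$freq_index - adapt_freq_index) * cfg$octaves_per_index
  out <- out[, c("adapt_intensity", "test_intensity", "freq_index", "freq_hz",
                 "octaves_from_adapt", "shift_deg", "converged")]
  attr(out, "adaptation") <- adaptation
  class(out) <- c("ventnet_aftereffect", class(out))
  out
}

#' Aftereffect generalization across adaptation and test intensities
#'
#' The full cross of adaptation intensities by test intensities: the network
#' is adapted once per adaptation intensity (the trained state is reused for
#' all of that row's tests) and the aftereffect-vs-frequency curve is
#' measured for every test intensity. Each curve is summarized by its
#' generalization bandwidth: the octave distance from the adaptation
#' frequency at which the aftereffect first falls below `floor_deg`.
#'
#' @inheritParams aftereffect_experiment
#' @param adapt_intensities,test_intensities intensity grids (defaults
#'   17-23).
#' @param floor_deg aftereffect floor defining the generalization bandwidth
#'   (default 0.5 deg).
#' @return a list with two tibbles: `curves` (all aftereffect curves,
#'   class `ventnet_aftereffect`) and `bandwidth` (`adapt_intensity`,
#'   `test_intensity`, `bandwidth_octaves`).
#' @export
generalization_matrix <- function(syn, cfg,
                                  adapt_intensities = 17:23,
                                  test_intensities = 17:23,
                                  test_freq_indices = NULL,
                                  floor_deg = 0.5,
                                  visual_azimuth = 100,
                                  auditory_azimuth = 80,
                                  adapt_freq_index = NULL,
                                  floor_frac = 0.01) {
  if (is.null(adapt_freq_index)) adapt_freq_index <- default_freq_index(cfg)
  curves <- purrr::map(adapt_intensities, function(ai) {
    aftereffect_experiment(syn, cfg, adapt_intensity = ai,
                           test_intensities = test_intensities,
                           test_freq_indices = test_freq_indices,
                           visual_azimuth = visual_azimuth,
                           auditory_azimuth = auditory_azimuth,
                           adapt_freq_index = adapt_freq_index,
                           floor_frac = floor_frac)
  })
  all <- dplyr::bind_rows(lapply(curves, tibble::as_tibble))
  bw <- dplyr::summarise(
    dplyr::group_by(all, .data$adapt_intensity, .data$test_intensity),
    bandwidth_octaves = generalization_bandwidth(
      .data$octaves_from_adapt, .data$shift_deg, floor_deg),
    .groups = "drop")
  class(all) <- c("ventnet_aftereffect", class(all))
  list(curves = all, bandwidth = bw)
}

#' Generalization bandwidth of an aftereffect curve
#'
#' Scans outward from the adaptation frequency (octave distance 0) and
#' returns the first octave distance at which the aftereffect falls below
#' `floor_deg`, taking the larger of the two directions; 0 when even the
#' aftereffect at the adaptation frequency is below the floor. This is a
#' summary statistic of this package (the spread of curves is otherwise
#' described only verbally); the floor is a tunable argument.
#'
#' @param octaves_from_adapt signed octave distances of the curve points.
#' @param shift_deg aftereffect (degrees) at those points.
#' @param floor_deg the aftereffect floor (default 0.5 deg).
#' @return bandwidth in octaves.
#' @export
generalization_bandwidth <- function(octaves_from_adapt, shift_deg,
                                     floor_deg = 0.5) {
  stopifnot(length(octaves_from_adapt) == length(shift_deg))
  one_side <- function(sgn) {
    sel <- sgn * octaves_from_adapt >= 0
    o <- abs(octaves_from_adapt[sel])
    s <- shift_deg[sel][order(o)]
    o <- sort(o)
    below <- which(s < floor_deg)
    if (!length(below)) max(o) else o[min(below)]
  }
  max(one_side(+1), one_side(-1))
}
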