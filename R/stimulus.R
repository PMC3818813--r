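#' Stimulus specification
#'
#' Describes the external stimuli applied to the network: an optional visual
#' flash (azimuth + intensity) and an optional auditory tone (azimuth,
#' frequency, intensity). Azimuths are in degrees and coincide with grid
#' indices (one neuron per degree, 0-based). The tone frequency can be given
#' either as a grid index (`auditory_freq_index`) or in Hz
#' (`auditory_freq_hz`), in which case it is resolved to the nearest grid
#' index when the input field is built.
#'
#' @param visual_azimuth azimuth of the visual stimulus in degrees, or `NULL`
#'   for no visual stimulus.
#' @param visual_intensity intensity of the visual stimulus; defaults to the
#'   configuration value `E0_v` at input-building time if `NULL`.
#' @param auditory_azimuth azimuth of the tone in degrees, or `NULL` for no
#'   auditory stimulus.
#' @param auditory_freq_index frequency-grid index of the tone (0-based).
#' @param auditory_freq_hz tone frequency in Hz (alternative to the index).
#' @param auditory_intensity tone intensity `E0_a` (arbitrary units, >= 0).
#'   Required when an auditory stimulus is present: unlike the visual
#'   intensity it has no basal default, because it is the experimental
#'   variable of every protocol.
#' @return an object of class `ventnet_stimulus`.
#' @examples
#' # the canonical adaptation pair: flash at 100 deg, tone at 80 deg / 1.1 kHz
#' stimulus(visual_azimuth = 100, auditory_azimuth = 80,
#'          auditory_freq_hz = 1100, auditory_intensity = 20)
#' @export
stimulus <- function(visual_azimuth = NULL, visual_intensity = NULL,
                     auditory_azimuth = NULL, auditory_freq_index = NULL,
                     auditory_freq_hz = NULL, auditory_intensity = NULL) {
  vp <- !is.null(visual_azimuth)
  ap <- !is.null(auditory_azimuth)
  if (!vp && !ap) {
    stop("a stimulus needs at least one modality; use null_stimulus() for none",
         call. = FALSE)
  }
  if (ap) {
    if (is.null(auditory_freq_index) && is.null(auditory_freq_hz)) {
      stop("an auditory stimulus needs a frequency (index or Hz)",
           call. = FALSE)
    }
    if (is.null(auditory_intensity)) {
      stop("an auditory stimulus needs an intensity", call. = FALSE)
    }
    stopifnot(auditory_intensity >= 0)
  }
  if (vp && !is.null(visual_intensity)) stopifnot(visual_intensity >= 0)
  structure(
    list(visual_present = vp,
         visual_azimuth = visual_azimuth,
         visual_intensity = visual_intensity,
         auditory_present = ap,
         auditory_azimuth = auditory_azimuth,
         auditory_freq_index = auditory_freq_index,
         auditory_freq_hz = auditory_freq_hz,
         auditory_intensity = auditory_intensity),
    class = "ventnet_stimulus")
}

#' @rdname stimulus
#' @export
null_stimulus <- function() {
  structure(list(visual_present = FALSE, auditory_present = FALSE),
            class = "ventnet_stimulus")
}

#' @export
print.ventnet_stimulus <- function(x, ...) {
  cat("<ventnet_stimulus>\n")
  if (x$visual_present) {
    cat(sprintf("  visual: azimuth %g deg, intensity %s\n", x$visual_azimuth,
                if (is.null(x$visual_intensity)) "E0_v (config default)"
                else format(x$visual_intensity)))
  }
  if (x$auditory_present) {
    f <- if (!is.null(x$auditory_freq_hz)) {
      sprintf("%g Hz", x$auditory_freq_hz)
    } else {
      sprintf("index %d", x$auditory_freq_index)
    }
    cat(sprintf("  auditory: azimuth %g deg, frequency %s, intensity %g\n",
                x$auditory_azimuth, f, x$auditory_intensity))
  }
  if (!x$visual_present && !x$auditory_present) cat("  (null stimulus)\n")
  invisible(x)
}

resolve_stimulus <- function(stim, cfg) {
  stopifnot(inherits(stim, "ventnet_stimulus"))
  if (stim$visual_present) {
    if (stim$visual_azimuth < 0 || stim$visual_azimuth >= cfg$n_azimuth_visual) {
      stop("visual azimuth outside the grid", call. = FALSE)
    }
    if (is.null(stim$visual_intensity)) stim$visual_intensity <- cfg$E0_v
  }
  if (stim$auditory_present) {
    if (stim$auditory_azimuth < 0 ||
        stim$auditory_azimuth >= cfg$n_azimuth_auditory) {
      stop("auditory azimuth outside the grid", call. = FALSE)
    }
    if (is.null(stim$auditory_freq_index)) {
      stim$auditory_freq_index <-
        as.integer(hz_to_freq_index(stim$auditory_freq_hz, cfg))
    }
    if (stim$auditory_freq_index < 0 ||
        stim$auditory_freq_index >= cfg$n_freq_auditory) {
      stop("auditory frequency index outside the grid", call. = FALSE)
    }
  }
  stim
}

#' External input fields
#'
#' The external input to each layer is the stimulus filtered by the neurons'
#' receptive fields: a circular Gaussian centred on the stimulated azimuth
#' (and, for the auditory layer, a separable circular Gaussian over azimuth
#' and frequency). The peak equals the stimulus intensity. An absent modality
#' gives an all-zero field.
#'
#' @param stim a [stimulus()].
#' @param cfg a [network_config()].
#' @return `visual_input()`: a numeric vector of length `n_azimuth_visual`.
#'   `auditory_input()`: an `n_azimuth_auditory x n_freq_auditory` matrix.
#' @export
visual_input <- function(stim, cfg) {
  stim <- resolve_stimulus(stim, cfg)
  n <- cfg$n_azimuth_visual
  if (!stim$visual_present) return(numeric(n))
  d <- circular_distance(0:(n - 1), stim$visual_azimuth, n)
  stim$visual_intensity * exp(-d^2 / (2 * cfg$sigma_p_v^2))
}

#' @rdname visual_input
#' @export
auditory_input <- function(stim, cfg) {
  stim <- resolve_stimulus(stim, cfg)
  np <- cfg$n_azimuth_auditory
  nf <- cfg$n_freq_auditory
  if (!stim$auditory_present) return(matrix(0, np, nf))
  da <- circular_distance(0:(np - 1), stim$auditory_azimuth, np)
  df <- circular_distance(0:(nf - 1), stim$auditory_freq_index, nf)
  stim$auditory_intensity *
    outer(exp(-da^2 / (2 * cfg$sigma_p_a^2)),
          exp(-df^2 / (2 * cfg$sigma_f_a^2)))
}
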