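#' Model configuration
#'
#' Builds the full parameter set of the two-layer visual-auditory network:
#' grid sizes, stimulus receptive-field widths, the neuron input-output
#' relationship, Mexican-hat lateral-kernel parameters for both layers,
#' cross-modal coupling strengths, Hebbian-rule parameters, and
#' numerical-integration settings. Defaults are the model's basal parameter
#' set; any subset can be overridden by name.
#'
#' The auditory layer is a circular azimuth x frequency grid: one neuron per
#' degree of azimuth and five neurons per octave of frequency (so 40 neurons
#' span eight octaves). The frequency grid is anchored by placing
#' `freq_anchor_hz` (default 1100 Hz) at index `freq_anchor_index`
#' (default 17), which puts the whole grid at roughly 104 Hz - 23 kHz.
#'
#' @param ... named parameter overrides, e.g. `network_config(E0_v = 10)`.
#' @param file optional path to a YAML configuration file; values in the file
#'   override the defaults, and `...` overrides the file.
#'
#' @return an object of class `ventnet_config`: a validated named list.
#'
#' @section Parameters:
#' \describe{
#'   \item{n_azimuth_visual, n_azimuth_auditory, n_freq_auditory}{grid sizes
#'     (180, 180, 40). The two azimuth counts must be equal because the
#'     cross-modal projection is azimuth-aligned.}
#'   \item{E0_v, sigma_p_v}{visual stimulus intensity (arbitrary units) and
#'     receptive-field width (index units = degrees).}
#'   \item{sigma_p_a, sigma_f_a}{auditory receptive-field widths along azimuth
#'     and frequency (index units).}
#'   \item{s, theta, tau_y}{sigmoid slope, sigmoid centre, and the first-order
#'     time constant in ms; shared by both layers.}
#'   \item{Lex0_v, Lin0_v, sigma_ex_p_v, sigma_in_p_v}{visual lateral
#'     Mexican-hat amplitudes and widths (excitation narrow and strong,
#'     inhibition broad and weak).}
#'   \item{Lex0_a, Lin0_a, sigma_ex_p_a, sigma_in_p_a, sigma_ex_f_a,
#'     sigma_in_f_a}{auditory lateral Mexican-hat parameters along azimuth and
#'     frequency.}
#'   \item{W_av, W_va}{cross-modal synaptic strengths, visual-to-auditory and
#'     auditory-to-visual (scalars, not learned).}
#'   \item{theta_post, alpha_ex0, alpha_in0, Lmax_v, Lmax_a}{Hebbian-rule
#'     parameters: postsynaptic gating threshold, learning factors, and the
#'     saturation ceilings of excitatory weights.}
#'   \item{dt, steady_tol, t_max, n_learning_steps}{Euler step (ms),
#'     steady-state tolerance on the per-step activity change, integration cap
#'     (ms), and the number of integration steps of an adaptation phase.}
#' }
#' @examples
#' cfg <- network_config()
#' cfg$E0_v
#' small <- network_config(n_azimuth_visual = 60, n_azimuth_auditory = 60,
#'                         n_freq_auditory = 20, sigma_p_a = 10, sigma_f_a = 7)
#' @export
network_config <- function(..., file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    vals <- unlist_config(yaml::read_yaml(file))
    cfg <- merge_config(cfg, vals, where = paste0("file '", file, "'"))
  }
  cfg <- merge_config(cfg, list(...), where = "arguments")
  validate_config(cfg)
}

default_config <- function() {
  list(
    n_azimuth_visual = 180L, n_azimuth_auditory = 180L, n_freq_auditory = 40L,
    E0_v = 15, sigma_p_v = 4, sigma_p_a = 30, sigma_f_a = 14,
    s = 0.6, theta = 12, tau_y = 3,
    Lex0_v = 2.4, Lin0_v = 1.4, sigma_ex_p_v = 2, sigma_in_p_v = 24,
    Lex0_a = 0.4, Lin0_a = 0.21,
    sigma_ex_p_a = 1.45, sigma_in_p_a = 8,
    sigma_ex_f_a = 1.45, sigma_in_f_a = 5,
    W_av = 8.5, W_va = 0.22,
    theta_post = 0.5, alpha_ex0 = 0.03, alpha_in0 = 0.05,
    Lmax_v = 2.4, Lmax_a = 0.4,
    dt = 1, steady_tol = 1e-6, t_max = 2000, n_learning_steps = 1000L,
    freq_anchor_hz = 1100, freq_anchor_index = 17L, octaves_per_index = 1 / 5
  )
}

# flatten one level of nesting so YAML files may group parameters in sections
unlist_config <- function(x) {
  out <- list()
  for (nm in names(x)) {
    if (is.list(x[[nm]])) out <- c(out, x[[nm]]) else out[[nm]] <- x[[nm]]
  }
  out
}

merge_config <- function(cfg, vals, where) {
  if (length(vals) == 0) return(cfg)
  if (is.null(names(vals)) || any(names(vals) == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration parameter(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(vals)] <- vals
  cfg
}

validate_config <- function(cfg) {
  num1 <- function(nm) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    v
  }
  counts <- c("n_azimuth_visual", "n_azimuth_auditory", "n_freq_auditory",
              "n_learning_steps")
  for (nm in counts) {
    v <- num1(nm)
    if (v < 1 || v != round(v)) {
      stop("parameter '", nm, "' must be a positive integer", call. = FALSE)
    }
    cfg[[nm]] <- as.integer(v)
  }
  if (cfg$n_azimuth_visual != cfg$n_azimuth_auditory) {
    stop("the visual and auditory azimuth grids must have the same size: ",
         "the cross-modal projection is azimuth-aligned", call. = FALSE)
  }
  positive <- c("sigma_p_v", "sigma_p_a", "sigma_f_a", "s", "tau_y",
                "Lex0_v", "Lin0_v", "sigma_ex_p_v", "sigma_in_p_v",
                "Lex0_a", "Lin0_a", "sigma_ex_p_a", "sigma_in_p_a",
                "sigma_ex_f_a", "sigma_in_f_a", "dt", "steady_tol", "t_max",
                "freq_anchor_hz", "octaves_per_index")
  for (nm in positive) {
    if (num1(nm) <= 0) {
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  nonneg <- c("E0_v", "W_av", "W_va", "alpha_ex0", "alpha_in0",
              "Lmax_v", "Lmax_a", "theta")
  for (nm in nonneg) {
    if (num1(nm) < 0) {
      stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
    }
  }
  tp <- num1("theta_post")
  if (tp <= 0 || tp > 1) {
    stop("theta_post must lie in (0, 1]", call. = FALSE)
  }
  ai <- num1("freq_anchor_index")
  if (ai < 0 || ai >= cfg$n_freq_auditory || ai != round(ai)) {
    stop("freq_anchor_index must be a grid index in [0, n_freq_auditory)",
         call. = FALSE)
  }
  cfg$freq_anchor_index <- as.integer(ai)
  # Mexican-hat shape: excitation stronger and narrower than inhibition
  if (!(cfg$Lex0_v > cfg$Lin0_v && cfg$sigma_ex_p_v < cfg$sigma_in_p_v)) {
    stop("visual lateral kernel violates the Mexican-hat condition ",
         "(need Lex0_v > Lin0_v and sigma_ex_p_v < sigma_in_p_v)",
         call. = FALSE)
  }
  if (!(cfg$Lex0_a > cfg$Lin0_a &&
        cfg$sigma_ex_p_a < cfg$sigma_in_p_a &&
        cfg$sigma_ex_f_a < cfg$sigma_in_f_a)) {
    stop("auditory lateral kernel violates the Mexican-hat condition ",
         "(need Lex0_a > Lin0_a and narrower excitatory widths)",
         call. = FALSE)
  }
  structure(cfg, class = "ventnet_config")
}

#' @export
print.ventnet_config <- function(x, ...) {
  cat("<ventnet_config>\n")
  cat(sprintf("  visual layer: %d azimuths; auditory layer: %d x %d (azimuth x frequency)\n",
              x$n_azimuth_visual, x$n_azimuth_auditory, x$n_freq_auditory))
  cat(sprintf("  frequency grid: %g octaves/index, %g Hz anchored at index %d (%.0f Hz - %.0f Hz)\n",
              x$octaves_per_index, x$freq_anchor_hz, x$freq_anchor_index,
              freq_index_to_hz(0, x),
              freq_index_to_hz(x$n_freq_auditory - 1, x)))
  cat(sprintf("  sigmoid: s = %g, theta = %g; tau_y = %g ms; dt = %g ms\n",
              x$s, x$theta, x$tau_y, x$dt))
  cat(sprintf("  cross-modal: W_av = %g, W_va = %g; Hebbian theta_post = %g\n",
              x$W_av, x$W_va, x$theta_post))
  invisible(x)
}

#' Write a configuration to a YAML file
#'
#' @param cfg a [network_config()] object.
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "ventnet_config"))
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' Circular distance between grid indices
#'
#' Both network dimensions are rings, so the distance between indices `i1` and
#' `i2` on a dimension of `n` neurons is the shorter way around:
#' `min(|i1 - i2|, n - |i1 - i2|)`.
#'
#' @param i1,i2 integer indices in `[0, n)`; vectorized.
#' @param n number of neurons on the dimension.
#' @return nonnegative integer distances, at most `n / 2`.
#' @examples
#' circular_distance(0, 179, 180) # 1: wrap-around neighbours
#' @export
circular_distance <- function(i1, i2, n) {
  if (any(i1 < 0 | i1 >= n) || any(i2 < 0 | i2 >= n)) {
    stop("indices must lie in [0, n)", call. = FALSE)
  }
  d <- abs(i1 - i2)
  pmin(d, n - d)
}

#' Convert between frequency-grid indices and Hz
#'
#' The tonotopic axis is logarithmic with `1 / octaves_per_index` neurons per
#' octave (5 by default): `f(j) = freq_anchor_hz * 2^((j - anchor) / 5)`.
#' `hz_to_freq_index()` resolves a frequency to the nearest grid index and
#' reports the residual (in octaves) as the `"residual_octaves"` attribute.
#'
#' @param j frequency-grid index (0-based); vectorized.
#' @param hz frequency in Hz; vectorized.
#' @param cfg a [network_config()].
#' @return `freq_index_to_hz()`: frequencies in Hz. `hz_to_freq_index()`:
#'   nearest integer indices with attribute `residual_octaves`.
#' @examples
#' cfg <- network_config()
#' freq_index_to_hz(cfg$freq_anchor_index + 5, cfg) # one octave above 1100 Hz
#' @export
freq_index_to_hz <- function(j, cfg) {
  if (any(j < 0 | j >= cfg$n_freq_auditory)) {
    stop("frequency index out of range", call. = FALSE)
  }
  cfg$freq_anchor_hz * 2^((j - cfg$freq_anchor_index) * cfg$octaves_per_index)
}

#' @rdname freq_index_to_hz
#' @export
hz_to_freq_index <- function(hz, cfg) {
  stopifnot(all(hz > 0))
  oct <- log2(hz / cfg$freq_anchor_hz) / cfg$octaves_per_index
  j <- as.integer(round(oct)) + cfg$freq_anchor_index
  if (any(j < 0 | j >= cfg$n_freq_auditory)) {
    stop("frequency outside the grid range (",
         signif(freq_index_to_hz(0, cfg), 3), " Hz - ",
         signif(freq_index_to_hz(cfg$n_freq_auditory - 1, cfg), 3), " Hz)",
         call. = FALSE)
  }
  structure(j, residual_octaves =
    (oct - round(oct)) * cfg$octaves_per_index)
}
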