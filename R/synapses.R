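#' Basal lateral and cross-modal synapses
#'
#' Builds the untrained synaptic state of the network. Within each layer,
#' lateral connectivity is a Mexican hat: the difference of a narrow, strong
#' excitatory Gaussian and a broad, weaker inhibitory Gaussian of circular
#' index distance (separable over azimuth and frequency in the auditory
#' layer). Excitatory and inhibitory components are stored separately because
#' the Hebbian rules treat them separately. Self-connections are zero in both
#' components and stay zero through learning. The per-neuron sums of incoming
#' excitatory and inhibitory weights are recorded at construction: they are
#' the conserved quantities of the population-normalization rule.
#'
#' Two representations are available. `"compact"` stores the auditory lateral
#' weights implicitly as separable circulant kernels plus dense rows only for
#' postsynaptic neurons whose weights have been modified by learning; lateral
#' input is then two small matrix products plus a correction for modified
#' rows. `"dense"` stores full `(np*nf) x (np*nf)` matrices and is intended
#' for small grids, where it serves as the reference implementation the
#' compact engine is verified against.
#'
#' @param cfg a [network_config()].
#' @param representation `"compact"` (default) or `"dense"` for the auditory
#'   layer; the visual layer (180 x 180) is always stored densely.
#' @return an object of class `ventnet_synapses`.
#' @examples
#' syn <- basal_synapses(network_config())
#' @export
basal_synapses <- function(cfg, representation = c("compact", "dense")) {
  stopifnot(inherits(cfg, "ventnet_config"))
  representation <- match.arg(representation)
  npv <- cfg$n_azimuth_visual
  np <- cfg$n_azimuth_auditory
  nf <- cfg$n_freq_auditory

  vis_exc <- cfg$Lex0_v * gauss_ring(npv, cfg$sigma_ex_p_v)
  vis_inh <- cfg$Lin0_v * gauss_ring(npv, cfg$sigma_in_p_v)
  diag(vis_exc) <- 0
  diag(vis_inh) <- 0
  visual <- list(exc = vis_exc, inh = vis_inh,
                 sum_exc = rowSums(vis_exc), sum_inh = rowSums(vis_inh),
                 Lmax = cfg$Lmax_v)

  GA_exc <- gauss_ring(np, cfg$sigma_ex_p_a)
  GF_exc <- gauss_ring(nf, cfg$sigma_ex_f_a)
  GA_inh <- gauss_ring(np, cfg$sigma_in_p_a)
  GF_inh <- gauss_ring(nf, cfg$sigma_in_f_a)
  n_a <- np * nf
  # ring sums are index-independent, so basal incoming sums are uniform
  sum_exc <- rep(cfg$Lex0_a * (sum(GA_exc[, 1]) * sum(GF_exc[, 1]) - 1), n_a)
  sum_inh <- rep(cfg$Lin0_a * (sum(GA_inh[, 1]) * sum(GF_inh[, 1]) - 1), n_a)

  auditory <- if (representation == "compact") {
    list(GA_exc = GA_exc, GF_exc = GF_exc, GA_inh = GA_inh, GF_inh = GF_inh,
         Lex0 = cfg$Lex0_a, Lin0 = cfg$Lin0_a,
         map = integer(n_a), rows = integer(0),
         M_exc = matrix(0, 0, n_a), M_inh = matrix(0, 0, n_a),
         sum_exc = sum_exc, sum_inh = sum_inh, Lmax = cfg$Lmax_a)
  } else {
    exc <- cfg$Lex0_a * kronecker(GF_exc, GA_exc)
    inh <- cfg$Lin0_a * kronecker(GF_inh, GA_inh)
    diag(exc) <- 0
    diag(inh) <- 0
    list(exc = exc, inh = inh,
         sum_exc = sum_exc, sum_inh = sum_inh, Lmax = cfg$Lmax_a)
  }

  structure(
    list(geometry = list(npv = npv, np = np, nf = nf, n_a = n_a),
         representation = representation,
         visual = visual, auditory = auditory,
         W_av = cfg$W_av, W_va = cfg$W_va,
         trained = FALSE, provenance = NULL),
    class = "ventnet_synapses")
}

# symmetric circulant Gaussian kernel matrix of a ring of n neurons
gauss_ring <- function(n, sigma) {
  idx <- 0:(n - 1)
  d <- outer(idx, idx, function(a, b) {
    dd <- abs(a - b)
    pmin(dd, n - dd)
  })
  exp(-d^2 / (2 * sigma^2))
}

# column-major flattening of the auditory grid: p = i + 1 + j * np
# for 0-based azimuth i and frequency j (matches as.vector() of the
# np x nf activity matrix)
aud_index <- function(i, j, np) i + 1L + j * np

# basal (untrained) incoming weight row of one auditory postsynaptic neuron
basal_row <- function(aud, p, component = c("exc", "inh")) {
  component <- match.arg(component)
  np <- nrow(aud$GA_exc)
  i <- (p - 1L) %% np + 1L
  j <- (p - 1L) %/% np + 1L
  r <- if (component == "exc") {
    aud$Lex0 * as.vector(outer(aud$GA_exc[, i], aud$GF_exc[, j]))
  } else {
    aud$Lin0 * as.vector(outer(aud$GA_inh[, i], aud$GF_inh[, j]))
  }
  r[p] <- 0
  r
}

#' Inspect incoming lateral weights of one neuron
#'
#' Returns the full incoming excitatory and inhibitory lateral weight vector
#' of a single postsynaptic neuron as a tidy table, together with the
#' difference from its untrained value. Works for both representations.
#'
#' @param syn a [basal_synapses()] or trained synaptic state.
#' @param layer `"auditory"` or `"visual"`.
#' @param azimuth postsynaptic azimuth in degrees (0-based index).
#' @param freq_index postsynaptic frequency index (auditory layer only).
#' @return a tibble with one row per presynaptic neuron: `pre_azimuth`,
#'   `exc`, `inh`, and — for the auditory layer — `pre_freq_index` plus the
#'   untrained values `exc_basal`, `inh_basal`.
#' @export
synaptic_weights <- function(syn, layer = c("auditory", "visual"),
                             azimuth, freq_index = NULL) {
  stopifnot(inherits(syn, "ventnet_synapses"))
  layer <- match.arg(layer)
  if (layer == "visual") {
    i <- azimuth + 1L
    stopifnot(i >= 1, i <= syn$geometry$npv)
    return(tibble::tibble(
      pre_azimuth = 0:(syn$geometry$npv - 1L),
      exc = syn$visual$exc[i, ],
      inh = syn$visual$inh[i, ]))
  }
  stopifnot(!is.null(freq_index))
  np <- syn$geometry$np
  nf <- syn$geometry$nf
  p <- aud_index(azimuth, freq_index, np)
  stopifnot(p >= 1, p <= syn$geometry$n_a)
  if (syn$representation == "compact") {
    exc_b <- basal_row(syn$auditory, p, "exc")
    inh_b <- basal_row(syn$auditory, p, "inh")
    r <- syn$auditory$map[p]
    exc <- if (r > 0) syn$auditory$M_exc[r, ] else exc_b
    inh <- if (r > 0) syn$auditory$M_inh[r, ] else inh_b
  } else {
    exc <- syn$auditory$exc[p, ]
    inh <- syn$auditory$inh[p, ]
    tmp <- basal_synapses_row_dense(syn, p)
    exc_b <- tmp$exc
    inh_b <- tmp$inh
  }
  tibble::tibble(
    pre_azimuth = rep(0:(np - 1L), nf),
    pre_freq_index = rep(0:(nf - 1L), each = np),
    exc = exc, inh = inh, exc_basal = exc_b, inh_basal = inh_b)
}

# dense stores keep a copy of the basal matrices from the first learning
# step onward (see apply_plasticity); before training, current == basal
basal_synapses_row_dense <- function(syn, p) {
  aud <- syn$auditory
  if (!is.null(aud$exc_basal)) {
    list(exc = aud$exc_basal[p, ], inh = aud$inh_basal[p, ])
  } else {
    list(exc = aud$exc[p, ], inh = aud$inh[p, ])
  }
}

#' @export
print.ventnet_synapses <- function(x, ...) {
  g <- x$geometry
  cat("<ventnet_synapses>\n")
  cat(sprintf("  visual layer: %d neurons (dense lateral weights)\n", g$npv))
  cat(sprintf("  auditory layer: %d x %d neurons, %s representation\n",
              g$np, g$nf, x$representation))
  if (x$representation == "compact") {
    cat(sprintf("  modified auditory rows: %d of %d\n",
                length(x$auditory$rows), g$n_a))
  }
  cat(sprintf("  cross-modal: W_av = %g, W_va = %g\n", x$W_av, x$W_va))
  cat(sprintf("  trained: %s\n", if (x$trained) "yes" else "no"))
  if (!is.null(x$provenance)) {
    cat("  provenance:", x$provenance$label, "\n")
  }
  invisible(x)
}
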