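#' Hebbian weight changes for one layer
#'
#' Threshold-gated potentiation rule applied to the lateral synapses of a
#' layer, written for full weight matrices (rows = postsynaptic neurons,
#' columns = presynaptic neurons). Excitatory synapses grow towards their
#' saturation ceiling and inhibitory synapses shrink towards zero whenever
#' pre- and postsynaptic activity are correlated and the postsynaptic
#' activity exceeds the gate `theta_post`:
#'
#' \deqn{\Delta L_{ex} = \alpha_{ex0} (L_{max} - L_{ex})\, y_{pre}\, [y_{post} - \theta_{post}]^+}
#' \deqn{\Delta L_{in} = -\alpha_{in0}\, L_{in}\, y_{pre}\, [y_{post} - \theta_{post}]^+}
#'
#' Self-connections receive no change (they do not exist in the network).
#'
#' @param y activity vector of the layer (values in `[0, 1]`), indexed like
#'   the rows/columns of the weight matrices.
#' @param exc,inh square weight matrices of the excitatory and inhibitory
#'   lateral components.
#' @param cfg a [network_config()] (supplies `alpha_ex0`, `alpha_in0`,
#'   `theta_post`).
#' @param Lmax saturation ceiling of the excitatory weights for this layer.
#' @return a list with matrices `exc` and `inh` of weight increments.
#' @export
hebbian_deltas <- function(y, exc, inh, cfg, Lmax) {
  stopifnot(length(y) == nrow(exc), nrow(exc) == ncol(exc),
            all(dim(exc) == dim(inh)))
  gate <- pmax(y - cfg$theta_post, 0)
  corr <- outer(gate, y) # [post, pre]
  d_exc <- cfg$alpha_ex0 * (Lmax - exc) * corr
  d_inh <- -cfg$alpha_in0 * inh * corr
  diag(d_exc) <- 0
  diag(d_inh) <- 0
  list(exc = d_exc, inh = d_inh)
}

#' Population normalization of incoming weights
#'
#' Rescales each postsynaptic neuron's incoming weights multiplicatively so
#' that their sum returns to its basal (construction-time) value. Applied
#' separately to the excitatory and the inhibitory component after every
#' learning step: if some incoming excitatory synapses grow, the others must
#' shrink.
#'
#' @param W weight matrix (rows = postsynaptic neurons).
#' @param target_sums basal incoming sums, one per row.
#' @return the rescaled matrix.
#' @export
normalize_incoming <- function(W, target_sums) {
  stopifnot(length(target_sums) == nrow(W))
  s <- rowSums(W)
  bad <- s <= 0 & target_sums > 0
  if (any(bad)) {
    stop("degenerate normalization: zero incoming-weight sum for ",
         sum(bad), " neuron(s)", call. = FALSE)
  }
  f <- ifelse(s > 0, target_sums / s, 1)
  W * f
}

# one learning application on the compact auditory store: update only rows
# of currently supra-threshold postsynaptic neurons, materializing their
# basal rows on first modification
plasticity_step_auditory_compact <- function(aud, y_a, cfg) {
  vy <- as.vector(y_a)
  gate <- pmax(vy - cfg$theta_post, 0)
  active <- which(gate > 0)
  if (!length(active)) return(aud)
  fresh <- active[aud$map[active] == 0L]
  if (length(fresh)) {
    n <- length(vy)
    aud$M_exc <- rbind(aud$M_exc,
                       t(vapply(fresh, function(p) basal_row(aud, p, "exc"),
                                numeric(n))))
    aud$M_inh <- rbind(aud$M_inh,
                       t(vapply(fresh, function(p) basal_row(aud, p, "inh"),
                                numeric(n))))
    aud$map[fresh] <- length(aud$rows) + seq_along(fresh)
    aud$rows <- c(aud$rows, fresh)
  }
  r <- aud$map[active]
  corr <- gate[active] %o% vy
  self <- cbind(seq_along(active), active)

  R <- aud$M_exc[r, , drop = FALSE]
  R <- R + cfg$alpha_ex0 * (aud$Lmax - R) * corr
  R[self] <- 0
  aud$M_exc[r, ] <- normalize_incoming(R, aud$sum_exc[active])

  R <- aud$M_inh[r, , drop = FALSE]
  R <- R * (1 - cfg$alpha_in0 * corr)
  aud$M_inh[r, ] <- normalize_incoming(R, aud$sum_inh[active])
  aud
}

# dense-matrix learning application (any layer); lyr holds exc/inh/sums/Lmax
plasticity_step_dense <- function(lyr, y, cfg) {
  vy <- as.vector(y)
  gate <- pmax(vy - cfg$theta_post, 0)
  active <- which(gate > 0)
  if (!length(active)) return(lyr)
  corr <- gate[active] %o% vy
  self <- cbind(seq_along(active), active)

  R <- lyr$exc[active, , drop = FALSE]
  R <- R + cfg$alpha_ex0 * (lyr$Lmax - R) * corr
  R[self] <- 0
  lyr$exc[active, ] <- normalize_incoming(R, lyr$sum_exc[active])

  R <- lyr$inh[active, , drop = FALSE]
  R <- R * (1 - cfg$alpha_in0 * corr)
  lyr$inh[active, ] <- normalize_incoming(R, lyr$sum_inh[active])
  lyr
}

apply_plasticity <- function(syn, state, cfg,
                             layers = c("visual", "auditory")) {
  if ("visual" %in% layers) {
    syn$visual <- plasticity_step_dense(syn$visual, state$y_v, cfg)
  }
  if ("auditory" %in% layers) {
    if (syn$representation == "compact") {
      syn$auditory <-
        plasticity_step_auditory_compact(syn$auditory, state$y_a, cfg)
    } else {
      if (is.null(syn$auditory$exc_basal)) {
        syn$auditory$exc_basal <- syn$auditory$exc
        syn$auditory$inh_basal <- syn$auditory$inh
      }
      syn$auditory <- plasticity_step_dense(syn$auditory, state$y_a, cfg)
    }
  }
  syn
}

#' Adaptation: exposure with Hebbian learning
#'
#' Implements the adaptation protocol: starting from the network null
#' condition, the (typically spatially discrepant, bimodal) stimulus is held
#' constant for `n_steps` Euler integration steps. After every step the
#' Hebbian increments are computed from the new activities and the incoming
#' weights of every postsynaptic neuron are renormalized to their basal
#' sums. Learning acts on the lateral synapses of both layers (the
#' cross-modal weights are fixed), from the very first step.
#'
#' @param syn a [basal_synapses()] state (or a previously trained state to
#'   continue from).
#' @param stim the adaptation [stimulus()]; the canonical protocol uses a
#'   visual flash at 100 deg together with a tone at 80 deg / 1.1 kHz.
#' @param cfg a [network_config()].
#' @param n_steps number of integration (= learning) steps; defaults to
#'   `cfg$n_learning_steps` (1000).
#' @param layers which layers learn; default both.
#' @return an object of class `ventnet_adaptation`: a list with
#'   \describe{
#'     \item{synapses}{the trained `ventnet_synapses` (flagged `trained`,
#'       with provenance describing the adaptation stimulus).}
#'     \item{final_state}{the network state after the last step.}
#'     \item{trace}{a tibble with one row per step: `step`, `t`,
#'       `n_supra_visual`, `n_supra_auditory` (neurons above `theta_post`).}
#'   }
#' @export
adapt_network <- function(syn, stim, cfg, n_steps = cfg$n_learning_steps,
                          layers = c("visual", "auditory")) {
  stopifnot(inherits(syn, "ventnet_synapses"), n_steps >= 1)
  layers <- match.arg(layers, several.ok = TRUE)
  e_v <- visual_input(stim, cfg)
  e_a <- auditory_input(stim, cfg)
  state <- new_state(cfg)
  n_sv <- integer(n_steps)
  n_sa <- integer(n_steps)
  for (k in seq_len(n_steps)) {
    state <- network_step(state, syn, e_v, e_a, cfg)
    syn <- apply_plasticity(syn, state, cfg, layers)
    n_sv[k] <- sum(state$y_v > cfg$theta_post)
    n_sa[k] <- sum(state$y_a > cfg$theta_post)
  }
  syn$trained <- TRUE
  syn$provenance <- list(
    label = sprintf(
      "adaptation: V@%s, A@%s/f%s, E0_a=%s, %d steps of %g ms",
      if (stim$visual_present) stim$visual_azimuth else "-",
      if (stim$auditory_present) stim$auditory_azimuth else "-",
      if (stim$auditory_present)
        resolve_stimulus(stim, cfg)$auditory_freq_index else "-",
      if (stim$auditory_present) stim$auditory_intensity else "-",
      n_steps, cfg$dt),
    stimulus = stim, n_steps = n_steps, dt = cfg$dt, layers = layers)
  structure(
    list(synapses = syn, final_state = state,
         trace = tibble::tibble(step = seq_len(n_steps),
                                t = seq_len(n_steps) * cfg$dt,
                                n_supra_visual = n_sv,
                                n_supra_auditory = n_sa)),
    class = "ventnet_adaptation")
}

#' @export
print.ventnet_adaptation <- function(x, ...) {
  cat("<ventnet_adaptation>\n")
  cat("  ", x$synapses$provenance$label, "\n", sep = "")
  cat(sprintf("  supra-threshold at last step: %d visual, %d auditory\n",
              dplyr::last(x$trace$n_supra_visual),
              dplyr::last(x$trace$n_supra_auditory)))
  invisible(x)
}
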