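#' Sigmoidal activation function
#'
#' Static input-output relationship of every neuron: a logistic function with
#' slope `s` and centre `theta`, saturating at 1 (activities are normalized
#' to the maximal firing rate).
#'
#' @param u net input (any numeric array).
#' @param cfg a [network_config()].
#' @return activations in (0, 1), same shape as `u`.
#' @export
activation <- function(u, cfg) {
  1 / (1 + exp(-cfg$s * (u - cfg$theta)))
}

new_state <- function(cfg) {
  structure(
    list(y_v = numeric(cfg$n_azimuth_visual),
         y_a = matrix(0, cfg$n_azimuth_auditory, cfg$n_freq_auditory),
         u_v = numeric(cfg$n_azimuth_visual),
         u_a = matrix(0, cfg$n_azimuth_auditory, cfg$n_freq_auditory),
         t = 0, n_steps = 0L, converged = NA),
    class = "ventnet_state")
}

#' @export
print.ventnet_state <- function(x, ...) {
  cat("<ventnet_state>\n")
  cat(sprintf("  t = %g ms (%d steps), converged: %s\n", x$t, x$n_steps,
              ifelse(is.na(x$converged), "not assessed", x$converged)))
  cat(sprintf("  visual activity:   max %.4f\n", max(x$y_v)))
  cat(sprintf("  auditory activity: max %.4f\n", max(x$y_a)))
  invisible(x)
}

# lateral input to the visual layer (dense weights)
lateral_input_visual <- function(syn, y_v) {
  as.vector((syn$visual$exc - syn$visual$inh) %*% y_v)
}

# lateral input to the auditory layer; compact path evaluates the separable
# circulant kernels as two small matrix products (the -Y term removes the
# self-connection, whose kernel value is 1 * 1) and then overwrites the
# entries of learning-modified postsynaptic rows with exact dot products
lateral_input_auditory <- function(syn, y_a) {
  aud <- syn$auditory
  if (syn$representation == "dense") {
    return(matrix((aud$exc - aud$inh) %*% as.vector(y_a),
                  nrow(y_a), ncol(y_a)))
  }
  base <- aud$Lex0 * (aud$GA_exc %*% y_a %*% aud$GF_exc - y_a) -
          aud$Lin0 * (aud$GA_inh %*% y_a %*% aud$GF_inh - y_a)
  if (length(aud$rows)) {
    vy <- as.vector(y_a)
    base[aud$rows] <- as.vector(aud$M_exc %*% vy) - as.vector(aud$M_inh %*% vy)
  }
  base
}

#' Net inputs to both layers
#'
#' The net input of a neuron is the sum of its external input, its lateral
#' (within-layer) input, and its cross-modal input. The cross-modal coupling
#' is azimuth-aligned: each visual neuron receives `W_va` times the summed
#' activity of the whole frequency column of auditory neurons at its azimuth,
#' and each auditory neuron receives `W_av` times the activity of the visual
#' neuron at its azimuth (the same value for every frequency).
#'
#' @param state a `ventnet_state` (see [run_to_steady_state()]).
#' @param syn a [basal_synapses()] or trained synaptic state.
#' @param e_v,e_a external input fields from [visual_input()] and
#'   [auditory_input()].
#' @return a list with elements `u_v` (vector) and `u_a` (matrix).
#' @export
net_inputs <- function(state, syn, e_v, e_a) {
  g <- syn$geometry
  if (length(state$y_v) != g$npv || !all(dim(state$y_a) == c(g$np, g$nf)) ||
      length(e_v) != g$npv || !all(dim(e_a) == c(g$np, g$nf))) {
    stop("state/input shapes do not match the synaptic geometry",
         call. = FALSE)
  }
  u_v <- e_v + lateral_input_visual(syn, state$y_v) +
    syn$W_va * rowSums(state$y_a)
  # column recycling adds y_v[i] to every frequency at azimuth i
  u_a <- e_a + lateral_input_auditory(syn, state$y_a) + syn$W_av * state$y_v
  list(u_v = u_v, u_a = u_a)
}

#' One Euler integration step
#'
#' Advances the first-order rate dynamics
#' `tau_y * dy/dt = -y + F(u)` by one explicit Euler step of length `dt`:
#' net inputs are computed synchronously from the current activities, then
#' `y <- y + (dt / tau_y) * (-y + F(u))`.
#'
#' @inheritParams net_inputs
#' @param cfg a [network_config()].
#' @return the updated `ventnet_state` (with `u_v`, `u_a` of the step just
#'   taken).
#' @export
network_step <- function(state, syn, e_v, e_a, cfg) {
  u <- net_inputs(state, syn, e_v, e_a)
  r <- cfg$dt / cfg$tau_y
  state$y_v <- state$y_v + r * (-state$y_v + activation(u$u_v, cfg))
  state$y_a <- state$y_a + r * (-state$y_a + activation(u$u_a, cfg))
  state$u_v <- u$u_v
  state$u_a <- u$u_a
  state$t <- state$t + cfg$dt
  state$n_steps <- state$n_steps + 1L
  state
}

#' Integrate the network to steady state
#'
#' Starting from the null condition (all activities zero), applies the
#' stimulus constantly and integrates until the largest per-step activity
#' change falls below `cfg$steady_tol`, or until `cfg$t_max` ms have elapsed.
#' Non-convergence is flagged on the returned state (`converged = FALSE`)
#' and raised as a warning, never silent.
#'
#' @param syn a [basal_synapses()] or trained synaptic state.
#' @param stim a [stimulus()].
#' @param cfg a [network_config()].
#' @param snapshot_times optional numeric vector of times (ms) at which to
#'   record the full auditory activity map; snapshots are taken at the first
#'   step whose time reaches each requested time.
#' @return a `ventnet_state`: activities `y_v` (vector), `y_a` (matrix), net
#'   inputs, elapsed time `t`, `n_steps`, `converged`, and (if requested)
#'   `snapshots`, a named list of auditory activity matrices.
#' @examples
#' cfg <- network_config(n_azimuth_visual = 60, n_azimuth_auditory = 60,
#'                       n_freq_auditory = 12, sigma_p_a = 10, sigma_f_a = 4,
#'                       sigma_in_p_a = 5, sigma_in_f_a = 2.5)
#' syn <- basal_synapses(cfg)
#' st <- run_to_steady_state(syn, stimulus(auditory_azimuth = 30,
#'                                         auditory_freq_index = 6,
#'                                         auditory_intensity = 20), cfg)
#' st$converged
#' @export
run_to_steady_state <- function(syn, stim, cfg, snapshot_times = NULL) {
  e_v <- visual_input(stim, cfg)
  e_a <- auditory_input(stim, cfg)
  state <- new_state(cfg)
  snaps <- list()
  next_snap <- sort(snapshot_times)
  repeat {
    y_v0 <- state$y_v
    y_a0 <- state$y_a
    state <- network_step(state, syn, e_v, e_a, cfg)
    if (length(next_snap) && state$t >= next_snap[1] - 1e-9) {
      snaps[[sprintf("t=%gms", next_snap[1])]] <- state$y_a
      next_snap <- next_snap[-1]
    }
    dmax <- max(max(abs(state$y_v - y_v0)), max(abs(state$y_a - y_a0)))
    if (dmax < cfg$steady_tol) {
      state$converged <- TRUE
      break
    }
    if (state$t >= cfg$t_max) {
      state$converged <- FALSE
      warning("network did not reach steady state within t_max = ",
              cfg$t_max, " ms (last per-step change ", signif(dmax, 3), ")",
              call. = FALSE)
      break
    }
  }
  if (length(snaps)) state$snapshots <- snaps
  state
}
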