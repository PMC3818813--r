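#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network state into a long activity table
#'
#' @param x a `ventnet_state`.
#' @param ... unused.
#' @return a tibble with columns `layer`, `azimuth_deg`, `freq_index`
#'   (`NA` for the visual layer), `activity`.
#' @export
tidy.ventnet_state <- function(x, ...) {
  np <- nrow(x$y_a)
  nf <- ncol(x$y_a)
  dplyr::bind_rows(
    tibble::tibble(layer = "visual",
                   azimuth_deg = seq_along(x$y_v) - 1,
                   freq_index = NA_integer_,
                   activity = x$y_v),
    tibble::tibble(layer = "auditory",
                   azimuth_deg = rep(0:(np - 1), nf),
                   freq_index = rep(0:(nf - 1), each = np),
                   activity = as.vector(x$y_a)))
}

#' @rdname tidy.ventnet_state
#' @export
glance.ventnet_state <- function(x, ...) {
  tibble::tibble(t = x$t, n_steps = x$n_steps, converged = x$converged,
                 max_activity_visual = max(x$y_v),
                 max_activity_auditory = max(x$y_a))
}

#' Tidy an adaptation result
#'
#' `tidy()` returns the per-step learning trace; `glance()` a one-row
#' summary of the adaptation run.
#'
#' @param x a `ventnet_adaptation` from [adapt_network()].
#' @param ... unused.
#' @export
tidy.ventnet_adaptation <- function(x, ...) x$trace

#' @rdname tidy.ventnet_adaptation
#' @export
glance.ventnet_adaptation <- function(x, ...) {
  p <- x$synapses$provenance
  tibble::tibble(
    n_steps = p$n_steps, dt = p$dt,
    layers = paste(p$layers, collapse = "+"),
    n_modified_auditory_rows =
      if (x$synapses$representation == "compact")
        length(x$synapses$auditory$rows) else NA_integer_,
    max_supra_auditory = max(x$trace$n_supra_auditory),
    final_t = x$final_state$t)
}
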