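#' Expand per-type LIF parameters to per-neuron vectors
#'
#' @param placement A placement; only LIF cell types (everything except MF
#'   and IO, which are spike sources) get state.
#' @param params Per-type parameter tibble, default [lif_params()].
#' @return List of per-neuron numeric vectors (\code{C_m}, \code{g_L}, ...)
#'   plus \code{cell_type}, \code{global_id} and \code{n}.
#' @export
expand_lif_params <- function(placement, params = lif_params()) {
  lif <- placement[placement$cell_type %in% params$cell_type, ]
  idx <- match(lif$cell_type, params$cell_type)
  out <- lapply(stats::setNames(nm = setdiff(names(params), "cell_type")),
                function(col) params[[col]][idx])
  out$cell_type <- lif$cell_type
  out$global_id <- lif$id
  out$n <- nrow(lif)
  out
}

#' Initialize network state
#'
#' Membrane potentials start at each type's resting potential, conductances
#' at zero, no refractoriness.
#'
#' @param params Expanded per-neuron parameters from [expand_lif_params()].
#' @return A \code{network_state} list with \code{u} (mV), \code{g_exc},
#'   \code{g_inh} (nS), \code{refrac} (ms remaining), \code{t} (ms).
#' @export
network_state_init <- function(params) {
  n <- params$n
  structure(
    list(u = params$E_L, g_exc = numeric(n), g_inh = numeric(n),
         refrac = numeric(n), t = 0),
    class = "network_state"
  )
}

#' One forward-Euler substep of the conductance-based LIF equations
#'
#' Membrane update for non-refractory units:
#' \deqn{u \leftarrow u + \frac{dt}{C_m}\left(-g_L(u - E_L) + I_e
#'   - g_{exc}(u - E_{exc}) - g_{inh}(u - E_{inh})\right)}
#' Refractory units stay clamped at \code{V_r} with their timers
#' decremented. Conductances then decay by the same Euler rule,
#' \eqn{g \leftarrow g (1 - dt/\tau)}. Units are mutually consistent:
#' nS x mV = pA, and pA x ms / pF = mV.
#'
#' @param state A \code{network_state}.
#' @param params Expanded per-neuron parameters.
#' @param dt Substep in ms (default 0.1).
#' @param reversal Named vector with \code{E_exc}, \code{E_inh}.
#' @return Updated state.
#' @export
lif_substep <- function(state, params, dt = 0.1,
                        reversal = reversal_potentials()) {
  refr <- state$refrac > dt / 2
  I <- -params$g_L * (state$u - params$E_L) + params$I_e -
    state$g_exc * (state$u - reversal[["E_exc"]]) -
    state$g_inh * (state$u - reversal[["E_inh"]])
  u_new <- state$u + dt / params$C_m * I
  state$u <- ifelse(refr, params$V_r, u_new)
  state$refrac <- pmax(state$refrac - ifelse(refr, dt, 0), 0)
  if (any(!is.finite(state$u))) {
    bad <- which(!is.finite(state$u))[1]
    stop(sprintf("non-finite membrane potential at neuron %d, t = %g ms",
                 bad, state$t), call. = FALSE)
  }
  state$g_exc <- state$g_exc * (1 - dt / params$tau_exc)
  state$g_inh <- state$g_inh * (1 - dt / params$tau_inh)
  state$t <- state$t + dt
  state
}

#' Threshold detection and reset
#'
#' Neurons at or above threshold emit a spike, are reset to \code{V_r}, and
#' enter their refractory period. Refractory neurons never spike.
#'
#' @inheritParams lif_substep
#' @return List with updated \code{state} and integer \code{spikes}
#'   (state indices of neurons that fired this substep).
#' @export
detect_and_reset <- function(state, params, dt = 0.1) {
  fired <- which(state$u >= params$V_th & state$refrac <= dt / 2)
  if (length(fired)) {
    state$u[fired] <- params$V_r[fired]
    state$refrac[fired] <- params$t_ref[fired]
  }
  list(state = state, spikes = fired)
}

#' Deliver synaptic spike arrivals
#'
#' Adds the summed arriving weights to the target conductance channel; the
#' conductance jumps instantaneously and decays exponentially afterwards
#' (handled by [lif_substep()]).
#'
#' @param state A \code{network_state}.
#' @param arrivals Numeric vector (length = number of neurons) of summed
#'   synaptic weights (nS) arriving this exchange step.
#' @param sign \code{"exc"} or \code{"inh"}.
#' @return Updated state.
#' @export
deliver_spikes <- function(state, arrivals, sign = c("exc", "inh")) {
  sign <- match.arg(sign)
  if (any(arrivals < 0)) stop("synaptic weights must be non-negative", call. = FALSE)
  slot <- if (sign == "exc") "g_exc" else "g_inh"
  state[[slot]] <- state[[slot]] + arrivals
  state
}

# deterministic counter-based substream: mixing (seed, stream, step) into a
# 31-bit state so that regenerating any step yields identical draws
# irrespective of call order.
counter_mix <- function(seed, stream, step) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 69069 + as.numeric(stream) * 30269 +
    as.numeric(step) * 30307 + 1
  as.integer(s %% m)
}

counter_uniform <- function(seed, stream, step, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(counter_mix(seed, stream, step))
  stats::runif(n)
}

#' Describe a Poisson stimulus
#'
#' A set of spike sources (mossy fibers or the inferior olive) firing as
#' independent inhomogeneous Poisson processes on the 1 ms exchange grid.
#' The rate is either constant or a raised-cosine sinusoid
#' \eqn{r(t) = (r_{max}/2)(1 - \cos(2\pi (t - t_{on} - \phi)/T))}, which
#' sweeps 0 to \code{r_max} Hz over one period.
#'
#' @param targets Integer vector of global source ids.
#' @param rate Constant rate in Hz (scalar), ignored if \code{r_max} given.
#' @param r_max,period Peak rate (Hz) and period (ms) of the sinusoid.
#' @param phase Phase offset in ms added to the sinusoid argument.
#' @param t_on,t_off Active window \code{[t_on, t_off)} in ms.
#' @param stream Integer stream id separating independent stimuli.
#' @return A \code{stimulus_spec} object.
#' @export
stimulus_spec <- function(targets, rate = 0, r_max = NULL, period = NULL,
                          phase = 0, t_on = 0, t_off = Inf, stream = 0L) {
  if (is.null(r_max) && rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.null(r_max) && (r_max < 0 || is.null(period) || period <= 0)) {
    stop("sinusoid needs r_max >= 0 and period > 0", call. = FALSE)
  }
  structure(
    list(targets = as.integer(targets), rate = rate, r_max = r_max,
         period = period, phase = phase, t_on = t_on, t_off = t_off,
         stream = as.integer(stream)),
    class = "stimulus_spec"
  )
}

#' Instantaneous rate of a stimulus
#' @param spec A [stimulus_spec()].
#' @param t_ms Time in ms.
#' @return Rate in Hz (0 outside the active window).
#' @export
stimulus_rate <- function(spec, t_ms) {
  if (t_ms < spec$t_on || t_ms >= spec$t_off) return(0)
  if (is.null(spec$r_max)) return(spec$rate)
  spec$r_max / 2 * (1 - cos(2 * pi * (t_ms - spec$t_on - spec$phase) / spec$period))
}

#' Generate source spikes for one exchange step
#'
#' Each target fires independently with probability
#' \eqn{\min(r(t) \cdot 0.001, 1)} within the 1 ms step. The stream is
#' counter-based: regenerating any step gives identical output regardless
#' of the order in which steps are evaluated.
#'
#' @param spec A [stimulus_spec()].
#' @param step Integer ms index (the step covers \code{[step, step + 1)} ms).
#' @param seed Master seed.
#' @return Integer vector of global ids of sources spiking in this step.
#' @export
poisson_sources <- function(spec, step, seed = 1) {
  r <- stimulus_rate(spec, step)
  if (r < 0) stop("rate must be >= 0", call. = FALSE)
  if (r == 0 || length(spec$targets) == 0) return(integer())
  p <- min(r * 1e-3, 1)
  u <- counter_uniform(seed, spec$stream, step, length(spec$targets))
  spec$targets[u < p]
}
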