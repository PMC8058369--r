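#' Reference plasticity state
#'
#' A self-contained representation of the PF->PC plastic weights used by
#' the per-operation contracts and tests: the per-synapse dimensionless
#' factor \code{w}, the presynaptic index \code{pre} of each synapse, a
#' per-parallel-fiber binary spike history over the trailing
#' \code{window + 1} one-ms bins, and the current climbing-fiber flag.
#' The engine maintains an equivalent flat representation internally.
#'
#' @param w Numeric weight factors per synapse.
#' @param pre 1-based presynaptic (parallel fiber) index per synapse.
#' @param n_pf Number of parallel fibers.
#' @param window Eligibility window in ms.
#' @return A \code{plasticity_state} list with \code{w}, \code{pre},
#'   \code{history} (matrix \code{n_pf x (window + 1)}, most recent column
#'   last), \code{cf} flag.
#' @export
plasticity_state <- function(w, pre, n_pf, window = 50L) {
  stopifnot(length(w) == length(pre), all(pre >= 1), all(pre <= n_pf))
  structure(
    list(w = as.numeric(w), pre = as.integer(pre), n_pf = as.integer(n_pf),
         history = matrix(0L, n_pf, window + 1L), cf = FALSE),
    class = "plasticity_state"
  )
}

#' Advance the plasticity state by one millisecond
#'
#' Pushes this step's parallel-fiber spike indicators and climbing-fiber
#' flag into the state, then applies the weight update to every synapse:
#' \deqn{w \leftarrow w + \lambda_{LTP}(w_{init} - w)
#'   - \lambda_{LTD}\, w\, CF(t) \sum_{\Delta t = 0}^{W} PF_j(t - \Delta t)}
#' clamped below at \code{w_floor}. Without climbing-fiber activity the
#' weight relaxes geometrically toward \code{w_init}; with conjunctive
#' PF+CF activity it is depressed multiplicatively.
#'
#' @param ps A [plasticity_state()].
#' @param pp A [plasticity_params()].
#' @param pf_spikes Integer vector of parallel fibers spiking this ms
#'   (1-based; multiple spikes in one ms count once).
#' @param cf_spike Logical: did the climbing fiber spike this ms?
#' @return Updated \code{plasticity_state}.
#' @export
update_weights <- function(ps, pp, pf_spikes = integer(), cf_spike = FALSE) {
  if (ncol(ps$history) != pp$window + 1L) {
    stop("history length does not match the plasticity window", call. = FALSE)
  }
  ps$history <- cbind(ps$history[, -1L, drop = FALSE],
                      as.integer(tabulate(pf_spikes, nbins = ps$n_pf) > 0L))
  ps$cf <- isTRUE(cf_spike)
  elig <- rowSums(ps$history)
  w <- ps$w
  ltd <- if (ps$cf) pp$ltd_rate * w * elig[ps$pre] else 0
  gate <- if (isTRUE(pp$ltp_gated)) ps$history[ps$pre, ncol(ps$history)] else 1
  ps$w <- pmax(w + pp$ltp_rate * (pp$w_init - w) * gate - ltd, pp$w_floor)
  ps
}

#' Effective synaptic conductance of a plastic synapse
#'
#' Links the dimensionless plastic factor to the rule's base conductance:
#' the delivered PF->PC jump is \code{w * rule_weight} nS.
#'
#' @param w Weight factor(s), >= 0.
#' @param rule_weight Base weight in nS (default the PF-PC value, 0.02 nS).
#' @return Conductance in nS.
#' @export
effective_weight <- function(w, rule_weight = 0.02) {
  stopifnot(all(w >= 0))
  w * rule_weight
}
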