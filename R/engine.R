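#' Assemble a runnable network
#'
#' Binds a placement, a synapse store, and neuron parameters into the
#' flat arrays the simulation loop consumes: per-neuron parameter vectors
#' in state order (all LIF cells, i.e. every type except the MF and IO
#' spike sources), and per-rule presynaptic-major adjacency for spike
#' scatter.
#'
#' @param placement A placement.
#' @param store A synapse store.
#' @param lif Per-type LIF parameter tibble, default [lif_params()].
#' @param reversal Reversal potentials, default [reversal_potentials()].
#' @return A \code{cereb_network} object.
#' @export
build_network <- function(placement, store, lif = lif_params(),
                          reversal = reversal_potentials()) {
  par <- expand_lif_params(placement, lif)
  counts <- table(factor(placement$cell_type, levels = cell_type_order()))
  n_mf <- as.integer(counts[["MF"]])
  # state index = global id - n_mf for the LIF block (MF first, IO last)
  lif_types <- setdiff(cell_type_order(), c("MF", "IO"))
  first_state <- cumsum(c(0, as.integer(counts[lif_types])))
  names(first_state) <- c(lif_types, "end")
  rules <- lapply(store, function(r) {
    e <- expand_csr(r$csr)
    o <- order(e$pre, e$post)
    pre_s <- e$pre[o]; post_s <- e$post[o]
    p0 <- c(0L, cumsum(tabulate(pre_s + 1L, nbins = r$csr$n_pre)))
    tgt <- post_s + first_state[[r$post]]
    list(name = r$name, pre = r$pre, post = r$post, sign = r$sign,
         weight = r$weight, delay = r$delay,
         p = as.integer(p0), tgt = as.integer(tgt),
         n_pre = r$csr$n_pre)
  })
  structure(
    list(placement = placement, store = store, params = par,
         reversal = reversal, rules = rules, n_mf = n_mf,
         n_lif = par$n, first_state = first_state,
         io_id = unname(id_range(placement, "IO")[1])),
    class = "cereb_network"
  )
}

#' @export
print.cereb_network <- function(x, ...) {
  cat(sprintf("<cereb_network> %d sources (MF), %d LIF neurons, %d rules\n",
              x$n_mf, x$n_lif, length(x$rules)))
  invisible(x)
}

#' Configure plasticity at parallel fiber-Purkinje cell synapses
#'
#' Bidirectional plasticity applied once per 1 ms exchange step to every
#' PF->PC synapse: an LTP term relaxing the dimensionless weight factor
#' toward \code{w_init} at \code{ltp_rate} per ms, and a multiplicative LTD
#' term triggered by climbing-fiber (IO) spikes, proportional to the number
#' of 1-ms bins in the trailing \code{window} in which the presynaptic
#' parallel fiber spiked. The delivered PF->PC conductance jump is
#' \code{w * base_weight} nS.
#'
#' @param ltp_rate LTP relaxation rate per ms (default 0.001).
#' @param ltd_rate LTD rate per coincidence (default 0.01).
#' @param w_init Initial and asymptotic weight factor (default 1).
#' @param window Eligibility window in ms; spikes 0..window ms before the
#'   CF spike count (default 50, i.e. 51 one-ms bins).
#' @param w_floor Lower clamp on the factor (default 0).
#' @param ltp_gated If FALSE (default), the LTP term relaxes every weight
#'   toward \code{w_init} every millisecond. If TRUE, LTP is applied only
#'   in milliseconds in which the presynaptic parallel fiber itself spiked
#'   (potentiation by presynaptic activity alone), which slows weight
#'   recovery by roughly the fiber's firing probability per ms and enables
#'   gradual multi-trial adaptation. The OKR protocol defaults to the
#'   gated variant; see the vignette.
#' @return A \code{plasticity_params} list.
#' @export
plasticity_params <- function(ltp_rate = 0.001, ltd_rate = 0.01,
                              w_init = 1.0, window = 50L, w_floor = 0,
                              ltp_gated = FALSE) {
  stopifnot(ltp_rate >= 0, ltd_rate >= 0, w_init > 0, window >= 0,
            w_floor >= 0)
  structure(list(ltp_rate = ltp_rate, ltd_rate = ltd_rate, w_init = w_init,
                 window = as.integer(window), w_floor = w_floor,
                 ltp_gated = isTRUE(ltp_gated)),
            class = "plasticity_params")
}

new_sim_state <- function(net, plasticity = NULL) {
  par <- net$params
  e <- new.env(parent = emptyenv())
  e$u <- par$E_L + 0.0  # force a copy: the engine mutates u in place
  e$g_exc <- numeric(par$n)
  e$g_inh <- numeric(par$n)
  e$refrac <- integer(par$n)
  e$step <- 0L
  max_delay <- max(vapply(net$rules, `[[`, numeric(1), "delay"))
  e$ring_depth <- as.integer(max_delay + 1)
  e$ring <- vector("list", e$ring_depth)
  empty_slot <- lapply(stats::setNames(nm = c("MF", setdiff(cell_type_order(),
                                                            c("MF", "IO")))),
                       function(x) integer())
  for (i in seq_len(e$ring_depth)) e$ring[[i]] <- empty_slot
  if (!is.null(plasticity)) {
    pf <- net$rules[["PF-PC"]]
    if (is.null(pf)) stop("plasticity requires a PF-PC rule", call. = FALSE)
    e$pp <- plasticity
    e$w <- rep(plasticity$w_init, length(pf$tgt))
    e$elig <- integer(pf$n_pre)
    e$hist <- vector("list", plasticity$window + 1L)
    for (i in seq_along(e$hist)) e$hist[[i]] <- integer()
  }
  e
}

#' Run the two-timescale simulation loop
#'
#' Advances the network in 1 ms exchange steps, each containing ten 0.1 ms
#' forward-Euler substeps. Per exchange step: (1) draw Poisson source
#' spikes, (2) deliver matured delayed spike batches through each rule's
#' adjacency, (3) integrate the substeps with threshold detection,
#' (4) enqueue this step's spikes into the delay ring, (5) apply the
#' plasticity update, (6) append to the spike record (flushed every
#' \code{flush_interval} ms when writing to file). Bit-reproducible for a
#' fixed seed.
#'
#' @param net A [build_network()] object.
#' @param stimuli List of [stimulus_spec()]; rates of overlapping stimuli
#'   on the same source add.
#' @param duration Duration in ms (integer number of exchange steps).
#' @param seed Master seed for the counter-based source streams.
#' @param plasticity Optional [plasticity_params()].
#' @param state Optional state from a previous call (trial carry-over).
#' @param record If FALSE, spikes are not accumulated (state evolution
#'   only); per-step spike counts are still available to callbacks.
#' @param out_file Optional path; spike events are appended as
#'   whitespace-separated \code{id time_ms} lines every
#'   \code{flush_interval} ms.
#' @param flush_interval Record flush interval in ms (default 50).
#' @param dt Euler substep in ms (default 0.1; must divide 1 ms).
#' @return A \code{sim_result} list: \code{spikes} (tibble \code{id},
#'   \code{time_ms}, \code{cell_type}), the final \code{state}, and the
#'   plastic weight vector \code{w} (NULL when plasticity is off).
#' @export
simulate_network <- function(net, stimuli, duration, seed = 1,
                             plasticity = NULL, state = NULL,
                             record = TRUE, out_file = NULL,
                             flush_interval = 50, dt = 0.1) {
  n_sub <- round(1 / dt)
  stopifnot(abs(n_sub * dt - 1) < 1e-9)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  par <- net$params
  rev <- net$reversal
  if (is.null(state)) state <- new_sim_state(net, plasticity)
  e <- state
  if (!is.null(plasticity) && is.null(e$pp)) {
    stop("state was initialized without plasticity", call. = FALSE)
  }
  dt_over_Cm <- dt / par$C_m
  n_ref_steps <- as.integer(round(par$t_ref / dt))
  dec_exc <- 1 - dt / par$tau_exc
  dec_inh <- 1 - dt / par$tau_inh
  n_src <- net$n_mf + 1L  # MFs plus IO
  lif_types <- setdiff(cell_type_order(), c("MF", "IO"))
  fs <- net$first_state
  pf <- net$rules[["PF-PC"]]

  chunks_id <- list(); chunks_t <- list(); ci <- 0L
  pending_id <- list(); pending_t <- list(); pi_ <- 0L
  if (!is.null(out_file) && !file.exists(out_file)) {
    writeLines(spike_file_header(net$placement), out_file)
  }
  flush_pending <- function() {
    if (pi_ == 0L || is.null(out_file)) return(invisible())
    ids <- unlist(pending_id[seq_len(pi_)], use.names = FALSE)
    ts <- unlist(pending_t[seq_len(pi_)], use.names = FALSE)
    if (length(ids)) {
      utils::write.table(data.frame(ids, ts), out_file, append = TRUE,
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
    pending_id <<- list(); pending_t <<- list(); pi_ <<- 0L
  }

  steps <- seq_len(as.integer(duration)) - 1L + e$step
  for (s in steps) {
    # (1) source spikes for this ms
    rate <- numeric(n_src)
    for (st in stimuli) {
      r <- stimulus_rate(st, s)
      if (r > 0) {
        loc <- st$targets
        loc[loc == net$io_id] <- net$n_mf + 1L  # IO mapped to last slot
        rate[loc] <- rate[loc] + r
      }
    }
    src_spk <- integer()
    io_fired <- FALSE
    if (any(rate > 0)) {
      u01 <- counter_uniform(seed, 0L, s, n_src)
      fired <- which(u01 < pmin(rate * 1e-3, 1))
      io_fired <- any(fired == n_src)
      src_spk <- fired[fired <= net$n_mf]
    }

    # (2) deliver matured batches
    for (rl in net$rules) {
      slot <- e$ring[[(s - rl$delay) %% e$ring_depth + 1L]][[rl$pre]]
      if (length(slot) == 0L) next
      g <- if (rl$sign == "exc") e$g_exc else e$g_inh
      if (rl$name == "PF-PC" && !is.null(e$pp)) {
        cs_scatter_add_w(rl$p, rl$tgt, e$w, slot, rl$weight, g)
      } else {
        cs_scatter_add(rl$p, rl$tgt, slot, rl$weight, g)
      }
    }

    # (3) ten Euler substeps with detection
    sp <- cs_step_block(e$u, e$g_exc, e$g_inh, e$refrac, dt_over_Cm,
                        par$g_L, par$E_L, par$I_e, par$V_th, par$V_r,
                        n_ref_steps, dec_exc, dec_inh,
                        rev[["E_exc"]], rev[["E_inh"]],
                        as.numeric(s), dt, n_sub)

    # (4) enqueue this step's spikes
    slot_new <- vector("list", length(lif_types) + 1L)
    names(slot_new) <- c("MF", lif_types)
    slot_new[["MF"]] <- src_spk - 1L
    spk_state <- sp$id  # 1-based state indices
    for (tp in lif_types) {
      lo <- fs[[tp]]; hi <- fs[[match(tp, lif_types) + 1L]]
      sel <- spk_state[spk_state > lo & spk_state <= hi]
      slot_new[[tp]] <- as.integer(unique(sel) - lo - 1L)
    }
    e$ring[[s %% e$ring_depth + 1L]] <- slot_new

    # (5) plasticity (once per exchange step, after detection)
    if (!is.null(e$pp)) {
      hpos <- s %% (e$pp$window + 1L) + 1L
      old <- e$hist[[hpos]]
      if (length(old)) e$elig[old] <- e$elig[old] - 1L
      new <- slot_new[["GrC"]] + 1L
      if (length(new)) e$elig[new] <- e$elig[new] + 1L
      e$hist[[hpos]] <- new
      gated <- isTRUE(e$pp$ltp_gated)
      pf_now <- if (gated) {
        v <- integer(pf$n_pre); v[new] <- 1L; v
      } else integer()
      cs_pfpc_update(e$w, pf$p, e$elig, io_fired, e$pp$ltp_rate,
                     e$pp$ltd_rate, e$pp$w_init, e$pp$w_floor,
                     gated, pf_now)
    }

    # (6) record
    if (record) {
      ids <- c(src_spk, spk_state + net$n_mf,
               if (io_fired) net$io_id else integer())
      ts <- c(rep(as.numeric(s), length(src_spk)), sp$time,
              if (io_fired) as.numeric(s) else numeric())
      if (length(ids)) {
        ci <- ci + 1L; chunks_id[[ci]] <- ids; chunks_t[[ci]] <- ts
        if (!is.null(out_file)) {
          pi_ <- pi_ + 1L; pending_id[[pi_]] <- ids; pending_t[[pi_]] <- ts
        }
      }
      if (!is.null(out_file) && (s + 1L) %% flush_interval == 0L) {
        flush_pending()
      }
    }
  }
  flush_pending()
  e$step <- e$step + as.integer(duration)

  spikes <- if (record) {
    spike_record(
      id = unlist(chunks_id, use.names = FALSE) %||% integer(),
      time_ms = unlist(chunks_t, use.names = FALSE) %||% numeric(),
      placement = net$placement
    )
  } else NULL
  structure(list(spikes = spikes, state = e,
                 w = if (!is.null(e$pp)) e$w else NULL, net = net),
            class = "sim_result")
}

#' Construct a spike record
#'
#' @param id Global neuron ids.
#' @param time_ms Spike times in ms (recorded at substep resolution).
#' @param placement Placement used to annotate cell types.
#' @return Tibble of class \code{spike_record} with columns \code{id},
#'   \code{time_ms}, \code{cell_type}.
#' @export
spike_record <- function(id, time_ms, placement) {
  ct <- placement$cell_type[id]
  out <- tibble::tibble(id = as.integer(id), time_ms = as.numeric(time_ms),
                        cell_type = ct)
  structure(out, id_ranges = attr(placement, "id_ranges"),
            n_cells = table(factor(placement$cell_type,
                                   levels = cell_type_order())),
            class = c("spike_record", class(out)))
}

#' Per-population raster
#'
#' @param rec A spike record.
#' @param cell_type Type to extract.
#' @return Tibble of events for that population (lossless partition).
#' @export
population_raster <- function(rec, cell_type) {
  rec[rec$cell_type == cell_type, ]
}
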