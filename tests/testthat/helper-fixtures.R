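# shared miniature models (built once per test run) and a naive reference
# engine used as an independent oracle for the optimized simulation loop

fixture_cache <- new.env(parent = emptyenv())

tiny_fixture <- function(scale = 0.01, seed = 1) {
  key <- sprintf("fx_%g_%d", scale, seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- suppressWarnings(scaffold_fixture(scale, seed = seed))
  }
  fixture_cache[[key]]
}

# hand-built placement: explicit coordinates, canonical id blocks
manual_placement <- function(coords) {
  vol <- volume_spec()
  rows <- list()
  for (tp in cell_type_order()) {
    xy <- coords[[tp]]
    if (is.null(xy)) next
    rows[[tp]] <- tibble::tibble(
      cell_type = tp, local_id = seq_len(nrow(xy)) - 1L,
      x = xy[, 1], y = xy[, 2], z = xy[, 3]
    )
  }
  pl <- dplyr::bind_rows(rows)
  pl$id <- seq_len(nrow(pl))
  pl <- pl[, c("cell_type", "local_id", "id", "x", "y", "z")]
  structure(pl, volume = vol,
            id_ranges = cerebscaffold:::id_ranges_from(pl),
            class = c("placement", class(pl)))
}

# naive clock-driven reference engine built from the pure-R per-operation
# contracts; mirrors the documented exchange-step semantics
reference_engine <- function(net, stimuli, duration, seed) {
  par <- net$params
  state <- network_state_init(par)
  max_delay <- max(vapply(net$rules, `[[`, numeric(1), "delay"))
  depth <- max_delay + 1L
  ring <- vector("list", depth)
  lif_types <- setdiff(cell_type_order(), c("MF", "IO"))
  empty <- lapply(stats::setNames(nm = c("MF", lif_types)), function(.) integer())
  for (i in seq_len(depth)) ring[[i]] <- empty
  n_src <- net$n_mf + 1L
  fs <- net$first_state
  ev_id <- list(); ev_t <- list()
  for (s in 0:(duration - 1)) {
    rate <- numeric(n_src)
    for (st in stimuli) {
      r <- stimulus_rate(st, s)
      if (r > 0) {
        loc <- st$targets
        loc[loc == net$io_id] <- net$n_mf + 1L
        rate[loc] <- rate[loc] + r
      }
    }
    src_spk <- integer()
    if (any(rate > 0)) {
      u01 <- cerebscaffold:::counter_uniform(seed, 0L, s, n_src)
      fired <- which(u01 < pmin(rate * 1e-3, 1))
      src_spk <- fired[fired <= net$n_mf]
    }
    for (rl in net$rules) {
      slot <- ring[[(s - rl$delay) %% depth + 1L]][[rl$pre]]
      if (!length(slot)) next
      arr <- numeric(par$n)
      for (j in slot) {
        if (rl$p[j + 2L] > rl$p[j + 1L]) {
          kk <- (rl$p[j + 1L] + 1L):(rl$p[j + 2L])
          tg <- rl$tgt[kk] + 1L
          arr[tg] <- arr[tg] + rl$weight
        }
      }
      state <- deliver_spikes(state, arr, rl$sign)
    }
    spikes_ms <- integer()
    for (sub in 1:10) {
      state <- lif_substep(state, par, dt = 0.1, reversal = net$reversal)
      dr <- detect_and_reset(state, par, dt = 0.1)
      state <- dr$state
      if (length(dr$spikes)) {
        ev_id[[length(ev_id) + 1L]] <- dr$spikes + net$n_mf
        ev_t[[length(ev_t) + 1L]] <- rep(s + sub * 0.1, length(dr$spikes))
        spikes_ms <- c(spikes_ms, dr$spikes)
      }
    }
    slot_new <- empty
    slot_new[["MF"]] <- src_spk - 1L
    for (tp in lif_types) {
      lo <- fs[[tp]]; hi <- fs[[match(tp, lif_types) + 1L]]
      sel <- spikes_ms[spikes_ms > lo & spikes_ms <= hi]
      slot_new[[tp]] <- as.integer(unique(sel) - lo - 1L)
    }
    ring[[s %% depth + 1L]] <- slot_new
    if (length(src_spk)) {
      ev_id[[length(ev_id) + 1L]] <- src_spk
      ev_t[[length(ev_t) + 1L]] <- rep(as.numeric(s), length(src_spk))
    }
  }
  tibble::tibble(id = unlist(ev_id) %||% integer(),
                 time_ms = unlist(ev_t) %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
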