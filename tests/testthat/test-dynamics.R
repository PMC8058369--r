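# single-type helper: expanded parameter vectors for n identical neurons
single_type_params <- function(type, n = 1L) {
  tab <- lif_params()
  row <- tab[tab$cell_type == type, ]
  par <- lapply(row[-1], function(v) rep(v, n))
  par$cell_type <- rep(type, n)
  par$n <- n
  par
}

test_that("the Euler membrane update reproduces hand-computed steps", {
  # equilibrium: a granule cell at rest with no input stays at rest
  par <- single_type_params("GrC")
  st <- network_state_init(par)
  expect_equal(st$u, -74)
  st2 <- lif_substep(st, par)
  expect_equal(st2$u, -74)

  # one step of a Purkinje cell at -62 mV with only its endogenous current:
  # du = 0.1 * 600 / 620
  par <- single_type_params("PC")
  st <- network_state_init(par)
  st2 <- lif_substep(st, par)
  expect_equal(st2$u, -62 + 0.1 * 600 / 620, tolerance = 1e-12)
  expect_equal(st2$u, -61.9032, tolerance = 1e-4)
})

test_that("Euler trajectories converge at first order to the closed form", {
  # frozen-conductance interval: u(t) = u_ss + (u0 - u_ss) exp(-t gL/Cm)
  par <- single_type_params("GoC")
  u_ss <- par$E_L + par$I_e / par$g_L
  closed <- function(t) u_ss + (par$E_L - u_ss) * exp(-t * par$g_L / par$C_m)
  err <- vapply(c(0.1, 0.05), function(dt) {
    st <- network_state_init(par)
    for (i in seq_len(round(50 / dt))) st <- lif_substep(st, par, dt = dt)
    abs(st$u - closed(50))
  }, numeric(1))
  expect_lt(err[1], 0.05)
  expect_lt(err[2], err[1] * 0.6)  # roughly halves when dt halves
})

test_that("threshold, reset and refractoriness implement the spike contract", {
  par <- single_type_params("PC")
  st <- network_state_init(par)
  st$u <- par$V_th - 1e-6
  expect_length(detect_and_reset(st, par)$spikes, 0L)
  st$u <- par$V_th  # boundary: >= fires
  dr <- detect_and_reset(st, par)
  expect_equal(dr$spikes, 1L)
  expect_equal(dr$state$u, par$V_r)
  expect_equal(dr$state$refrac, par$t_ref)

  # deterministic PC driven by I_e alone: ISI matches the closed form
  # tau ln((u_ss - V_r)/(u_ss - V_th)) + t_ref ~ 27.6 ms
  st <- network_state_init(par)
  spikes <- numeric()
  for (i in 1:20000) {
    st <- lif_substep(st, par, dt = 0.1)
    dr <- detect_and_reset(st, par, dt = 0.1)
    st <- dr$state
    if (length(dr$spikes)) spikes <- c(spikes, st$t)
  }
  isi <- mean(diff(spikes))
  u_ss <- -62 + 600 / 7
  isi_closed <- 620 / 7 * log((u_ss + 72) / (u_ss + 47)) + 0.8
  expect_equal(isi_closed, 27.6, tolerance = 0.01)
  expect_equal(isi, isi_closed, tolerance = 0.01)
  # refractory contract: no two spikes closer than t_ref
  expect_true(all(diff(spikes) > par$t_ref - 1e-9))
})

test_that("synaptic delivery jumps conductances additively and decays geometrically", {
  par <- single_type_params("GrC", n = 3L)
  st <- network_state_init(par)
  st0 <- deliver_spikes(st, c(0, 0, 0), "exc")
  expect_equal(st0$g_exc, c(0, 0, 0))

  # one MF spike jumps g_exc by the published 9.0 nS
  st1 <- deliver_spikes(st, c(9, 0, 0), "exc")
  expect_equal(st1$g_exc, c(9, 0, 0))

  # two simultaneous deliveries equal the sum of two sequential ones
  stA <- deliver_spikes(st, c(18, 0, 0), "inh")
  stB <- deliver_spikes(deliver_spikes(st, c(9, 0, 0), "inh"), c(9, 0, 0), "inh")
  expect_equal(stA$g_inh, stB$g_inh)
  expect_error(deliver_spikes(st, c(-1, 0, 0), "exc"), "non-negative")

  # decay ratio per substep is exactly (1 - dt/tau)
  st1$g_inh <- c(5, 5, 5)
  st2 <- lif_substep(st1, par, dt = 0.1)
  expect_equal(st2$g_exc, st1$g_exc * (1 - 0.1 / 0.5))
  expect_equal(st2$g_inh, st1$g_inh * (1 - 0.1 / 10))
  expect_true(all(st2$g_exc >= 0) && all(st2$g_inh >= 0))
})

test_that("Poisson sources are counter-based and match binomial statistics", {
  spec <- stimulus_spec(1:50, rate = 0)
  expect_length(poisson_sources(spec, 5, seed = 1), 0L)

  spec <- stimulus_spec(1:1000, rate = 150, t_on = 0, t_off = 50)
  # regenerating a step gives identical output irrespective of order
  a <- poisson_sources(spec, 7, seed = 3)
  b <- poisson_sources(spec, 9, seed = 3)
  expect_identical(poisson_sources(spec, 7, seed = 3), a)
  expect_identical(poisson_sources(spec, 9, seed = 3), b)
  expect_false(identical(a, poisson_sources(spec, 7, seed = 4)))

  # 150 Hz x 50 ms x 1000 sources ~ Binomial(50000, 0.15)
  totals <- vapply(1:100, function(sd) {
    sum(vapply(0:49, function(s) length(poisson_sources(spec, s, seed = sd)),
               numeric(1)))
  }, numeric(1))
  se <- sqrt(50000 * 0.15 * 0.85)
  expect_lt(abs(mean(totals) - 7500), 3 * se / sqrt(100))

  # sinusoid 0-30 Hz over one 2 s cycle: expected 30 spikes per source
  sin_spec <- stimulus_spec(1:500, r_max = 30, period = 2000)
  rates <- vapply(0:1999, function(s) stimulus_rate(sin_spec, s), numeric(1))
  expect_equal(sum(rates) / 1000, 30, tolerance = 1e-9)  # analytic integral
  counts <- vapply(1:20, function(sd) {
    sum(vapply(0:1999, function(s) length(poisson_sources(sin_spec, s, seed = sd)),
               numeric(1))) / 500
  }, numeric(1))
  se1 <- sqrt(30 / 500)  # per-seed SE of the per-source mean
  expect_lt(abs(mean(counts) - 30), 3 * se1 / sqrt(20))

  expect_error(stimulus_spec(1:5, rate = -2), ">= 0")
})

test_that("voltage stays bounded under sustained bombardment", {
  par <- single_type_params("GrC", n = 10L)
  st <- network_state_init(par)
  set.seed(99)
  umin <- Inf; umax <- -Inf
  for (i in 1:500) {
    if (i %% 10 == 0) {  # deliveries on the 1 ms exchange grid
      st <- deliver_spikes(st, runif(10, 0, 3), "exc")
      st <- deliver_spikes(st, runif(10, 0, 3), "inh")
    }
    st <- lif_substep(st, par, dt = 0.1)
    dr <- detect_and_reset(st, par, dt = 0.1)
    st <- dr$state
    umin <- min(umin, st$u); umax <- max(umax, st$u)
  }
  expect_lte(umax, -42)        # never observed above threshold
  expect_gte(umin, -80 - 10)   # bounded below near E_inh (Euler overshoot)
})
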