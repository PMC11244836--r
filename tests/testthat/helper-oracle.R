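# Independent reference implementations used as oracles. These are coded
# from the textbook equations, deliberately not sharing code with the package.

# Textbook squid-axon Hodgkin-Huxley right-hand side (standard rate functions,
# written directly; voltages in mV, time in ms).
oracle_hh_rhs <- function(v, m, h, n, p, i_ext = 0, g_extra_na = 0) {
  alpha_m <- 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  beta_m <- 4 * exp(-(v + 65) / 18)
  alpha_h <- 0.07 * exp(-(v + 65) / 20)
  beta_h <- 1 / (1 + exp(-(v + 35) / 10))
  alpha_n <- 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  beta_n <- 0.125 * exp(-(v + 65) / 80)
  i_na <- (p$gNa * m^3 * h + g_extra_na) * (v - p$vNa)
  i_k <- p$gK * n^4 * (v - p$vK)
  i_l <- p$gL * (v - p$vL)
  c(dv = (i_ext - i_na - i_k - i_l) / p$c,
    dm = alpha_m * (1 - m) - beta_m * m,
    dh = alpha_h * (1 - h) - beta_h * h,
    dn = alpha_n * (1 - n) - beta_n * n)
}

# Fine-step forward-Euler integration of g + tau * dg/dt = drive(t),
# returning times and g on the fine grid.
oracle_gtms <- function(drive_fun, tau, t_end, dt) {
  nt <- round(t_end / dt)
  g <- numeric(nt + 1)
  for (i in seq_len(nt)) {
    t <- (i - 1) * dt
    g[i + 1] <- g[i] + dt * (drive_fun(t) - g[i]) / tau
  }
  list(time = seq(0, by = dt, length.out = nt + 1), g = g)
}

# Forward-Euler reference integration of a single driven HH neuron at a very
# small step; used for spike-count convergence checks.
oracle_hh_integrate <- function(p, i_ext, t_end, dt) {
  v <- -65
  am <- 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10)); bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20); bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10)); bn <- 0.125 * exp(-(v + 65) / 80)
  s <- c(v, am / (am + bm), ah / (ah + bh), an / (an + bn))
  nt <- round(t_end / dt)
  spikes <- numeric(0); last <- -Inf
  for (i in seq_len(nt)) {
    d <- oracle_hh_rhs(s[1], s[2], s[3], s[4], p, i_ext = i_ext)
    vold <- s[1]
    s <- s + dt * d
    t <- i * dt
    if (vold < 0 && s[1] >= 0 && t - last >= 2) {
      spikes <- c(spikes, t); last <- t
    }
  }
  spikes
}

# random neuron states away from the rate-function singularities
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- runif(1, -80, 20)
    while (min(abs(v + 40), abs(v + 55)) < 0.5) v <- runif(1, -80, 20)
    list(v = v, m = runif(1), h = runif(1), n = runif(1),
         gTMS = runif(1, 0, 2))
  })
}

single_node_net <- function(mem, id = "n1", tms_tau = 30) {
  nodes <- micturinet:::.node_row(id, "hh", "probe", mem, tms_target = TRUE)
  nodes$tms_tau <- tms_tau
  build_network(list(nodes = nodes,
                     edges = micturinet:::.edge_row(id, id, 0)[0, ],
                     cable = NULL))
}
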