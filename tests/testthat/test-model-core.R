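test_that("calcium activation has the tanh sigmoid form and limits", {
  p <- ml_params()
  expect_equal(m_inf(p$v1, p), 0.5)
  expect_equal(m_inf(1e6, p), 1.0)
  expect_equal(m_inf(-1e6, p), 0.0)
  # frozen reference: 0.5 * (1 + tanh(1)), tanh(1) evaluated independently
  expect_equal(m_inf(p$v1 + p$v2, p), 0.8807970779778823, tolerance = 1e-12)
  # strictly increasing
  vs <- seq(-120, 120, by = 1)
  expect_true(all(diff(m_inf(vs, p)) > 0))
  expect_error(m_inf(NaN, p), "non-finite")
})

test_that("recovery kinetics: steady state, time constant, limits", {
  p <- ml_params()
  at_v3 <- w_inf_tau(p$v3, p)
  expect_equal(at_v3$w_inf, 0.5)
  expect_equal(at_v3$tau_w, 1.0)
  lo <- w_inf_tau(-1e3, p)
  expect_equal(lo$w_inf, 0.0, tolerance = 1e-12)
  expect_gt(lo$tau_w, 0)
  expect_lt(lo$tau_w, 1e-6)
  # frozen references: 0.5 * (1 + tanh(2)) and 1 / cosh(1)
  at2 <- w_inf_tau(p$v3 + 2 * p$v4, p)
  expect_equal(at2$w_inf, 0.9820137900379085, tolerance = 1e-12)
  expect_equal(at2$tau_w, 0.6480542736638855, tolerance = 1e-12)
  # tau_w maximal at v3
  vs <- seq(-100, 100, by = 0.5)
  taus <- w_inf_tau(vs, p)$tau_w
  expect_equal(vs[which.max(taus)], p$v3)
  expect_error(w_inf_tau(Inf, p), "non-finite")
})

test_that("gap-junction current is ohmic and antisymmetric", {
  expect_equal(gap_junction_current(-60, -60, 0.5), 0)
  expect_equal(gap_junction_current(-60, -50, 0.1), 1.0)
  set.seed(11)
  for (i in 1:20) {
    va <- runif(1, -90, 40); vb <- runif(1, -90, 40); g <- runif(1, 0, 5)
    expect_identical(gap_junction_current(va, vb, g),
                     -gap_junction_current(vb, va, g))
  }
  expect_error(gap_junction_current(-60, -50, -1), "non-negative")
})

test_that("passive compartment balance: equilibrium, leak decay, stimulus gating", {
  topo <- build_ladder_topology(3, "middle", 0.4)
  p <- passive_params()
  stim <- stimulus_protocol(1, 2)
  n <- 3 * 10 + 3
  rest <- c(rep(p$e_leak, 30), rep(0.1, 3))
  # uniform potential at e_leak, no stimulus -> zero derivative everywhere
  for (cab in 1:3) for (i in 1:9)
    expect_equal(passive_rhs(rest, cab, i, topo,
                             p, stimulus_protocol(1, 0), 10), 0)
  # pure leak decay on a displaced compartment of an uncoupled network
  topo0 <- build_ladder_topology(3, "none", 0)
  st <- rest
  st[v_index(2, 4, topo0)] <- p$e_leak + 10
  # neighbors still at e_leak contribute axial terms; isolate leak by
  # displacing the whole cable uniformly
  st2 <- rest
  st2[v_index(2, 1:10, topo0)] <- p$e_leak + 10
  expect_equal(passive_rhs(st2, 2, 4, topo0, p, stimulus_protocol(1, 0), 10),
               -10 * p$g_leak / p$c_m)
  # stimulus applies only at compartment 1 of stimulated cables in-window
  expect_equal(passive_rhs(rest, 1, 1, topo, p, stim, 10),
               stim$amplitude / p$c_m)
  expect_equal(passive_rhs(rest, 2, 1, topo, p, stim, 10), 0)
  expect_equal(passive_rhs(rest, 1, 1, topo, p, stim, 250), 0)
  expect_error(passive_rhs(rest, 1, 10, topo, p, stim, 0), "out of range")
})

test_that("active compartment: fixed point, nullcline, limit cycle", {
  p <- ml_params()
  rest <- ml_rest(p)
  expect_equal(active_rhs(rest$v, rest$w, 0, p), c(0, 0), tolerance = 1e-9)
  # independent confirmation of the fixed point: long relaxation with deSolve
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(active_rhs(y[1], y[2], parms, p))
  relax <- deSolve::ode(c(v = -50, w = 0.2), seq(0, 2000, by = 1), f, 0,
                        method = "lsoda")
  expect_equal(unname(relax[nrow(relax), "v"]), rest$v, tolerance = 1e-5)
  # dw/dt vanishes on the recovery nullcline
  expect_equal(active_rhs(-20, w_inf_tau(-20, p)$w_inf, 0, p)[2], 0)
  # constant suprathreshold axial current -> repetitive large spikes
  drive <- 120
  out <- rk4_integrate(function(t, y) active_rhs(y[1], y[2], drive, p),
                       c(rest$v, rest$w), c(0, 500), 0.01)
  v <- out$Y[, 1]
  expect_gt(max(v) - min(v), 40)
  spikes <- detect_spikes(v, out$times, 0, 2)
  expect_gt(length(spikes), 3)
})

test_that("assembled state length and packing follow the documented order", {
  sys <- tiny_system(10, "none", 0)
  expect_identical(sys$n_v + sys$n_cables, 110L)
  topo <- sys$topo
  expect_identical(v_index(1, 1, topo), 1L)
  expect_identical(v_index(2, 1, topo), 11L)
  expect_identical(v_index(10, 10, topo), 100L)
  expect_identical(w_index(3, topo), 103L)
  expect_error(v_index(11, 1, topo), "out of range")
})

test_that("assembled rhs agrees with the scalar reference passive_rhs", {
  sys <- tiny_system(3, "middle", 0.7, amplitude = 4, stim_cables = c(1, 3))
  set.seed(42)
  st <- c(runif(30, -80, 0), runif(3, 0, 1))
  d <- sys$rhs(50, st)
  for (cab in 1:3) for (i in 1:9)
    expect_equal(d[v_index(cab, i, sys$topo)],
                 passive_rhs(st, cab, i, sys$topo, sys$passive, sys$stim, 50),
                 tolerance = 1e-12)
  # active compartments follow active_rhs with the axial coupling current
  for (cab in 1:3) {
    va <- st[v_index(cab, 10, sys$topo)]
    v9 <- st[v_index(cab, 9, sys$topo)]
    w <- st[30 + cab]
    ref <- active_rhs(va, w, sys$passive$g_axial * (v9 - va), sys$active)
    expect_equal(d[v_index(cab, 10, sys$topo)], ref[1], tolerance = 1e-12)
    expect_equal(d[w_index(cab, sys$topo)], ref[2], tolerance = 1e-12)
  }
})

test_that("coupling currents cancel pairwise: total charge balance", {
  # with zero leak and the active compartments made passive-and-leakless,
  # the only residual current is the external stimulus
  pas <- passive_params(g_leak = 0, g_axial = 3)
  act <- ml_params(c_m = pas$c_m, g_ca = 0, g_k = 0, g_l = 1e-12)
  sys <- tiny_system(4, "distal", 1.3, amplitude = 7, stim_cables = c(2, 4),
                     passive = pas, active = act)
  set.seed(7)
  for (rep in 1:5) {
    st <- c(runif(40, -80, 20), runif(4, 0, 1))
    d <- sys$rhs(10, st)  # in-window
    total <- sum(d[1:40] * sys$cm)
    expect_equal(total, 2 * 7, tolerance = 1e-9)
  }
})

test_that("permuting cable labels of a symmetric topology permutes trajectories", {
  # the 4-cable chain with stimulus on cables 2:3 is symmetric under
  # reversal k -> 5 - k, so cable c and cable 5 - c must trace identically
  sys <- tiny_system(4, "proximal", 0.8, amplitude = 120, stim_cables = 2:3)
  traj <- integrate_network(sys, c(-20, 150), 0.02)
  for (comp in c(1, 5, 10)) {
    expect_equal(compartment_trace(traj, 1, comp),
                 compartment_trace(traj, 4, comp), tolerance = 1e-10)
    expect_equal(compartment_trace(traj, 2, comp),
                 compartment_trace(traj, 3, comp), tolerance = 1e-10)
  }
})

test_that("topology validation rejects malformed wiring", {
  expect_error(gap_junction(1, 2, 1, 3, 0.5))           # same cable
  expect_error(network_topology(2, cable_spec(),
                                list(gap_junction(1, 10, 2, 10, 0.5))),
               "passive")                                # active compartment
  expect_error(network_topology(2, cable_spec(),
                                list(gap_junction(1, 2, 3, 2, 0.5))),
               "outside")                                # missing cable
  expect_error(network_topology(3, cable_spec(),
                                list(gap_junction(1, 2, 2, 2, 0.5),
                                     gap_junction(2, 2, 1, 2, 0.5))),
               "duplicate")
})

test_that("all-passive steady state equals the sparse linear-system solution", {
  sys <- all_passive_system(4, "middle", 0.5, amplitude = 5,
                            stim_cables = 1:2)
  # keep the stimulus on for the whole run so the network relaxes to the
  # driven steady state
  stim_on <- stimulus_protocol(1:2, 5, onset = 0, duration = 1e6)
  sys_on <- assemble_network(sys$topo, sys$passive, sys$active, stim_on)
  traj <- integrate_network(sys_on, c(0, 1500), 0.05, record_every = 100L)
  v_relaxed <- traj$V[nrow(traj$V), ]
  v_lin <- passive_steady_state(sys_on)
  expect_equal(v_relaxed, v_lin, tolerance = 1e-6)
  # third route: independent dense solve of the same balance equations
  A <- as.matrix(sys_on$M)
  diag(A)[sys_on$active_idx] <- diag(A)[sys_on$active_idx] -
    sys_on$passive$g_leak
  b <- sys_on$b0 + sys_on$stim_vec
  b[sys_on$active_idx] <- b[sys_on$active_idx] +
    sys_on$passive$g_leak * sys_on$passive$e_leak
  v_dense <- solve(A, -b)
  expect_equal(v_lin, v_dense, tolerance = 1e-9)
})
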