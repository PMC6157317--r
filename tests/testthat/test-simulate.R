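test_that("RK4 reproduces the analytic exponential and converges at order 4", {
  out <- rk4_integrate(function(t, y) -y, 1, c(0, 1), 0.01)
  expect_equal(out$Y[nrow(out$Y), 1], exp(-1), tolerance = 1e-6)
  # zero dynamics returns the initial state everywhere
  z <- rk4_integrate(function(t, y) 0 * y, c(3, -2), c(0, 5), 0.1)
  expect_true(all(z$Y[, 1] == 3), all(z$Y[, 2] == -2))
  # self-convergence order on the exponential: error ratio ~ 2^4
  err <- sapply(c(0.1, 0.05), function(dt) {
    o <- rk4_integrate(function(t, y) -y, 1, c(0, 1), dt)
    abs(o$Y[nrow(o$Y), 1] - exp(-1))
  })
  order <- log2(err[1] / err[2])
  expect_equal(order, 4, tolerance = 0.1)
})

test_that("compiled and pure-R network backends agree to roundoff", {
  sys <- tiny_system(3, "middle", 0.8, amplitude = 100, stim_cables = 1:2)
  a <- integrate_network(sys, c(-10, 120), 0.05, backend = "cpp")
  b <- integrate_network(sys, c(-10, 120), 0.05, backend = "R")
  expect_equal(a$times, b$times)
  expect_equal(a$V, b$V, tolerance = 1e-10)
  expect_equal(a$W, b$W, tolerance = 1e-10)
})

test_that("network integration agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  sys <- tiny_system(2, "proximal", 0.6, amplitude = 110, stim_cables = 1)
  traj <- integrate_network(sys, c(0, 100), 0.005)
  f <- function(t, y, parms) list(sys$rhs(t, y))
  ref <- deSolve::ode(sys$initial_state(), seq(0, 100, by = 1), f, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9)
  pick <- match(seq(0, 100, by = 1), traj$times)
  expect_equal(unname(traj$V[pick, 1]), unname(ref[, 2]), tolerance = 1e-3)
})

test_that("divergence is reported with the first bad time", {
  # an unstable linear system blows up; integrator must name a time
  expect_error(rk4_integrate(function(t, y) 1e3 * y, 1, c(0, 10), 0.1),
               "diverged.*t = ")
})

test_that("spike detection counts distinct threshold crossings", {
  t <- seq(0, 100, by = 0.1)
  expect_identical(detect_spikes(rep(-60, length(t)), t), numeric(0))
  # two upward crossings of 0 mV, 30 ms apart
  v <- rep(-50, length(t))
  v[t >= 20 & t < 25] <- 10
  v[t >= 50 & t < 55] <- 10
  s <- detect_spikes(v, t, threshold = 0, refractory = 2)
  expect_length(s, 2)
  expect_equal(diff(s), 30)
  # refractory period suppresses rapid re-crossings
  v2 <- rep(-50, length(t))
  v2[t >= 20 & t < 20.2] <- 10
  v2[t >= 20.5 & t < 20.7] <- 10
  expect_length(detect_spikes(v2, t, 0, 2), 1)
  expect_length(detect_spikes(v2, t, 0, 0.2), 2)
  expect_error(detect_spikes(numeric(0), numeric(0)), "empty")
})

test_that("spike count matches an independent peak-finding oracle", {
  p <- ml_params()
  rest <- ml_rest(p)
  out <- rk4_integrate(function(t, y) active_rhs(y[1], y[2], 120, p),
                       c(rest$v, rest$w), c(0, 500), 0.01)
  v <- out$Y[, 1]
  spikes <- detect_spikes(v, out$times, 0, 2)
  # oracle: count strict local maxima above 0 mV
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  peaks <- peaks[v[peaks] > 0]
  expect_identical(length(spikes), length(peaks))
})

test_that("summary counts spiking cables and flags back-propagation", {
  params <- preset_params()
  sys <- tiny_system(3, "none", 0, amplitude = params$strong,
                     stim_cables = c(1, 3),
                     passive = passive_params(g_leak = params$g_leak,
                                              g_axial = params$g_axial))
  traj <- integrate_network(sys, c(-50, 250), 0.01)
  sm <- summarize_trajectory(traj)
  expect_identical(sm$spiking_cable_count, 2L)
  expect_identical(sm$spiking_cables, c(1L, 3L))
  # every spiking cable back-propagates into its passive compartments
  expect_true(all(sm$backprop[sm$spiking_cables]))
  expect_false(any(sm$backprop[2]))
  expect_equal(dim(sm$peak_v), c(3, 10))
  # zero-amplitude stimulus leaves the network silent
  sys0 <- tiny_system(3, "none", 0, amplitude = 0, stim_cables = c(1, 3))
  sm0 <- summarize_trajectory(integrate_network(sys0, c(-50, 250), 0.02))
  expect_identical(sm0$spiking_cable_count, 0L)
})

test_that("resting network stays at rest and w stays within [0, 1]", {
  sys <- tiny_system(4, "proximal", 1, amplitude = 0, stim_cables = 1)
  traj <- integrate_network(sys, c(0, 500), 0.02)
  drift <- abs(sweep(traj$V, 2, traj$V[1, ]))
  expect_lt(max(drift), 0.5)
  expect_true(all(traj$W >= 0 & traj$W <= 1))
})

test_that("gating variable stays in [0, 1] on driven trajectories", {
  sys <- tiny_system(3, "distal", 2, amplitude = 200, stim_cables = 1:3)
  traj <- integrate_network(sys, c(-50, 250), 0.01)
  expect_true(all(traj$W >= 0 & traj$W <= 1))
})

test_that("trajectories are bit-identical across repeated runs", {
  sys <- tiny_system(3, "proximal", 1, amplitude = 150, stim_cables = 2)
  a <- integrate_network(sys, c(-20, 150), 0.02)
  b <- integrate_network(sys, c(-20, 150), 0.02)
  expect_identical(a$V, b$V)
  expect_identical(a$W, b$W)
})
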