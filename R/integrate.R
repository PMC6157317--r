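#' Fixed-step 4th-order Runge-Kutta for a generic system
#'
#' A plain fixed-step RK4 over a uniform grid, used for small reference
#' systems and as the pure-R backend of the network integrator. Fixed-step
#' integration is chosen over adaptive schemes so that trajectories are
#' bit-identical across runs and platforms.
#'
#' @param f Function `f(t, y)` returning dy/dt (numeric vector).
#' @param y0 Initial state.
#' @param t_span Numeric `c(t0, t1)` (ms).
#' @param dt Step size (ms), > 0; the span must be an integer number of steps.
#' @param record_every Record every k-th step (default 1).
#' @return List with `times` and a matrix `Y` (one row per recorded time).
#' @export
#' @examples
#' out <- rk4_integrate(function(t, y) -y, 1, c(0, 1), 0.01)
#' out$Y[nrow(out$Y), 1] - exp(-1)  # ~1e-10
rk4_integrate <- function(f, y0, t_span, dt, record_every = 1L) {
  stopifnot(dt > 0, t_span[2] > t_span[1])
  n_steps <- round((t_span[2] - t_span[1]) / dt)
  y <- as.numeric(y0)
  n_rec <- n_steps %/% record_every + 1L
  Y <- matrix(NA_real_, n_rec, length(y))
  times <- numeric(n_rec)
  Y[1, ] <- y; times[1] <- t_span[1]
  r <- 1L
  for (s in seq_len(n_steps)) {
    t <- t_span[1] + (s - 1) * dt
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("integration diverged (non-finite state) at t = ",
           t_span[1] + s * dt, " ms")
    if (s %% record_every == 0L) {
      r <- r + 1L
      Y[r, ] <- y; times[r] <- t_span[1] + s * dt
    }
  }
  list(times = times, Y = Y)
}

#' Integrate an assembled network
#'
#' Runs the fixed-step RK4 integrator over the assembled system and returns
#' a `trajectory` object holding the membrane potentials of every
#' compartment and the recovery variable of every active compartment on a
#' uniform time grid.
#'
#' The default backend is the compiled core; `backend = "R"` evaluates the
#' same scheme through the R closure of [assemble_network()] and exists for
#' cross-checking (the two agree to floating-point roundoff on short runs).
#'
#' @param sys A `network_system` from [assemble_network()].
#' @param t_span Numeric `c(t0, t1)` (ms). Negative start times give the
#'   network an unstimulated settling period when the stimulus onset is 0.
#' @param dt Step (ms), default 0.01.
#' @param record_every Record every k-th step.
#' @param init Initial flat state; defaults to `sys$initial_state()`.
#' @param backend `"cpp"` (default) or `"R"`.
#' @return An object of class `trajectory` with fields `times` (ms), `V`
#'   (matrix, one column per compartment in [v_index()] order), `W` (matrix,
#'   one column per cable), `dt`, and the generating `topo` and `stim`.
#' @export
integrate_network <- function(sys, t_span = c(-50, 250), dt = 0.01,
                              record_every = 1L, init = NULL,
                              backend = c("cpp", "R")) {
  backend <- match.arg(backend)
  stopifnot(inherits(sys, "network_system"), dt > 0, t_span[2] > t_span[1])
  if (is.null(init)) init <- sys$initial_state()
  stopifnot(length(init) == sys$n_v + sys$n_cables)
  if (backend == "cpp") {
    out <- .rk4_network_cpp(
      sys$A_i, sys$A_j, sys$A_x, sys$b0, sys$stim_vec,
      sys$stim$onset, sys$stim$onset + sys$stim$duration,
      sys$active_idx - 1L, unclass(sys$active),
      sys$cm, init[seq_len(sys$n_v)], init[sys$n_v + seq_len(sys$n_cables)],
      t_span[1], t_span[2], dt, as.integer(record_every))
    times <- out$times; V <- out$V; W <- out$W
  } else {
    out <- rk4_integrate(sys$rhs, init, t_span, dt, record_every)
    times <- out$times
    V <- out$Y[, seq_len(sys$n_v), drop = FALSE]
    W <- out$Y[, sys$n_v + seq_len(sys$n_cables), drop = FALSE]
  }
  structure(list(times = times, V = V, W = W, dt = dt,
                 record_every = as.integer(record_every),
                 topo = sys$topo, stim = sys$stim),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d cables, t = [%g, %g] ms, dt = %g ms, %d samples\n",
              x$topo$n_cables, min(x$times), max(x$times), x$dt,
              length(x$times)))
  invisible(x)
}

#' Extract the voltage trace of one compartment
#'
#' @param traj A `trajectory`.
#' @param cable Cable index.
#' @param comp Compartment index (`n_passive + 1` for the active one).
#' @return Numeric vector of potentials (mV), one per recorded time.
#' @export
compartment_trace <- function(traj, cable, comp) {
  traj$V[, v_index(cable, comp, traj$topo)]
}
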