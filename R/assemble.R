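#' Flat state-vector index of one compartment
#'
#' The network state is packed cable-major, compartment-minor: the membrane
#' potentials of cable 1 (compartments 1..n_passive+1, where n_passive+1 is
#' the active compartment) come first, then cable 2, and so on; the
#' n_cables Morris-Lecar recovery variables w follow after all potentials.
#'
#' @param cable Cable index (1-based).
#' @param comp Compartment index (1..n_passive+1).
#' @param topo A [network_topology()].
#' @return Integer position of the potential in the flat state vector.
#' @export
v_index <- function(cable, comp, topo) {
  np1 <- topo$spec$n_passive + 1L
  if (any(cable < 1 | cable > topo$n_cables) || any(comp < 1 | comp > np1))
    stop("compartment index out of range")
  as.integer((cable - 1L) * np1 + comp)
}

#' Index of a cable's recovery variable in the flat state vector
#' @inheritParams v_index
#' @return Integer position of w in the flat state vector.
#' @export
w_index <- function(cable, topo) {
  as.integer(topo$n_cables * (topo$spec$n_passive + 1L) + cable)
}

#' Right-hand side of one passive compartment (reference form)
#'
#' The compartment balance
#' `c_m dV/dt = -g_leak (V - e_leak) + g_axial (V_{i-1} - V_i) +
#' g_axial (V_{i+1} - V_i) + I_ext(t) 1[i = 1, cable stimulated] +
#' sum over junctions of g_gj (V_partner - V_i)`.
#' Compartment 1 is a sealed end (no distal neighbor); the neighbor at
#' `n_passive + 1` is the active compartment.
#'
#' This scalar form is the reference definition; the integrator uses an
#' equivalent sparse linear operator built by [assemble_network()].
#'
#' @param state Flat state vector (see [v_index()]).
#' @param cable,i Cable and passive compartment index of the target.
#' @param topo A [network_topology()].
#' @param p A [passive_params()].
#' @param stim A [stimulus_protocol()].
#' @param t Time (ms).
#' @return dV/dt (mV/ms).
#' @export
passive_rhs <- function(state, cable, i, topo, p, stim, t) {
  np <- topo$spec$n_passive
  if (i < 1 || i > np) stop("passive compartment index out of range")
  v <- state[v_index(cable, i, topo)]
  cur <- -p$g_leak * (v - p$e_leak)
  if (i > 1)
    cur <- cur + p$g_axial * (state[v_index(cable, i - 1L, topo)] - v)
  cur <- cur + p$g_axial * (state[v_index(cable, i + 1L, topo)] - v)
  if (i == stim$target_compartment && cable %in% stim$stimulated_cables &&
      t >= stim$onset && t < stim$onset + stim$duration)
    cur <- cur + stim$amplitude
  gj <- topo$gj
  if (nrow(gj) > 0) {
    ha <- gj$cable_a == cable & gj$comp_a == i
    hb <- gj$cable_b == cable & gj$comp_b == i
    if (any(ha))
      cur <- cur + sum(gj$g_gj[ha] *
        (state[v_index(gj$cable_b[ha], gj$comp_b[ha], topo)] - v))
    if (any(hb))
      cur <- cur + sum(gj$g_gj[hb] *
        (state[v_index(gj$cable_a[hb], gj$comp_a[hb], topo)] - v))
  }
  cur / p$c_m
}

#' Assemble the full network dynamical system
#'
#' Collects every compartment balance into one flat first-order system
#' `d(state)/dt = f(t, state)` using the packing documented in [v_index()].
#' The linear part (leak, axial links, gap junctions) is precomputed as a
#' sparse triplet operator; the Morris-Lecar currents of the active
#' compartments are the only nonlinearity. Axial current into each active
#' compartment is `g_axial (V_{n_passive} - V_active)`; every coupling link
#' contributes equal-magnitude, opposite-sign currents to its two endpoints.
#'
#' @param topo A [network_topology()].
#' @param passive A [passive_params()].
#' @param active An [ml_params()].
#' @param stim A [stimulus_protocol()].
#' @return An object of class `network_system` with the precomputed
#'   operator, an R closure `rhs(t, state)`, and an `initial_state()`
#'   generator (all V at `e_leak`, all w at `w_inf(e_leak)`).
#' @export
assemble_network <- function(topo, passive, active, stim) {
  stopifnot(inherits(topo, "network_topology"),
            inherits(passive, "passive_params"),
            inherits(active, "ml_params"),
            inherits(stim, "stimulus_protocol"))
  if (length(stim$stimulated_cables) > 0 &&
      max(stim$stimulated_cables) > topo$n_cables)
    stop("stimulus targets a cable outside the network")
  np <- topo$spec$n_passive
  nc <- topo$n_cables
  nv <- nc * (np + 1L)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  pas <- unlist(lapply(seq_len(nc), function(c) v_index(c, 1:np, topo)))
  # leak on passive compartments
  add(pas, pas, rep(-passive$g_leak, length(pas)))
  b0 <- numeric(nv)
  b0[pas] <- passive$g_leak * passive$e_leak
  # axial links i <-> i+1 within each cable (includes link to active comp)
  for (c in seq_len(nc)) {
    i1 <- v_index(c, 1:np, topo)
    i2 <- v_index(c, 2:(np + 1L), topo)
    add(i1, i2, rep(passive$g_axial, np))
    add(i2, i1, rep(passive$g_axial, np))
    add(i1, i1, rep(-passive$g_axial, np))
    add(i2, i2, rep(-passive$g_axial, np))
  }
  # gap junctions
  gj <- topo$gj
  if (nrow(gj) > 0) {
    ia <- v_index(gj$cable_a, gj$comp_a, topo)
    ib <- v_index(gj$cable_b, gj$comp_b, topo)
    add(ia, ib, gj$g_gj); add(ib, ia, gj$g_gj)
    add(ia, ia, -gj$g_gj); add(ib, ib, -gj$g_gj)
  }
  # collapse duplicate triplets
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  Tm <- methods::as(M, "TsparseMatrix")

  stim_vec <- numeric(nv)
  if (length(stim$stimulated_cables) > 0)
    stim_vec[v_index(stim$stimulated_cables, stim$target_compartment, topo)] <-
      stim$amplitude

  active_idx <- v_index(seq_len(nc), np + 1L, topo)
  cm <- rep(passive$c_m, nv)
  cm[active_idx] <- active$c_m

  ml <- active
  rhs <- function(t, state) {
    v <- state[seq_len(nv)]
    w <- state[nv + seq_len(nc)]
    dv <- as.numeric(M %*% v) + b0
    if (t >= stim$onset && t < stim$onset + stim$duration)
      dv <- dv + stim_vec
    va <- v[active_idx]
    wt <- w_inf_tau(va, ml)
    dv[active_idx] <- dv[active_idx] -
      ml$g_ca * m_inf(va, ml) * (va - ml$e_ca) -
      ml$g_k * w * (va - ml$e_k) - ml$g_l * (va - ml$e_l)
    dw <- ml$phi * (wt$w_inf - w) / wt$tau_w
    c(dv / cm, dw)
  }

  initial_state <- function() {
    # start at the network's resting fixed point so that the settling
    # period before stimulus onset carries no transient artifacts
    network_rest_(M, b0, active_idx, ml, passive, nv, nc)
  }

  structure(list(
    topo = topo, passive = passive, active = active, stim = stim,
    n_v = nv, n_cables = nc, n_passive = np,
    A_i = Tm@i, A_j = Tm@j, A_x = Tm@x, M = M, b0 = b0,
    stim_vec = stim_vec, active_idx = active_idx, cm = cm,
    rhs = rhs, initial_state = initial_state
  ), class = "network_system")
}

# Newton solve of the unstimulated network fixed point. The recovery
# variable is eliminated through w = w_inf(V), leaving a V-only root
# problem: M V + b0 + I_ML(V_active) = 0.
network_rest_ <- function(M, b0, active_idx, ml, passive, nv, nc,
                          tol = 1e-10, max_iter = 50) {
  rest1 <- ml_rest(ml, g_axial = passive$g_axial,
                   v_neighbor = passive$e_leak)
  v <- rep(passive$e_leak, nv)
  v[active_idx] <- rest1$v
  Md <- as.matrix(M)
  for (it in seq_len(max_iter)) {
    va <- v[active_idx]
    u1 <- (va - ml$v1) / ml$v2
    u3 <- (va - ml$v3) / ml$v4
    m <- 0.5 * (1 + tanh(u1))
    wv <- 0.5 * (1 + tanh(u3))
    f <- as.numeric(Md %*% v) + b0
    f[active_idx] <- f[active_idx] -
      ml$g_ca * m * (va - ml$e_ca) - ml$g_k * wv * (va - ml$e_k) -
      ml$g_l * (va - ml$e_l)
    if (max(abs(f)) < tol) break
    dm <- (1 - tanh(u1)^2) / (2 * ml$v2)
    dw <- (1 - tanh(u3)^2) / (2 * ml$v4)
    J <- Md
    dia <- -ml$g_ca * (dm * (va - ml$e_ca) + m) -
      ml$g_k * (dw * (va - ml$e_k) + wv) - ml$g_l
    J[cbind(active_idx, active_idx)] <- J[cbind(active_idx, active_idx)] + dia
    v <- v - solve(J, f)
  }
  c(v, 0.5 * (1 + tanh((v[active_idx] - ml$v3) / ml$v4)))
}

#' Resting fixed point of an assembled network
#'
#' Solves the unstimulated steady state of the full nonlinear network by
#' Newton iteration, with the recovery variables eliminated through their
#' nullcline `w = w_inf(V)`.
#'
#' @param sys A `network_system` from [assemble_network()].
#' @return Flat state vector (packing of [v_index()]) at rest.
#' @export
network_rest <- function(sys) {
  network_rest_(sys$M, sys$b0, sys$active_idx, sys$active, sys$passive,
                sys$n_v, sys$n_cables)
}

#' Steady state of an all-passive network under constant input
#'
#' With the active compartments replaced by passive ones (pure leak), the
#' network is linear and its steady state under a constant stimulus solves
#' the sparse system `-(M - g_leak on active diag) V = b0 + stim`. Used as
#' an independent oracle for the relaxed dynamics.
#'
#' @param sys A `network_system` from [assemble_network()].
#' @return Numeric vector of steady-state potentials (length `n_v`).
#' @export
passive_steady_state <- function(sys) {
  M <- sys$M
  b <- sys$b0 + sys$stim_vec
  # give the active compartments the passive leak so the system is linear
  d <- rep(0, sys$n_v)
  d[sys$active_idx] <- -sys$passive$g_leak
  b[sys$active_idx] <- b[sys$active_idx] +
    sys$passive$g_leak * sys$passive$e_leak
  A <- M + Matrix::Diagonal(sys$n_v, d)
  as.numeric(Matrix::solve(A, -b))
}
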