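#' Passive-compartment parameters
#'
#' Lumped electrical constants of one passive cable compartment. Units are
#' lumped per-compartment quantities (uF, mS, mV), not densities: the model
#' carries no explicit geometry, so only conductance ratios matter for the
#' qualitative filtering regimes.
#'
#' @param c_m Membrane capacitance per compartment (uF). Must be > 0.
#' @param g_leak Leak conductance (mS). Must be >= 0.
#' @param e_leak Leak reversal potential (mV).
#' @param g_axial Axial conductance between serially adjacent compartments of
#'   one cable (mS). Must be > 0.
#' @return An object of class `passive_params`.
#' @export
#' @examples
#' passive_params()
passive_params <- function(c_m = 1, g_leak = 0.1, e_leak = -60, g_axial = 1) {
  stopifnot(is.numeric(c_m), c_m > 0, is.numeric(g_leak), g_leak >= 0,
            is.numeric(e_leak), is.finite(e_leak),
            is.numeric(g_axial), g_axial > 0)
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 g_axial = g_axial),
            class = "passive_params")
}

#' Morris-Lecar active-compartment parameters
#'
#' Parameters of the two-variable (V, w) Morris-Lecar impulse generator that
#' terminates the proximal end of every cable. The default set is the classic
#' Hopf (type II) parameterization.
#'
#' @param c_m Membrane capacitance (uF).
#' @param g_ca,g_k,g_l Maximal calcium, potassium and leak conductances (mS).
#' @param e_ca,e_k,e_l Reversal potentials (mV).
#' @param v1,v2 Half-activation and slope voltage of the instantaneous
#'   calcium activation (mV); `v2 > 0`.
#' @param v3,v4 Half-activation and slope voltage of the potassium recovery
#'   variable (mV); `v4 > 0`.
#' @param phi Recovery rate scale (1/ms); `phi > 0`.
#' @return An object of class `ml_params`.
#' @export
#' @examples
#' p <- ml_params()
#' m_inf(p$v1, p)  # 0.5 at half-activation
ml_params <- function(c_m = 20, g_ca = 4.4, g_k = 8, g_l = 2,
                      e_ca = 120, e_k = -84, e_l = -60,
                      v1 = -1.2, v2 = 18, v3 = 2, v4 = 30, phi = 0.04) {
  stopifnot(c_m > 0, g_ca >= 0, g_k >= 0, g_l >= 0,
            v2 > 0, v4 > 0, phi > 0,
            all(is.finite(c(e_ca, e_k, e_l, v1, v3))))
  structure(list(c_m = c_m, g_ca = g_ca, g_k = g_k, g_l = g_l,
                 e_ca = e_ca, e_k = e_k, e_l = e_l,
                 v1 = v1, v2 = v2, v3 = v3, v4 = v4, phi = phi),
            class = "ml_params")
}

#' Steady-state calcium activation
#'
#' `m_inf(V) = (1 + tanh((V - v1) / v2)) / 2`. The calcium conductance is
#' treated as instantaneous, so this is the only calcium gating quantity.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param p An [ml_params()] object.
#' @return Activation in \[0, 1\], strictly increasing in `v`.
#' @export
m_inf <- function(v, p) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  0.5 * (1 + tanh((v - p$v1) / p$v2))
}

#' Recovery-variable steady state and time constant
#'
#' `w_inf(V) = (1 + tanh((V - v3) / v4)) / 2` and
#' `tau_w(V) = 1 / cosh((V - v3) / (2 v4))` (ms). `tau_w` is maximal at
#' `v = v3`.
#'
#' @inheritParams m_inf
#' @return A list with components `w_inf` (in \[0, 1\]) and `tau_w` (ms > 0).
#' @export
w_inf_tau <- function(v, p) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  u <- (v - p$v3)
  list(w_inf = 0.5 * (1 + tanh(u / p$v4)),
       tau_w = 1 / cosh(u / (2 * p$v4)))
}

#' Ohmic gap-junction current
#'
#' Current flowing into the `self` compartment through one gap junction:
#' `I = g_gj * (v_partner - v_self)` (uA), positive values depolarize self.
#' The junction is undirected: the two directed currents of one junction are
#' exactly antisymmetric.
#'
#' @param v_self,v_partner Membrane potentials (mV) of the two coupled
#'   compartments.
#' @param g_gj Junction conductance (mS), must be >= 0.
#' @return Current (uA) into the self compartment.
#' @export
#' @examples
#' gap_junction_current(-60, -50, 0.1)  # +1 uA into self
gap_junction_current <- function(v_self, v_partner, g_gj) {
  if (any(g_gj < 0)) stop("gap-junction conductance must be non-negative")
  g_gj * (v_partner - v_self)
}

#' Morris-Lecar right-hand side of one active compartment
#'
#' `c_m dV/dt = -g_ca m_inf(V)(V - e_ca) - g_k w (V - e_k) - g_l (V - e_l) +
#' i_axial`; `dw/dt = phi (w_inf(V) - w) / tau_w(V)`.
#'
#' @param v Membrane potential (mV).
#' @param w Recovery variable in \[0, 1\].
#' @param i_axial Axial current (uA) arriving from the most proximal passive
#'   compartment of the same cable.
#' @param p An [ml_params()] object.
#' @return Numeric vector `c(dv, dw)` (mV/ms, 1/ms).
#' @export
active_rhs <- function(v, w, i_axial, p) {
  if (!all(is.finite(c(v, w, i_axial)))) stop("non-finite state")
  wt <- w_inf_tau(v, p)
  i_ion <- -p$g_ca * m_inf(v, p) * (v - p$e_ca) -
    p$g_k * w * (v - p$e_k) - p$g_l * (v - p$e_l)
  c((i_ion + i_axial) / p$c_m,
    p$phi * (wt$w_inf - w) / wt$tau_w)
}

#' Resting fixed point of a Morris-Lecar compartment
#'
#' Locates `(V*, w*)` with `active_rhs(V*, w*, i_axial, p) == c(0, 0)`:
#' the lowest zero of the voltage balance with `w = w_inf(V)` is bracketed
#' on a grid and polished by root finding. With `g_axial > 0` the balance
#' includes an ohmic coupling `g_axial (v_neighbor - V)` to a neighboring
#' compartment held at `v_neighbor`, which gives the appropriate resting
#' point for an active compartment attached to a passive chain at rest.
#'
#' @param p An [ml_params()] object.
#' @param i_axial Constant axial current (uA), default 0.
#' @param v_init Starting voltage for the search (mV).
#' @param g_axial Coupling conductance to a clamped neighbor (mS).
#' @param v_neighbor Neighbor potential (mV); only used when `g_axial > 0`.
#' @return A list with components `v` and `w`.
#' @export
ml_rest <- function(p, i_axial = 0, v_init = p$e_l, g_axial = 0,
                    v_neighbor = p$e_l) {
  f <- function(v) {
    w <- w_inf_tau(v, p)$w_inf
    -p$g_ca * m_inf(v, p) * (v - p$e_ca) - p$g_k * w * (v - p$e_k) -
      p$g_l * (v - p$e_l) + i_axial + g_axial * (v_neighbor - v)
  }
  # bracket the lowest zero crossing, then polish with uniroot
  vs <- seq(v_init - 40, v_init + 40, by = 0.5)
  fv <- vapply(vs, f, numeric(1))
  k <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(k) == 0) stop("no resting point found near v_init")
  r <- stats::uniroot(f, c(vs[k[1]], vs[k[1] + 1]), tol = 1e-12)
  list(v = r$root, w = w_inf_tau(r$root, p)$w_inf)
}
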