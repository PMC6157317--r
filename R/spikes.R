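#' Detect spikes as thresholded upward crossings
#'
#' A spike is recorded at each upward crossing of `threshold` (sample k
#' below, sample k+1 at or above), with successive spikes separated by at
#' least `refractory` ms. Detection is deterministic.
#'
#' @param v_trace Membrane-potential series (mV) on a uniform grid.
#' @param times Matching time grid (ms).
#' @param threshold Spike threshold (mV), default 0.
#' @param refractory Minimum inter-spike interval (ms), >= 0, default 2.
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' detect_spikes(30 * sin(t / 5) - 10, t)
detect_spikes <- function(v_trace, times, threshold = 0, refractory = 2) {
  if (length(v_trace) == 0) stop("empty voltage trace")
  stopifnot(length(v_trace) == length(times), refractory >= 0)
  n <- length(v_trace)
  up <- which(v_trace[-n] < threshold & v_trace[-1] >= threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  ct <- times[up]
  keep <- ct[1]
  if (length(ct) > 1)
    for (k in 2:length(ct))
      if (ct[k] - keep[length(keep)] >= refractory) keep <- c(keep, ct[k])
  keep
}

#' Summarize a trajectory into spike statistics
#'
#' Extracts per-cable spike times at the active compartments, counts the
#' cables that produced at least one impulse, flags back-propagation (a
#' passive compartment of the same cable exceeding `backprop_threshold`
#' within `backprop_window` ms after an active-compartment spike), and
#' records the peak depolarization of every compartment.
#'
#' @param traj A `trajectory` from [integrate_network()].
#' @param threshold Spike threshold at the active compartment (mV).
#' @param refractory Refractory period for detection (ms).
#' @param backprop_threshold Potential a passive compartment must exceed to
#'   count as invaded by a back-propagating impulse (mV), default -20.
#' @param backprop_window Time window after each spike (ms), default 10.
#' @return An object of class `spike_summary` with fields `spike_times`
#'   (list, one numeric vector per cable), `spiking_cable_count`,
#'   `spiking_cables`, `backprop` (logical per cable), and `peak_v`
#'   (matrix cables x compartments, mV).
#' @export
summarize_trajectory <- function(traj, threshold = 0, refractory = 2,
                                 backprop_threshold = -20,
                                 backprop_window = 10) {
  stopifnot(inherits(traj, "trajectory"))
  stim <- traj$stim
  if (max(traj$times) < stim$onset + stim$duration ||
      max(traj$times) < stim$onset + 100)
    stop("trajectory must cover the full stimulus window and at least ",
         "100 ms past stimulus onset")
  topo <- traj$topo
  np <- topo$spec$n_passive
  nc <- topo$n_cables
  spike_times <- vector("list", nc)
  backprop <- logical(nc)
  peak_v <- matrix(NA_real_, nc, np + 1L)
  for (c in seq_len(nc)) {
    va <- compartment_trace(traj, c, np + 1L)
    st <- detect_spikes(va, traj$times, threshold, refractory)
    spike_times[[c]] <- st
    Vp <- traj$V[, v_index(c, 1:np, topo), drop = FALSE]
    peak_v[c, ] <- c(apply(Vp, 2, max), max(va))
    if (length(st) > 0) {
      after <- rep(FALSE, length(traj$times))
      for (s in st)
        after <- after | (traj$times >= s & traj$times <= s + backprop_window)
      backprop[c] <- any(Vp[after, , drop = FALSE] > backprop_threshold)
    }
  }
  spiking <- which(vapply(spike_times, length, integer(1)) > 0)
  structure(list(spike_times = spike_times,
                 spiking_cable_count = length(spiking),
                 spiking_cables = spiking,
                 backprop = backprop,
                 peak_v = peak_v,
                 threshold = threshold, refractory = refractory),
            class = "spike_summary")
}

#' @export
print.spike_summary <- function(x, ...) {
  cat(sprintf("spike_summary: %d spiking cable(s) of %d: %s\n",
              x$spiking_cable_count, length(x$spike_times),
              paste(x$spiking_cables, collapse = ", ")))
  invisible(x)
}
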