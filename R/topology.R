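#' Cable specification
#'
#' One cable stands for one unbranched dendritic process: `n_passive`
#' serially connected passive compartments (index 1 is the most distal,
#' sealed input end) terminated by a single Morris-Lecar active compartment
#' at index `n_passive + 1` (the proximal impulse-initiation site).
#'
#' @param n_passive Number of passive compartments (default 9).
#' @return An object of class `cable_spec`.
#' @export
cable_spec <- function(n_passive = 9) {
  stopifnot(is.numeric(n_passive), n_passive >= 1, n_passive == round(n_passive))
  structure(list(n_passive = as.integer(n_passive)), class = "cable_spec")
}

#' Gap-junction edge
#'
#' An undirected ohmic coupling between passive compartments of two distinct
#' cables. The active compartment can never carry a gap junction.
#'
#' @param cable_a,cable_b Cable indices (1-based); must differ.
#' @param comp_a,comp_b Passive compartment indices on each cable.
#' @param g_gj Junction conductance (mS), >= 0.
#' @return An object of class `gap_junction`.
#' @export
gap_junction <- function(cable_a, comp_a, cable_b, comp_b, g_gj) {
  stopifnot(cable_a != cable_b, g_gj >= 0, comp_a >= 1, comp_b >= 1)
  structure(list(cable_a = as.integer(cable_a), comp_a = as.integer(comp_a),
                 cable_b = as.integer(cable_b), comp_b = as.integer(comp_b),
                 g_gj = g_gj),
            class = "gap_junction")
}

#' Stimulus protocol
#'
#' A rectangular current step delivered to the most distal passive
#' compartment (index 1) of a set of cables, emulating receptor current
#' entering at the tips of the dendritic processes.
#'
#' @param stimulated_cables Integer vector of cable indices receiving input.
#' @param amplitude Step amplitude i_ext (uA), >= 0.
#' @param onset Step onset (ms), default 0.
#' @param duration Step duration (ms), > 0, default 200.
#' @return An object of class `stimulus_protocol`. The target compartment is
#'   fixed to 1 (the sealed distal end).
#' @export
stimulus_protocol <- function(stimulated_cables, amplitude,
                              onset = 0, duration = 200) {
  stopifnot(amplitude >= 0, duration > 0,
            length(stimulated_cables) == 0 || all(stimulated_cables >= 1))
  structure(list(stimulated_cables = as.integer(sort(unique(stimulated_cables))),
                 target_compartment = 1L, amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stimulus_protocol")
}

#' Network topology
#'
#' A bundle of identical cables plus a list of gap-junction edges.
#'
#' @param n_cables Number of cables.
#' @param spec A [cable_spec()].
#' @param gap_junctions A list of [gap_junction()] objects (possibly empty).
#' @param condition Label for the coupling pattern: one of `"none"`,
#'   `"distal"`, `"middle"`, `"proximal"`, `"custom"`.
#' @return An object of class `network_topology` whose `gj` element is a
#'   data frame with columns `cable_a, comp_a, cable_b, comp_b, g_gj`.
#' @export
network_topology <- function(n_cables, spec = cable_spec(),
                             gap_junctions = list(), condition = "custom") {
  stopifnot(n_cables >= 1,
            condition %in% c("none", "distal", "middle", "proximal", "custom"))
  np <- spec$n_passive
  if (length(gap_junctions) > 0) {
    gj <- do.call(rbind, lapply(gap_junctions, function(j) {
      stopifnot(inherits(j, "gap_junction"))
      data.frame(cable_a = j$cable_a, comp_a = j$comp_a,
                 cable_b = j$cable_b, comp_b = j$comp_b, g_gj = j$g_gj)
    }))
    if (any(gj$cable_a > n_cables | gj$cable_b > n_cables))
      stop("gap junction references a cable outside the network")
    if (any(gj$comp_a > np | gj$comp_b > np))
      stop("gap junctions must connect passive compartments (index <= ",
           np, ")")
    # canonical undirected key to detect duplicates
    key <- ifelse(gj$cable_a < gj$cable_b,
                  paste(gj$cable_a, gj$comp_a, gj$cable_b, gj$comp_b),
                  paste(gj$cable_b, gj$comp_b, gj$cable_a, gj$comp_a))
    if (anyDuplicated(key)) stop("duplicate gap-junction edges")
  } else {
    gj <- data.frame(cable_a = integer(), comp_a = integer(),
                     cable_b = integer(), comp_b = integer(),
                     g_gj = numeric())
  }
  structure(list(n_cables = as.integer(n_cables), spec = spec, gj = gj,
                 condition = condition),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("network_topology: %d cables x (%d passive + 1 active), %d gap junctions [%s]\n",
              x$n_cables, x$spec$n_passive, nrow(x$gj), x$condition))
  invisible(x)
}

#' Ladder topologies of the preset simulation experiments
#'
#' Builds the two-dimensional parallel-cable arrangement used in the preset
#' experiments: cables 1..n side by side, with one gap junction between each
#' nearest-neighbor pair (cable k and k+1) at a single passive compartment
#' whose index encodes the coupling level: 2 (distal), 5 (middle) or 9
#' (proximal). `condition = "none"` yields the uncoupled control.
#'
#' @param n_cables Number of cables (>= 2).
#' @param condition One of `"none"`, `"distal"`, `"middle"`, `"proximal"`.
#' @param g_gj Gap-junction conductance (mS), shared by all junctions.
#' @param spec A [cable_spec()]; the compartment indices above assume the
#'   default 9 passive compartments.
#' @return A [network_topology()].
#' @export
#' @examples
#' build_ladder_topology(10, "proximal", 0.5)
build_ladder_topology <- function(n_cables, condition, g_gj,
                                  spec = cable_spec()) {
  stopifnot(n_cables >= 2)
  condition <- match.arg(condition, c("none", "distal", "middle", "proximal"))
  if (condition == "none")
    return(network_topology(n_cables, spec, list(), condition))
  comp <- switch(condition, distal = 2L, middle = 5L, proximal = 9L)
  if (comp > spec$n_passive)
    stop("cable has too few passive compartments for condition ", condition)
  gjs <- lapply(seq_len(n_cables - 1), function(k)
    gap_junction(k, comp, k + 1L, comp, g_gj))
  network_topology(n_cables, spec, gjs, condition)
}

#' Preset stimulus protocols
#'
#' The preset experiments stimulate 7 of the cables: the interior block
#' (cables 2-8) in the 10-cable network, and the edge-anchored set
#' 1,2,3,4,6,7,9 in the 20-cable network (a calibrated commitment — the
#' published figure patterns are not machine-readable; see the methods
#' vignette). `strength` selects the calibrated strong or weak amplitude
#' from `params`.
#'
#' @param n_cables 10 or 20 (the preset sizes).
#' @param strength `"strong"` or `"weak"`.
#' @param params A [preset_params()] carrying the calibrated amplitudes.
#' @return A [stimulus_protocol()].
#' @export
default_stimulus <- function(n_cables, strength = c("strong", "weak"),
                             params = preset_params()) {
  strength <- match.arg(strength)
  cables <- switch(as.character(n_cables),
                   "10" = 2:8,
                   "20" = c(1L, 2L, 3L, 4L, 6L, 7L, 9L),
                   stop("no preset stimulus for ", n_cables,
                        " cables; construct a stimulus_protocol() directly"))
  amp <- if (strength == "strong") params$strong else params$weak
  stimulus_protocol(cables, amp)
}
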