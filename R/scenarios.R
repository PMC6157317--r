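#' Frozen preset parameters
#'
#' The four free constants of the preset experiments — strong and weak
#' stimulus amplitudes, the gap-junction conductance, and the axial
#' conductance — fixed once by [calibrate_presets()] against the eight
#' published spiking-cable counts and then frozen here. The calibration
#' provenance (grids searched, feasible set, margins) ships in
#' `inst/calibration/provenance.json`.
#'
#' @param strong Strong stimulus amplitude (uA).
#' @param weak Weak stimulus amplitude (uA); must be < `strong`.
#' @param g_gj Gap-junction conductance (mS).
#' @param g_axial Axial conductance (mS).
#' @param g_leak Passive leak conductance (mS). The calibrated presets use
#'   an electrotonically compact chain (leak much smaller than the axial
#'   conductance), which the published counts require; see the methods
#'   vignette.
#' @return An object of class `preset_params`.
#' @export
preset_params <- function(strong = .frozen_presets$strong,
                          weak = .frozen_presets$weak,
                          g_gj = .frozen_presets$g_gj,
                          g_axial = .frozen_presets$g_axial,
                          g_leak = .frozen_presets$g_leak) {
  stopifnot(strong > 0, weak > 0, weak < strong, g_gj >= 0, g_axial > 0,
            g_leak >= 0)
  structure(list(strong = strong, weak = weak, g_gj = g_gj,
                 g_axial = g_axial, g_leak = g_leak),
            class = "preset_params")
}

#' Scenario configuration
#'
#' A declarative description of one simulation experiment, resolvable to a
#' concrete (topology, stimulus, parameters) triple. Presets are named
#' `fig7_<cond>` (10 cables, strong input), `fig8_<cond>` (10 cables, weak
#' input) and `fig9_<cond>` (20 cables, strong input) with `<cond>` one of
#' `none`, `distal`, `middle`, `proximal`.
#'
#' @param preset Preset name, or `NULL` for a fully explicit scenario.
#' @param n_cables,condition,strength Used when `preset` is `NULL` (or to
#'   override parts of it).
#' @param params A [preset_params()].
#' @param topology Optional explicit [network_topology()] (overrides the
#'   ladder construction).
#' @param stimulus Optional explicit [stimulus_protocol()].
#' @param passive,active Optional [passive_params()] / [ml_params()]
#'   overrides; by default the packaged defaults with `g_axial` taken from
#'   `params`.
#' @param dt Integration step (ms).
#' @param t_span Simulation window (ms); the default gives a 50 ms
#'   unstimulated settling period before the 200 ms stimulus plus 50 ms tail.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(preset = NULL, n_cables = 10,
                            condition = "none",
                            strength = c("strong", "weak"),
                            params = preset_params(),
                            topology = NULL, stimulus = NULL,
                            passive = NULL, active = ml_params(),
                            dt = 0.01, t_span = c(-50, 250)) {
  strength <- match.arg(strength)
  if (!is.null(preset)) {
    m <- regmatches(preset,
                    regexec("^fig([789])_(none|distal|middle|proximal)$",
                            preset))[[1]]
    if (length(m) == 0)
      stop("unknown preset '", preset, "'; expected fig{7,8,9}_{none,distal,middle,proximal}")
    n_cables <- if (m[2] == "9") 20L else 10L
    strength <- if (m[2] == "8") "weak" else "strong"
    condition <- m[3]
  }
  if (is.null(passive))
    passive <- passive_params(g_leak = params$g_leak,
                              g_axial = params$g_axial)
  structure(list(preset = preset, n_cables = as.integer(n_cables),
                 condition = condition, strength = strength,
                 params = params, topology = topology, stimulus = stimulus,
                 passive = passive, active = active,
                 dt = dt, t_span = t_span),
            class = "scenario_config")
}

#' Run one scenario
#'
#' Resolves the configuration, integrates the network, and reduces the
#' trajectory to a `scenario_result`: the spike summary, the spiking-cable
#' count, and the identity of any cables that fired without receiving
#' direct input. Ladder presets are fully deterministic.
#'
#' @param cfg A [scenario_config()].
#' @param keep_trajectory Keep the full trajectory in the result (large);
#'   default `FALSE`.
#' @return An object of class `scenario_result`.
#' @export
#' @examples
#' \donttest{
#' r <- run_scenario(scenario_config("fig7_none"))
#' r$spiking_cable_count  # 7
#' }
run_scenario <- function(cfg, keep_trajectory = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  topo <- cfg$topology
  if (is.null(topo))
    topo <- if (cfg$condition == "none")
      build_ladder_topology(cfg$n_cables, "none", 0)
    else
      build_ladder_topology(cfg$n_cables, cfg$condition, cfg$params$g_gj)
  stim <- cfg$stimulus
  if (is.null(stim))
    stim <- default_stimulus(cfg$n_cables, cfg$strength, cfg$params)
  sys <- assemble_network(topo, cfg$passive, cfg$active, stim)
  traj <- integrate_network(sys, cfg$t_span, cfg$dt)
  sm <- summarize_trajectory(traj)
  nonstim_fired <- setdiff(sm$spiking_cables, stim$stimulated_cables)
  structure(list(summary = sm,
                 condition = topo$condition,
                 strength = cfg$strength,
                 spiking_cable_count = sm$spiking_cable_count,
                 spiking_cables = sm$spiking_cables,
                 nonstim_fired = nonstim_fired,
                 config = cfg,
                 trajectory = if (keep_trajectory) traj else NULL),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result [%s, %s]: %d spiking cable(s)%s\n",
              x$condition, x$strength, x$spiking_cable_count,
              if (length(x$nonstim_fired) > 0)
                paste0(" (non-stimulated: ",
                       paste(x$nonstim_fired, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Classify the filtering regime of a coupling condition
#'
#' Compares the spiking-cable count of a coupled network with its uncoupled
#' control: gap junctions that recruit extra cables implement a
#' stronger-input-spread filter (`"spread"`), junctions that abolish firing
#' implement a weaker-input-cut filter (`"cut"`), and an unchanged count is
#' `"neutral"`.
#'
#' @param count_with_gj Spiking-cable count with gap junctions.
#' @param count_without_gj Spiking-cable count of the matched uncoupled
#'   control.
#' @return One of `"spread"`, `"cut"`, `"neutral"`.
#' @export
#' @examples
#' classify_regime(9, 7)  # "spread"
#' classify_regime(0, 7)  # "cut"
classify_regime <- function(count_with_gj, count_without_gj) {
  stopifnot(length(count_with_gj) == 1, length(count_without_gj) == 1)
  if (count_with_gj < 0 || count_without_gj < 0)
    stop("spike counts cannot be negative")
  if (count_with_gj > count_without_gj) "spread"
  else if (count_with_gj < count_without_gj) "cut"
  else "neutral"
}

# internal: spiking-cable count of one ladder scenario at given constants
.ladder_count <- function(n_cables, condition, amplitude, g_gj, g_axial,
                          dt = 0.01, t_span = c(-50, 250),
                          active = ml_params(),
                          g_leak = preset_params()$g_leak) {
  topo <- if (condition == "none")
    build_ladder_topology(n_cables, "none", 0)
  else build_ladder_topology(n_cables, condition, g_gj)
  stim <- stimulus_protocol(if (n_cables == 10) 2:8 else
    c(1L, 2L, 3L, 4L, 6L, 7L, 9L), amplitude)
  sys <- assemble_network(topo,
                          passive_params(g_leak = g_leak,
                                         g_axial = g_axial),
                          active, stim)
  sm <- summarize_trajectory(integrate_network(sys, t_span, dt))
  list(count = sm$spiking_cable_count,
       nonstim = setdiff(sm$spiking_cables, stim$stimulated_cables))
}

# internal: do all strong-input constraints (the published counts) hold at
# this amplitude?
.strong_ok <- function(amp, g_gj, g_axial, dt = 0.01,
                       g_leak = preset_params()$g_leak) {
  c10 <- function(cond)
    .ladder_count(10, cond, amp, g_gj, g_axial, dt, g_leak = g_leak)$count
  if (c10("none") != 7) return(FALSE)
  if (c10("distal") != 0) return(FALSE)
  if (c10("middle") != 0) return(FALSE)
  if (c10("proximal") != 9) return(FALSE)
  if (.ladder_count(20, "distal", amp, g_gj, g_axial, dt,
                    g_leak = g_leak)$count != 2)
    return(FALSE)
  if (.ladder_count(20, "middle", amp, g_gj, g_axial, dt,
                    g_leak = g_leak)$count != 3)
    return(FALSE)
  p20 <- .ladder_count(20, "proximal", amp, g_gj, g_axial, dt,
                       g_leak = g_leak)
  p20$count == 8 && length(p20$nonstim) >= 1
}

# internal: do all weak-input constraints hold at this amplitude?
.weak_ok <- function(amp, g_gj, g_axial, dt = 0.01,
                     g_leak = preset_params()$g_leak) {
  c10 <- function(cond)
    .ladder_count(10, cond, amp, g_gj, g_axial, dt, g_leak = g_leak)$count
  c10("none") == 7 && c10("distal") == 0 && c10("middle") == 0 &&
    c10("proximal") == 0
}

# internal: bisection distance from amp (where pred holds) to the nearest
# amplitude where it fails, searched towards `towards`
.margin_bisect <- function(pred, amp, towards, iters = 8) {
  lo <- amp; hi <- towards
  if (pred(hi)) return(abs(hi - amp))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (pred(mid)) lo <- mid else hi <- mid
  }
  abs(lo - amp)
}

#' Calibrate the preset parameters against the published spike counts
#'
#' Grid search over (strong amplitude, weak amplitude, gap-junction
#' conductance, axial conductance) for points at which all eight preset
#' outcomes hold simultaneously: with strong input, the 10-cable ladder
#' gives 7 (uncoupled), 0 (distal), 0 (middle) and 9 (proximal) spiking
#' cables and the 20-cable ladder gives 2 (distal), 3 (middle) and 8
#' (proximal, including a cable with no direct input); with weak input the
#' 10-cable ladder gives 7 uncoupled and 0 under every coupling condition.
#' Among satisfying points the one maximizing the amplitude margin (distance
#' to the nearest count change, measured by bisection) is returned.
#'
#' This search is run once at build time; its result is frozen into
#' [preset_params()] and all tests run against the frozen constants.
#'
#' @param strong_grid,weak_grid Amplitude grids (uA).
#' @param g_gj_grid,g_axial_grid Conductance grids (mS).
#' @param dt Integration step used during the search (ms).
#' @param g_leak Passive leak conductance (mS), held fixed during the
#'   search.
#' @param verbose Print progress.
#' @return A list with `params` (a [preset_params()] or `NULL` if no grid
#'   point satisfies every constraint), `feasible` (data frame of all
#'   satisfying grid points with margins), and `closest_miss` (when
#'   infeasible: per-point constraint diagnostics).
#' @export
calibrate_presets <- function(strong_grid, weak_grid, g_gj_grid,
                              g_axial_grid, dt = 0.01,
                              g_leak = preset_params()$g_leak,
                              verbose = TRUE) {
  stopifnot(length(strong_grid) > 0, length(weak_grid) > 0,
            length(g_gj_grid) > 0, length(g_axial_grid) > 0)
  feasible <- list()
  misses <- list()
  for (ga in g_axial_grid) for (gj in g_gj_grid) {
    s_ok <- vapply(strong_grid, .strong_ok, logical(1), gj, ga, dt, g_leak)
    w_ok <- vapply(weak_grid, .weak_ok, logical(1), gj, ga, dt, g_leak)
    if (verbose)
      message(sprintf("g_axial=%g g_gj=%g: %d/%d strong, %d/%d weak feasible",
                      ga, gj, sum(s_ok), length(s_ok),
                      sum(w_ok), length(w_ok)))
    if (!any(s_ok) || !any(w_ok)) {
      misses[[length(misses) + 1]] <- data.frame(
        g_axial = ga, g_gj = gj,
        n_strong_ok = sum(s_ok), n_weak_ok = sum(w_ok))
      next
    }
    for (s in strong_grid[s_ok]) for (w in weak_grid[w_ok]) {
      if (w >= s) next
      step_s <- if (length(strong_grid) > 1)
        min(diff(sort(unique(strong_grid)))) else 0.1 * s
      step_w <- if (length(weak_grid) > 1)
        min(diff(sort(unique(weak_grid)))) else 0.1 * w
      ms <- min(
        .margin_bisect(function(a) .strong_ok(a, gj, ga, dt, g_leak),
                       s, s - step_s),
        .margin_bisect(function(a) .strong_ok(a, gj, ga, dt, g_leak),
                       s, s + step_s))
      mw <- min(
        .margin_bisect(function(a) .weak_ok(a, gj, ga, dt, g_leak),
                       w, w - step_w),
        .margin_bisect(function(a) .weak_ok(a, gj, ga, dt, g_leak),
                       w, w + step_w))
      feasible[[length(feasible) + 1]] <- data.frame(
        strong = s, weak = w, g_gj = gj, g_axial = ga,
        margin = min(ms, mw))
    }
  }
  feasible <- if (length(feasible) > 0) do.call(rbind, feasible) else NULL
  misses <- if (length(misses) > 0) do.call(rbind, misses) else NULL
  if (is.null(feasible)) {
    warning("no grid point satisfies all preset constraints")
    return(list(params = NULL, feasible = NULL, closest_miss = misses))
  }
  best <- feasible[which.max(feasible$margin), ]
  list(params = preset_params(best$strong, best$weak, best$g_gj,
                              best$g_axial, g_leak),
       feasible = feasible, closest_miss = misses)
}

#' Amplitude x conductance sweep over coupling conditions
#'
#' Runs every (amplitude, g_gj, condition) cell of a grid on the ladder
#' network and tabulates the spiking-cable count and the filtering regime
#' relative to the matched uncoupled control at the same amplitude.
#'
#' @param amplitudes Stimulus amplitudes (uA).
#' @param g_gj_values Gap-junction conductances (mS).
#' @param conditions Subset of `c("none","distal","middle","proximal")`.
#' @param n_cables Ladder size (preset stimulus pattern is used).
#' @param g_axial Axial conductance (mS).
#' @param dt Integration step (ms).
#' @param g_leak Passive leak conductance (mS).
#' @return A data frame with columns `amplitude, g_gj, condition, count,
#'   control_count, regime`.
#' @export
sweep_grid <- function(amplitudes, g_gj_values,
                       conditions = c("none", "distal", "middle", "proximal"),
                       n_cables = 10, g_axial = preset_params()$g_axial,
                       dt = 0.01, g_leak = preset_params()$g_leak) {
  stopifnot(length(amplitudes) > 0, length(g_gj_values) > 0,
            length(conditions) > 0)
  rows <- list()
  for (amp in amplitudes) {
    control <- .ladder_count(n_cables, "none", amp, 0, g_axial, dt,
                             g_leak = g_leak)$count
    for (gj in g_gj_values) for (cond in conditions) {
      cnt <- if (cond == "none") control
      else .ladder_count(n_cables, cond, amp, gj, g_axial, dt,
                         g_leak = g_leak)$count
      rows[[length(rows) + 1]] <- data.frame(
        amplitude = amp, g_gj = gj, condition = cond,
        count = cnt, control_count = control,
        regime = classify_regime(cnt, control))
    }
  }
  do.call(rbind, rows)
}

#' Spiking-cable counts over sampled morphology-derived networks
#'
#' Extends the ladder experiments to networks whose wiring is drawn from
#' the calibrated bundle statistics: for each seed, a bundle graph is
#' sampled, reduced to `n_keep` cables, simulated under the preset stimulus
#' strength applied to `n_stim` randomly chosen cables, and summarized.
#'
#' @param stats A [morph_stats()].
#' @param n_keep Cables retained per sampled network (>= 2).
#' @param seeds Integer vector of seeds, one network per seed.
#' @param strength `"strong"` or `"weak"`.
#' @param n_stim Number of stimulated cables (default 7, the preset).
#' @param g_gj Conductance per adhesion contact (mS); defaults to the
#'   frozen preset value.
#' @param params A [preset_params()].
#' @param dt Integration step (ms).
#' @return A list with `per_seed` (data frame: seed, n_gj, count,
#'   n_nonstim_fired) and `summary` (mean and sd of counts).
#' @export
network_scale_experiment <- function(stats, n_keep, seeds,
                                     strength = c("strong", "weak"),
                                     n_stim = 7, g_gj = NULL,
                                     params = preset_params(), dt = 0.01) {
  strength <- match.arg(strength)
  stopifnot(n_keep >= 2, length(seeds) > 0, n_stim <= n_keep)
  if (is.null(g_gj)) g_gj <- params$g_gj
  amp <- if (strength == "strong") params$strong else params$weak
  rows <- lapply(seeds, function(sd) {
    g <- sample_bundle(stats, sd)
    topo <- graph_to_topology(g, g_gj, n_keep, seed = sd)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(sd))
    stim_cables <- sort(sample(seq_len(n_keep), n_stim))
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    stim <- stimulus_protocol(stim_cables, amp)
    sys <- assemble_network(topo,
                            passive_params(g_leak = params$g_leak,
                                           g_axial = params$g_axial),
                            ml_params(), stim)
    sm <- summarize_trajectory(integrate_network(sys, c(-50, 250), dt))
    data.frame(seed = sd, n_gj = nrow(topo$gj),
               count = sm$spiking_cable_count,
               n_nonstim_fired = length(setdiff(sm$spiking_cables,
                                                stim_cables)))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       summary = c(mean = mean(per_seed$count), sd = stats::sd(per_seed$count)))
}
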