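#' Read a scenario configuration file
#'
#' Accepts YAML or JSON with optional sections `preset`, `topology`,
#' `stimulus`, `params`, `integration`. Any omitted entry falls back to the
#' packaged default, so the minimal useful config is a single line naming a
#' preset.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed config: top level must be a mapping")
  pp <- do.call(preset_params, as.list(raw$params %||% list()))
  topo <- NULL
  n_cables <- raw$topology$n_cables %||% 10
  condition <- raw$topology$condition %||% "none"
  if (!is.null(raw$topology$gap_junctions)) {
    gj_tab <- as.data.frame(raw$topology$gap_junctions)
    gjs <- lapply(seq_len(nrow(gj_tab)), function(i)
      gap_junction(gj_tab$cable_a[i], gj_tab$comp_a[i],
                   gj_tab$cable_b[i], gj_tab$comp_b[i],
                   gj_tab$g_gj[i] %||% pp$g_gj))
    topo <- network_topology(n_cables, cable_spec(), gjs, "custom")
  }
  stim <- NULL
  if (!is.null(raw$stimulus$cables))
    stim <- stimulus_protocol(unlist(raw$stimulus$cables),
                              raw$stimulus$amplitude,
                              raw$stimulus$onset %||% 0,
                              raw$stimulus$duration %||% 200)
  integ <- raw$integration %||% list()
  scenario_config(
    preset = raw$preset,
    n_cables = n_cables, condition = condition,
    strength = raw$stimulus$strength %||% "strong",
    params = pp, topology = topo, stimulus = stim,
    dt = integ$dt %||% 0.01,
    t_span = unlist(integ$t_span %||% c(-50, 250)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory as a long-format CSV
#'
#' One row per (time, cable, compartment) with columns `time_ms, cable,
#' compartment, V_mV, w`; `w` is empty except on active-compartment rows.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @param thin Keep every `thin`-th time sample (default 10) to bound file
#'   size.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, thin = 10L) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- seq(1, length(traj$times), by = thin)
  topo <- traj$topo
  np1 <- topo$spec$n_passive + 1L
  rows <- lapply(seq_len(topo$n_cables), function(c) {
    do.call(rbind, lapply(seq_len(np1), function(i) data.frame(
      time_ms = traj$times[keep], cable = c, compartment = i,
      V_mV = traj$V[keep, v_index(c, i, topo)],
      w = if (i == np1) traj$W[keep, c] else NA_real_)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a trajectory CSV
#' @param path File written by [write_trajectory_csv()].
#' @return Data frame with the exported columns.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}

#' Export a spike summary as JSON
#'
#' @param summary A `spike_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "spike_summary"))
  obj <- list(
    spiking_cable_count = summary$spiking_cable_count,
    spiking_cables = as.integer(summary$spiking_cables),
    spike_times = lapply(summary$spike_times, as.numeric),
    backprop = as.logical(summary$backprop),
    threshold = summary$threshold, refractory = summary$refractory)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a spike-summary JSON
#' @param path File written by [write_summary_json()].
#' @return A list with the exported fields.
#' @export
read_summary_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a bundle graph as JSON
#'
#' Serializes beads (with positions and zones), adhesion edges, the
#' generating statistics and the seed, so the file alone reproduces the
#' graph.
#'
#' @param g A `bundle_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "bundle_graph"))
  st <- unclass(g$stats)
  st$beads_pmf <- as.numeric(st$beads_pmf)
  st$adhesion_pmf <- as.numeric(st$adhesion_pmf)
  obj <- list(seed = g$seed, dropped_stubs = g$dropped_stubs,
              stats = st, beads = g$beads, edges = g$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read back a bundle-graph JSON
#' @param path File written by [write_graph_json()].
#' @return A `bundle_graph`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- obj$stats
  stats <- morph_stats(
    n_processes = st$n_processes, total_beads = st$total_beads,
    total_incidences = st$total_incidences,
    zero_adhesion_beads = st$zero_adhesion_beads,
    distal_incidences = st$distal_incidences,
    proximal_incidences = st$proximal_incidences,
    beads_support = st$beads_support,
    adhesion_support = st$adhesion_support,
    degree_range = st$degree_range, axial_domain = st$axial_domain,
    distal_mean = st$distal_mean, proximal_mean = st$proximal_mean,
    axial_sd = st$axial_sd)
  structure(list(beads = as.data.frame(obj$beads),
                 edges = as.data.frame(obj$edges),
                 stats = stats, seed = as.integer(obj$seed),
                 dropped_stubs = as.integer(obj$dropped_stubs)),
            class = "bundle_graph")
}

#' Write a run manifest
#'
#' Machine-readable record sufficient to re-run a result bit-identically:
#' configuration hash, package version, seeds, timestamp, output paths.
#'
#' @param out_paths Named character vector/list of files the run produced.
#' @param seeds Seeds used (possibly empty).
#' @param config_hash Hash string of the resolved configuration (any stable
#'   digest; the CLI uses the serialized config).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(out_paths, seeds, config_hash, path) {
  obj <- list(package = "sensillanet",
              version = as.character(utils::packageVersion("sensillanet")),
              config_hash = config_hash,
              seeds = as.integer(seeds),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              outputs = as.list(out_paths))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Stable hash of an R object (for manifests)
#' @param x Any serializable object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  # simple polynomial rolling checksum; dependency-free and stable
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
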