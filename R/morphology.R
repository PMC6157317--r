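#' Empirical bead and adhesion-region statistics of a dendritic bundle
#'
#' Calibration constants of the stochastic bundle generator: the counts
#' enumerated by electron microscopy in one reconstructed basiconic
#' sensillum. 102 unbranched dendritic processes carried 388 beads (local
#' swellings, 1-7 per process) bearing 696 adhesion-region incidences
#' (putative gap-junction contacts; each physical contact contributes one
#' incidence to each of its two beads). 95 beads carried no adhesion region;
#' the rest carried 1-12. Incidences split into a distal peak (191) and a
#' proximal peak (505) along the sensillar axis, measured relative to the
#' outer antennal cuticle surface (0 = surface, positive = distal).
#'
#' @param n_processes Number of dendritic processes in the bundle.
#' @param total_beads Target total bead count.
#' @param total_incidences Target total adhesion-region incidences.
#' @param zero_adhesion_beads Target count of beads with no adhesion region.
#' @param distal_incidences,proximal_incidences Target incidence split
#'   between the distal and proximal peaks (must sum to `total_incidences`).
#' @param beads_support Support of the per-process bead-count distribution.
#' @param adhesion_support Support of the per-bead incidence distribution
#'   (adhesion-bearing beads only).
#' @param degree_range Reference range of the number of adjacent processes
#'   per process.
#' @param axial_domain Axial extent (um) of the modeled region.
#' @param distal_mean,proximal_mean,axial_sd Parameters (um) of the
#'   zone-conditional truncated-normal bead-position distributions.
#' @return An object of class `morph_stats`.
#' @export
morph_stats <- function(n_processes = 102, total_beads = 388,
                        total_incidences = 696, zero_adhesion_beads = 95,
                        distal_incidences = 191, proximal_incidences = 505,
                        beads_support = 1:7, adhesion_support = 1:12,
                        degree_range = c(3, 17), axial_domain = c(-10, 8),
                        distal_mean = 4, proximal_mean = -4, axial_sd = 2) {
  stopifnot(n_processes >= 1, total_beads > 0, total_incidences > 0,
            zero_adhesion_beads >= 0, zero_adhesion_beads < total_beads,
            distal_incidences + proximal_incidences == total_incidences,
            axial_domain[1] < axial_domain[2], axial_sd > 0)
  mean_beads <- total_beads / n_processes
  mean_adh <- total_incidences / (total_beads - zero_adhesion_beads)
  stopifnot(mean_beads >= min(beads_support), mean_beads <= max(beads_support),
            mean_adh >= min(adhesion_support), mean_adh <= max(adhesion_support))
  structure(list(
    n_processes = as.integer(n_processes),
    total_beads = total_beads, total_incidences = total_incidences,
    zero_adhesion_beads = zero_adhesion_beads,
    distal_incidences = distal_incidences,
    proximal_incidences = proximal_incidences,
    p_distal = distal_incidences / total_incidences,
    p_zero = zero_adhesion_beads / total_beads,
    beads_support = beads_support,
    beads_pmf = maxent_pmf(beads_support, mean_beads),
    adhesion_support = adhesion_support,
    adhesion_pmf = maxent_pmf(adhesion_support, mean_adh),
    degree_range = degree_range, axial_domain = axial_domain,
    distal_mean = distal_mean, proximal_mean = proximal_mean,
    axial_sd = axial_sd
  ), class = "morph_stats")
}

#' Maximum-entropy distribution on a finite integer support with given mean
#'
#' The distribution maximizing entropy on `support` subject to a mean
#' constraint has the exponential-family form `p_k proportional to
#' exp(lambda k)`; `lambda` is solved by root finding. This is the
#' least-assumption completion of a distribution of which only the support
#' and the mean are known.
#'
#' @param support Integer support (strictly increasing).
#' @param mean_target Required mean; must lie inside the support range.
#' @return Named numeric vector of probabilities over `support`.
#' @export
#' @examples
#' p <- maxent_pmf(1:7, 388 / 102)
#' sum(p * (1:7))  # 3.80392...
maxent_pmf <- function(support, mean_target) {
  stopifnot(length(support) >= 2, all(diff(support) > 0),
            mean_target > min(support), mean_target < max(support))
  mean_at <- function(lam) {
    lw <- lam * support
    w <- exp(lw - max(lw))
    sum(w * support) / sum(w)
  }
  r <- stats::uniroot(function(l) mean_at(l) - mean_target,
                      lower = -20, upper = 20, tol = 1e-13)
  lw <- r$root * support
  w <- exp(lw - max(lw))
  stats::setNames(w / sum(w), support)
}

# draw from a truncated normal by inverse-CDF (deterministic given RNG state)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Sample a dendritic-bundle connectivity graph
#'
#' Draws one synthetic bundle with the statistical structure of the
#' measured morphology: per process, a bead count from the calibrated pmf;
#' per bead, a zone (distal/proximal, with the stub-weighted zone
#' probability `p_distal`), an axial position from the zone's truncated
#' normal, and an adhesion-incidence count (zero with probability `p_zero`,
#' otherwise from the calibrated pmf on 1-12). Incidence stubs are then
#' paired within each zone by a uniform configuration-model matching that
#' rejects matchings containing same-process pairs (adhesions join distinct
#' processes); one leftover stub per odd-sized zone is dropped and the
#' owning bead's incidence count decremented, so the handshake identity
#' (sum of incidences = 2 x edges) holds exactly on the returned graph.
#'
#' @param stats A [morph_stats()] object.
#' @param seed Integer seed; fixes all randomness of the draw.
#' @param max_retries Full re-shuffles attempted before giving up on a
#'   conflict-free matching.
#' @return An object of class `bundle_graph`: `beads` (data frame with
#'   process, bead, zone, axial_um, n_adhesions), `edges` (data frame with
#'   bead_a, bead_b, process_a, process_b, zone), the generating `stats`,
#'   `seed`, and `dropped_stubs`.
#' @export
#' @examples
#' g <- sample_bundle(morph_stats(), seed = 1)
#' nrow(g$beads); sum(g$beads$n_adhesions) == 2 * nrow(g$edges)
sample_bundle <- function(stats, seed, max_retries = 5000L) {
  stopifnot(inherits(stats, "morph_stats"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  np <- stats$n_processes
  n_beads_per <- sample(stats$beads_support, np, replace = TRUE,
                        prob = stats$beads_pmf)
  nb <- sum(n_beads_per)
  process <- rep(seq_len(np), n_beads_per)
  zone <- ifelse(stats::runif(nb) < stats$p_distal, "distal", "proximal")
  axial <- numeric(nb)
  di <- zone == "distal"
  axial[di] <- rtruncnorm1(sum(di), stats$distal_mean, stats$axial_sd,
                           stats$axial_domain[1], stats$axial_domain[2])
  axial[!di] <- rtruncnorm1(sum(!di), stats$proximal_mean, stats$axial_sd,
                            stats$axial_domain[1], stats$axial_domain[2])
  n_adh <- ifelse(stats::runif(nb) < stats$p_zero, 0L,
                  sample(stats$adhesion_support, nb, replace = TRUE,
                         prob = stats$adhesion_pmf))
  beads <- data.frame(process = process, bead = seq_len(nb),
                      zone = zone, axial_um = axial, n_adhesions = n_adh)

  dropped <- 0L
  edges <- list()
  for (z in c("distal", "proximal")) {
    bz <- beads$zone == z
    stubs <- rep(beads$bead[bz], beads$n_adhesions[bz])
    if (length(stubs) %% 2 == 1) {
      # drop one uniformly chosen stub; keep incidence bookkeeping exact
      k <- sample.int(length(stubs), 1)
      beads$n_adhesions[stubs[k]] <- beads$n_adhesions[stubs[k]] - 1L
      stubs <- stubs[-k]
      dropped <- dropped + 1L
    }
    if (length(stubs) == 0) next
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      perm <- sample(stubs)
      a <- perm[seq(1, length(perm), by = 2)]
      b <- perm[seq(2, length(perm), by = 2)]
      if (!any(beads$process[a] == beads$process[b])) { ok <- TRUE; break }
    }
    if (!ok)
      stop("no conflict-free stub matching found in zone '", z,
           "' after ", max_retries, " retries; try a different seed")
    edges[[z]] <- data.frame(bead_a = a, bead_b = b,
                             process_a = beads$process[a],
                             process_b = beads$process[b],
                             zone = z)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(bead_a = integer(), bead_b = integer(),
               process_a = integer(), process_b = integer(),
               zone = character())
  rownames(edges) <- NULL
  structure(list(beads = beads, edges = edges, stats = stats,
                 seed = as.integer(seed), dropped_stubs = dropped),
            class = "bundle_graph")
}

#' @export
print.bundle_graph <- function(x, ...) {
  cat(sprintf("bundle_graph: %d processes, %d beads, %d adhesion edges (seed %d)\n",
              x$stats$n_processes, nrow(x$beads), nrow(x$edges), x$seed))
  invisible(x)
}

#' Adjacency degree of each process
#'
#' Number of distinct other processes a process touches through adhesion
#' edges.
#'
#' @param g A `bundle_graph`.
#' @return Integer vector of length `n_processes`.
#' @export
bundle_degrees <- function(g) {
  stopifnot(inherits(g, "bundle_graph"))
  np <- g$stats$n_processes
  deg <- integer(np)
  if (nrow(g$edges) > 0) {
    pairs <- unique(rbind(
      data.frame(p = g$edges$process_a, q = g$edges$process_b),
      data.frame(p = g$edges$process_b, q = g$edges$process_a)))
    tab <- table(factor(pairs$p, levels = seq_len(np)))
    deg <- as.integer(tab)
  }
  deg
}

#' Map an axial position to a passive compartment index
#'
#' Monotone map from the axial coordinate (um; positive = distal) to the
#' passive compartment index of a cable: the distal end of the domain maps
#' to compartment 1, the proximal end to compartment `n_passive`.
#'
#' @param axial_um Axial positions (um).
#' @param n_passive Passive compartments per cable.
#' @param domain Axial extent, `c(proximal_limit, distal_limit)`.
#' @return Integer compartment indices in `1..n_passive`.
#' @export
axial_to_compartment <- function(axial_um, n_passive = 9,
                                 domain = c(-10, 8)) {
  x <- pmin(pmax(axial_um, domain[1]), domain[2])
  idx <- round(1 + (domain[2] - x) / (domain[2] - domain[1]) * (n_passive - 1))
  as.integer(pmin(pmax(idx, 1), n_passive))
}

#' Convert a sampled bundle graph into a simulable network topology
#'
#' Keeps `n_keep` processes (a seeded uniform subsample), maps every
#' adhesion edge between kept processes to a gap junction at the passive
#' compartments given by each endpoint bead's axial position, and drops
#' edges touching removed processes. Parallel contacts mapping to the same
#' compartment pair are merged by summing their conductances.
#'
#' @param g A `bundle_graph`.
#' @param g_gj Conductance per adhesion contact (mS), uniform.
#' @param n_keep Number of processes to keep (>= 1).
#' @param seed Seed for the subsample.
#' @param compartment_map Function mapping axial um to compartment index;
#'   defaults to [axial_to_compartment()] over the stats' axial domain.
#' @param spec A [cable_spec()].
#' @return A [network_topology()] with `n_keep` cables.
#' @export
graph_to_topology <- function(g, g_gj, n_keep = g$stats$n_processes,
                              seed = g$seed, compartment_map = NULL,
                              spec = cable_spec()) {
  stopifnot(inherits(g, "bundle_graph"), n_keep >= 1,
            n_keep <= g$stats$n_processes)
  if (is.null(compartment_map))
    compartment_map <- function(x)
      axial_to_compartment(x, spec$n_passive, g$stats$axial_domain)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  kept <- sort(sample(seq_len(g$stats$n_processes), n_keep))
  cable_of <- match(seq_len(g$stats$n_processes), kept)  # NA if dropped
  e <- g$edges
  e <- e[!is.na(cable_of[e$process_a]) & !is.na(cable_of[e$process_b]), ,
         drop = FALSE]
  if (nrow(e) == 0)
    return(network_topology(n_keep, spec, list(), "custom"))
  ca <- cable_of[e$process_a]
  cb <- cable_of[e$process_b]
  ka <- compartment_map(g$beads$axial_um[e$bead_a])
  kb <- compartment_map(g$beads$axial_um[e$bead_b])
  # canonical orientation, then merge parallel contacts
  flip <- ca > cb
  tmp <- ca[flip]; ca[flip] <- cb[flip]; cb[flip] <- tmp
  tmp <- ka[flip]; ka[flip] <- kb[flip]; kb[flip] <- tmp
  df <- stats::aggregate(
    list(g = rep(g_gj, length(ca))),
    by = list(cable_a = ca, comp_a = ka, cable_b = cb, comp_b = kb), FUN = sum)
  gjs <- lapply(seq_len(nrow(df)), function(i)
    gap_junction(df$cable_a[i], df$comp_a[i], df$cable_b[i], df$comp_b[i],
                 df$g[i]))
  network_topology(n_keep, spec, gjs, "custom")
}
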