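test_that("maximum-entropy pmf hits the target mean with exponential form", {
  p <- maxent_pmf(1:7, 388 / 102)
  expect_equal(sum(p), 1)
  expect_equal(sum(p * (1:7)), 388 / 102, tolerance = 1e-10)
  # exponential-family characterization: log p is affine in k
  expect_equal(unname(diff(log(p))), rep(unname(diff(log(p))[1]), 6),
               tolerance = 1e-8)
  q <- maxent_pmf(1:12, 696 / 293)
  expect_equal(sum(q * (1:12)), 696 / 293, tolerance = 1e-10)
  expect_error(maxent_pmf(1:7, 8), "mean_target")
})

test_that("morph_stats defaults encode the measured bundle counts", {
  st <- morph_stats()
  expect_identical(st$n_processes, 102L)
  expect_equal(st$distal_incidences + st$proximal_incidences,
               st$total_incidences)
  expect_equal(st$p_distal, 191 / 696)
  expect_equal(st$p_zero, 95 / 388)
  expect_error(morph_stats(distal_incidences = 200), "total_incidences")
})

test_that("bundle sampling is seed-deterministic and leaves the RNG alone", {
  st <- morph_stats()
  g1 <- sample_bundle(st, seed = 7)
  set.seed(123); r_before <- runif(1)
  g2 <- sample_bundle(st, seed = 7)
  expect_identical(g1$beads, g2$beads)
  expect_identical(g1$edges, g2$edges)
  g3 <- sample_bundle(st, seed = 8)
  expect_false(identical(g1$edges, g3$edges))
  # global RNG stream is restored around the seeded draw
  set.seed(123)
  expect_identical(runif(1), r_before)
})

test_that("sampled bundles respect support, handshake and zone locality", {
  st <- morph_stats()
  for (seed in 1:25) {
    g <- sample_bundle(st, seed)
    bp <- table(g$beads$process)
    expect_true(all(bp >= 1 & bp <= 7))
    expect_identical(length(bp), 102L)
    adh <- g$beads$n_adhesions
    expect_true(all(adh >= 0 & adh <= 12))
    # handshake: every incidence is one end of one realized contact
    expect_identical(sum(adh), 2L * nrow(g$edges))
    # adhesions join distinct processes, within one zone
    expect_true(all(g$edges$process_a != g$edges$process_b))
    expect_identical(g$beads$zone[g$edges$bead_a],
                     g$edges$zone)
    expect_identical(g$beads$zone[g$edges$bead_b],
                     g$edges$zone)
    # axial positions live in the modeled domain
    expect_true(all(g$beads$axial_um >= st$axial_domain[1] &
                      g$beads$axial_um <= st$axial_domain[2]))
  }
})

test_that("sampler means track the measured totals over many seeds", {
  st <- morph_stats()
  draws <- lapply(1:200, function(s) {
    g <- sample_bundle(st, s)
    c(beads = nrow(g$beads),
      inc = sum(g$beads$n_adhesions),
      zero = sum(g$beads$n_adhesions == 0),
      distal = sum(g$beads$n_adhesions[g$beads$zone == "distal"]))
  })
  m <- colMeans(do.call(rbind, draws))
  expect_equal(unname(m["beads"]), 388, tolerance = 0.02)
  expect_equal(unname(m["inc"]), 696, tolerance = 0.02)
  expect_equal(unname(m["zero"]), 95, tolerance = 0.05)
  # stub-weighted zone split converges to 191:505
  expect_equal(unname(m["distal"] / m["inc"]), 191 / 696, tolerance = 0.05)
})

test_that("adjacency degrees are mostly inside the observed 3-17 range", {
  st <- morph_stats()
  fr <- vapply(1:50, function(s) {
    deg <- bundle_degrees(sample_bundle(st, s))
    mean(deg >= 3 & deg <= 17)
  }, numeric(1))
  # soft realism check; the attained fraction is reported by the
  # acceptance tooling, here we require a clear majority
  expect_gt(mean(fr), 0.6)
})

test_that("axial positions map monotonically onto compartments", {
  x <- seq(8, -10, length.out = 50)
  idx <- axial_to_compartment(x)
  expect_true(all(diff(idx) >= 0))
  expect_identical(axial_to_compartment(8), 1L)
  expect_identical(axial_to_compartment(-10), 9L)
  expect_identical(axial_to_compartment(100), 1L)   # clamped
  expect_identical(axial_to_compartment(-100), 9L)
})

test_that("graph_to_topology maps kept edges and drops the rest", {
  st <- morph_stats()
  g <- sample_bundle(st, 3)
  topo <- graph_to_topology(g, g_gj = 0.5)
  # total mapping: every edge becomes gap-junction conductance; merged
  # parallel contacts conserve the summed conductance
  expect_identical(topo$n_cables, 102L)
  expect_equal(sum(topo$gj$g_gj), 0.5 * nrow(g$edges))
  expect_true(all(topo$gj$comp_a <= 9 & topo$gj$comp_b <= 9))
  # a single kept process has no partners
  topo1 <- graph_to_topology(g, g_gj = 0.5, n_keep = 1)
  expect_identical(nrow(topo1$gj), 0L)
  # subsampling drops edges to removed processes
  topo20 <- graph_to_topology(g, g_gj = 0.5, n_keep = 20, seed = 5)
  expect_identical(topo20$n_cables, 20L)
  expect_lt(nrow(topo20$gj), nrow(g$edges))
})

test_that("proximal-only bundles wire at proximal compartments", {
  st <- morph_stats(distal_incidences = 0, proximal_incidences = 696,
                    proximal_mean = -6, axial_sd = 1)
  g <- sample_bundle(st, 11)
  expect_true(all(g$beads$zone == "proximal"))
  topo <- graph_to_topology(g, g_gj = 0.5)
  expect_true(all(c(topo$gj$comp_a, topo$gj$comp_b) >= 5))
})
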