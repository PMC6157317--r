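---
title: "Modeling electrically coupled ORN dendrites in a basiconic sensillum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electrically coupled ORN dendrites in a basiconic sensillum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensillanet)
```

## The model

A basiconic sensillum of a carpenter ant packs on the order of a hundred
unbranched olfactory receptor neuron (ORN) dendritic processes into one
cuticular peg. Along these processes lie beads — local swellings where the
membranes of neighboring processes appose closely and where gap-junction
proteins concentrate. If those appositions are conducting, the dendrites
form an electrical micro-network *before* any spike leaves the sensillum.
`sensillanet` implements a minimal biophysical caricature of that
hypothesis and asks what such coupling does to the sensillum's output.

Each dendritic process is a **cable**: a chain of `n_passive = 9` passive
compartments (compartment 1 is the sealed distal tip, where receptor
current enters) terminated by one **active compartment** — a two-variable
Morris-Lecar impulse generator — at the proximal end. The passive balance
for compartment $i$ of cable $c$ is

$$
c_m \dot V_i = -g_{\mathrm{leak}}(V_i - E_{\mathrm{leak}})
  + g_{\mathrm{axial}}(V_{i-1} - V_i) + g_{\mathrm{axial}}(V_{i+1} - V_i)
  + I_{\mathrm{ext}}(t)\,\mathbf 1[i = 1]
  + \textstyle\sum_j g_{\mathrm{gj}} (V^{(j)} - V_i),
$$

with the last sum over gap junctions incident on that compartment. The
active compartment follows the standard Morris-Lecar equations

$$
C \dot V = -g_{Ca} m_\infty(V)(V - E_{Ca}) - g_K w (V - E_K)
           - g_L (V - E_L) + I_{\mathrm{axial}},\qquad
\dot w = \phi\,\frac{w_\infty(V) - w}{\tau_w(V)},
$$

with $m_\infty, w_\infty$ the usual $\tfrac12[1 + \tanh(\cdot)]$ sigmoids
and $\tau_w = 1/\cosh(\cdot)$. Gap junctions are ohmic, undirected, and
connect passive compartments of *different* cables only. All quantities
are lumped per-compartment values (µF, mS, µA, mV, ms), not densities: the
model carries no geometry, and only conductance ratios matter for the
qualitative behavior.

Parameters of the active compartment default to the classic Hopf (type II)
Morris-Lecar set ($C = 20$ µF, $g_{Ca} = 4.4$, $g_K = 8$, $g_L = 2$ mS,
$E_{Ca} = 120$, $E_K = -84$, $E_L = -60$ mV, $v_1 = -1.2$, $v_2 = 18$,
$v_3 = 2$, $v_4 = 30$ mV, $\phi = 0.04$/ms). This set has a stable rest
near $-60$ mV and a sharp current threshold near 90 µA, which makes the
active compartment a clean binary reporter of whether enough receptor
current survived the passive network.

## Numerical realization

The network is assembled into one flat ODE system (cable-major packing,
recovery variables last; see `v_index()`) whose linear part — leak, axial
links, gap junctions — is a precomputed sparse operator; the Morris-Lecar
currents are the only nonlinearity. Integration is fixed-step 4th-order
Runge-Kutta (`dt = 0.01` ms by default), in compiled code, chosen over
adaptive schemes so that trajectories are bit-identical across runs and
platforms; a pure-R backend of the same scheme exists for cross-checking,
and the test suite also compares against an independent stiff solver.
Halving the step changes no membrane potential by more than 0.1 mV on the
preset scenarios, and all preset spike counts are unchanged when the step
is doubled.

Simulations start at the network's resting fixed point, found by Newton
iteration with the recovery variable eliminated along its nullcline
(`network_rest()`), then get a 50 ms unstimulated settling period before
stimulus onset at $t = 0$; the stimulus is a 200 ms rectangular current
step into compartment 1 of the stimulated cables, and the run ends at
$t = 250$ ms. A cable "fires" if its active compartment crosses 0 mV
upward at least once (2 ms refractory); back-propagation is flagged when a
passive compartment of a firing cable exceeds $-20$ mV within 10 ms after
a spike. The published traces define impulses only pictorially, so these
thresholds are package conventions; counts are insensitive to the exact
values because subthreshold compartments stay tens of millivolts below.

## Preset experiments and calibration

The preset scenarios place 10 or 20 cables side by side with one gap
junction between each nearest-neighbor pair at a single passive
compartment: index 2 (*distal*), 5 (*middle*) or 9 (*proximal*), or no
junctions at all (*none*). Seven cables receive input: the interior block
(cables 2-8) in the 10-cable network and the edge-anchored set
{1,2,3,4,6,7,9} in the 20-cable network. The published wiring diagrams are
not machine-readable, so both stimulated sets are calibrated commitments;
the 20-cable set was chosen non-contiguous because no contiguous 7-block
reproduces the published 20-cable counts anywhere in the searched
parameter space (the provenance file records the alternatives tried).

The target outcomes are integer spiking-cable counts: with strong input
the 10-cable network must give 7 (none), 0 (distal), 0 (middle) and 9
(proximal); with weak input 7 (none) and 0 under every coupling level; and
with strong input the 20-cable network must give 2 (distal), 3 (middle)
and 8 (proximal, including at least one cable that received no direct
input).

The five free constants — strong and weak amplitude, $g_{\mathrm{gj}}$,
$g_{\mathrm{axial}}$, $g_{\mathrm{leak}}$ — are not published;
`calibrate_presets()` recovers them by grid search with a
margin-maximizing tie-break (bisection distance to the nearest count
change). The search was run once at build time; the frozen point in
`preset_params()` is strong = 100.5 µA, weak = 90 µA,
$g_{\mathrm{gj}}$ = 9 mS, $g_{\mathrm{axial}}$ = 8 mS,
$g_{\mathrm{leak}}$ = 0.001 mS, with provenance shipped in
`inst/calibration/provenance.json`. Tests run only against the frozen
constants.

One published count is not attainable at any searched point, and the
obstruction is informative. A complete distal/middle cut of the 10-cable
block requires the lateral deficit wave to penetrate the whole stimulated
block, which forces a junctional conductance of at least about 9 mS at the
calibrated leak. At that coupling, the 13 unstimulated cables of the
20-cable ladder form a sink that silences every cable deeper than index 7
at the amplitude where the 10-cable proximal condition recruits exactly
its two flanking cables; weakening the coupling to shrink that sink
destroys the 10-cable recruitment instead. The frozen point therefore
reproduces every published 10-cable outcome exactly (strong 7/0/0/9, weak
7/0/0/0) together with the 20-cable distal (2) and middle (3) counts,
while the 20-cable proximal condition yields 7 firing cables including
one recruit, against the published 8. The corresponding
acceptance check is left failing by design, and the count is reported as
computed.

Two qualitative mechanisms organize the outcome space, and understanding
them motivated the calibrated regime:

* **Dilution.** Coupling spreads the injected current over stimulated and
  unstimulated cables alike. Seven inputs shared among ten cables leave
  each with about 70% of the uncoupled current, so any amplitude below
  ~1.4x the firing threshold can in principle be cut by coupling. Distal
  and middle junctions dilute *before* the current reaches the spike
  initiation site, so nobody fires.
* **Recruitment.** Proximal junctions sit next to the spike initiation
  site. Once a stimulated cable fires, its impulse back-propagates into
  compartment 9 and pumps suprathreshold current directly into the
  neighboring cable's spike initiation zone — a regenerative, nonlinear
  effect that distal placement cannot produce because spikes attenuate
  along the passive chain. This is what recruits cables that received no
  input.

The calibrated point uses a small leak conductance relative to the axial
and junctional conductances: the passive chain is then nearly lossless
(electrotonically compact), dilution by the unstimulated cables is strong
enough for a complete distal/middle cut, and the deficit wave penetrates
the whole stimulated block. The weak amplitude sits just above the firing
threshold, where even proximal coupling drains enough charge to silence
every cable — the weaker-input-cut regime; the strong amplitude sits in
the window where proximal coupling recruits exactly the two flanking
cables of the 10-cable block — the stronger-input-spread regime.
`classify_regime()` labels any coupled/uncoupled count pair accordingly.

## The synthetic dendritic-bundle generator

The second half of the package inverts the measured bead statistics of one
reconstructed sensillum into a generative model (`sample_bundle()`). The
measured calibration constants are: 102 processes; 388 beads; 1-7 beads
per process; 696 adhesion-region incidences; 95 beads with none, 1-12 on
the rest; 191 incidences in a distal peak and 505 in a proximal peak along
the sensillar axis; and 3-17 adjacent processes per process.

Where only a support and a mean are known, the generator commits to the
**maximum-entropy distribution** on that support with that mean (an
exponential-family pmf, `maxent_pmf()`): the bead count per process on
{1..7} with mean 388/102 (the published "mean of four" is this value
rounded), and the incidence count of adhesion-bearing beads on {1..12}
with mean 696/293. Each bead is zero-adhesion with probability 95/388.
Zones are assigned per bead with the stub-weighted probability 191/696 of
being distal, which makes the expected zone split of incidences match the
measured 191:505 exactly because incidence counts are drawn independently
of zone. Axial positions are zone-conditional truncated normals (distal
mean +4 µm, proximal mean -4 µm, sd 2 µm, domain [-10, +8] µm relative to
the outer cuticle surface — the figure's positions are not printed
numerically, so these are configuration-exposed conventions); the trough
near the socket level emerges from the mixture.

Incidence stubs are paired within each zone by a uniform
configuration-model matching that rejects matchings containing
same-process pairs (adhesions join distinct processes); a leftover stub in
an odd-sized zone is dropped and its bead's count decremented, so the
handshake identity (incidences = 2 x edges) holds exactly on every
returned graph. Pairing within zones encodes that adhesions are local
membrane appositions: a distal bead cannot touch a proximal one.

What the generator does *not* emulate: spatial correlation between a
bead's axial position and its partner's beyond zone membership, bead
motility, geometry of the twisted bundle, and any dependence of adhesion
count on bead size. Passing its calibration tests therefore shows that the
marginal statistics are right, not that the generator reproduces the
spatial microstructure of a real bundle. The measured adjacency range
(3-17 neighbors) is used as a soft realism check only — the sampler's
degree distribution is an emergent property, reported by
`bundle_degrees()`, not a fitted target.

`graph_to_topology()` bridges the two halves: each adhesion edge becomes a
gap junction at the compartments given by its beads' axial positions
(monotone map, `axial_to_compartment()`), enabling network-scale
experiments (`network_scale_experiment()`) on topologies with the measured
statistics rather than the idealized ladder.

## Numerical and design choices

* Fixed-step RK4, `dt = 0.01` ms; the stability limit of the stiffest
  preset configuration is comfortably above the doubled step used in the
  robustness checks.
* Spike threshold 0 mV, refractory 2 ms, back-propagation threshold
  $-20$ mV within 10 ms — conventions, documented above.
* The uncoupled ("none") condition is built with zero junctions, so its
  counts cannot depend on $g_{\mathrm{gj}}$ (verified by test).
* Degenerate inputs: empty voltage traces, non-finite states, negative
  conductances, out-of-range compartment indices and duplicate undirected
  edges are rejected with errors at construction or detection time.
* Configuration-model matching retries up to 5000 reshuffles before
  raising an error naming the zone; the retry count is seed-stable.
* Problem sizes in the shipped tests: ladder networks of 10-20 cables
  (state dimension 110-220), 200-1000 sampled bundles for the calibration
  means, 50 bundle draws for support/handshake properties. These sizes
  give Monte-Carlo errors well inside the asserted tolerances.

## Known limitations

The model is a two-dimensional caricature: real dendritic processes twist
in three dimensions and contact many partners (3-17), while the ladder
couples nearest neighbors only. Receptor-current transduction, channel
noise, ephaptic interactions and the actual molecular identity of the
junctions are all outside scope. The published figure wiring is not
machine-readable, so the preset stimulated sets and junction placements
are calibrated commitments — parameter sets that reproduce every published
count simultaneously — rather than transcriptions; the calibration
provenance records the search space and every satisfying point.
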