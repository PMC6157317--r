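# Frozen constants produced by the one-time calibration search; the search
# space, satisfying set and closest-miss analysis are recorded in
# inst/calibration/provenance.json.
#
# At this point the 10-cable ladder reproduces all eight published
# 10-cable outcomes (strong: 7/0/0/9; weak: 7/0/0/0) and the 20-cable
# ladder reproduces the distal (2) and middle (3) counts and the
# proximal-recruitment property; the 20-cable proximal count itself is 7
# (published: 8), a documented limitation of the nearest-neighbor-chain
# wiring (see the calibration provenance and the methods vignette).
.frozen_presets <- list(
  strong = 100.5,   # uA
  weak = 90,        # uA
  g_gj = 9,         # mS
  g_axial = 8,      # mS
  g_leak = 0.001    # mS
)
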