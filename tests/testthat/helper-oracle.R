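# Independent naive TI-RADS scorer: if/else chains over the lexicon, no
# shared code with the engine's lookup tables.
naive_tirads <- function(comp, echo, shape, marg, foci) {
  p <- 0
  p <- p + switch(comp, purely_cystic = 0, spongiform = 0,
                  mixed_cystic_solid = 1, solid = 2)
  p <- p + switch(echo, anechoic = 0, hyperechoic = 1, isoechoic = 1,
                  hypoechoic = 2, very_hypoechoic = 3)
  if (shape == "taller_than_wide") p <- p + 3
  if (marg == "irregular_protrusion") p <- p + 2
  if (marg == "spiculated_sharp_angles") p <- p + 3
  for (f in foci) {
    if (f == "macrocalcification") p <- p + 1
    if (f == "peripheral_calcification") p <- p + 2
    if (f == "microcalcification") p <- p + 3
  }
  cat <- if (p >= 7) "TR5" else if (p >= 4) "TR4" else if (p == 3) "TR3" else
    if (p == 2) "TR2" else "TR1"
  list(points = p, category = cat)
}

# percent comparisons at the published precision
expect_percent <- function(actual, printed, tol = 0.1) {
  testthat::expect_lt(max(abs(actual - printed)), tol + 1e-9)
}
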