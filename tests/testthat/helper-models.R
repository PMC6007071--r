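# Shared fixtures: models and deterministic random states used across tests.

# The AI topology: TI minus the PO -> PP and PO -> OO paths; PO becomes a sink.
ai_model <- function(nt = 2) {
  m <- drop_paths(sw_model("TI", nt = nt), c("p2", "d1"))
  m$name <- "AI"
  m
}

# Deterministic random points on the conservation simplex (reduced coords).
random_simplex_points <- function(n, tot = 4, seed = 42) {
  withr::with_seed(seed, {
    w <- matrix(stats::rexp(4 * n), ncol = 4)
    w <- w / rowSums(w) * tot
    unname(cbind(w[, 1], w[, 2], w[, 3])) # columns: OO, PP, PO
  })
}

# Independent transcription of the reduced mass-action equations, written
# directly from the three balance equations (OP eliminated by conservation).
# Used as the oracle for build_rhs(); kept deliberately separate from the
# package's implementation.
reference_rhs <- function(r, nt, nd, tot, s) {
  OO <- s[[1]]
  PP <- s[[2]]
  PO <- s[[3]]
  OP <- tot - PP - OO - PO
  dOO <- -r["p0"] * nt * PP * OO - r["p1"] * nt * PP * OO +
    r["d0"] * nd * OO * OP + r["d1"] * nd * OO * PO -
    r["bp0"] * nt * OO - r["bp1"] * nt * OO +
    r["bd0"] * nd * OP + r["bd1"] * nd * PO
  dPP <- r["p3"] * nt * PP * OP + r["p2"] * nt * PP * PO -
    r["d2"] * nd * OO * PP - r["d3"] * nd * OO * PP +
    r["bp3"] * nt * OP + r["bp2"] * nt * PO -
    r["bd2"] * nd * PP - r["bd3"] * nd * PP
  dPO <- r["p1"] * nt * PP * OO - r["p2"] * nt * PP * PO +
    r["d2"] * nd * OO * PP - r["d1"] * nd * OO * PO +
    r["bp1"] * nt * OO - r["bp2"] * nt * PO +
    r["bd2"] * nd * PP - r["bd1"] * nd * PO
  unname(c(dOO, dPP, dPO))
}
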