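test_that("regimes classify correctly at representative points", {
  expect_equal(classify_regime(preset("AM"), nt = 4)$regime, "bistable")
  cl9 <- classify_regime(preset("AM"), nt = 9)
  expect_equal(cl9$regime, "monostable")
  st <- cl9$ss[cl9$ss$stability == "stable", ]
  expect_gt(st$PP, st$OO) # only the on branch survives above the window
  cl_ai <- classify_regime(ai_model(), nt = 5)
  expect_equal(cl_ai$regime, "absorbing")
  expect_equal(cl_ai$absorbing_species, "PO")
  expect_equal(classify_regime(preset("BD1"), nt = 4)$regime, "oscillatory")
})

test_that("a coarse sweep reconstructs the hysteresis loop of the switch", {
  bd <- bifurcation_sweep(preset("AM"), step = 0.25)
  g <- glance(bd)
  bist <- g$nt[g$regime == "bistable"]
  expect_gt(length(bist), 10)
  # both stable branches coexist exactly on the bistable window
  pts <- bd$points
  for (nt in c(min(bist), 4, max(bist))) {
    st <- pts[pts$nt == nt & pts$stability == "stable", ]
    expect_equal(nrow(st), 2)
    us <- pts[pts$nt == nt & pts$stability == "unstable", ]
    expect_equal(nrow(us), 1)
    # unstable branch lies between the stable ones in OO
    expect_true(us$OO > min(st$OO) && us$OO < max(st$OO))
  }
  # outside the window a single branch remains
  expect_equal(sum(pts$nt == 0 & pts$stability == "stable"), 1)
  expect_equal(sum(pts$nt == 10 & pts$stability == "stable"), 1)
})

test_that("the broken-paths network shows an oscillatory window on a sigmoid branch", {
  bd <- bifurcation_sweep(preset("BP"), nt_range = c(1, 3.5), step = 0.1)
  expect_gt(nrow(bd$cycles), 3)
  expect_true(all(bd$cycles$nt > 1.5 & bd$cycles$nt < 2.6))
  expect_true(all(bd$cycles$period > 0))
  # never more than one stable state: bistability is lost
  expect_true(all(bd$regimes$n_stable <= 1))
})

test_that("a dead network sweeps to a flat, everywhere-marginal diagram", {
  m <- sw_model(topology = character(0), name = "null")
  bd <- bifurcation_sweep(m, nt_range = c(0, 1), step = 0.5)
  expect_true(all(bd$points$stability == "marginal"))
  expect_true(all(bd$regimes$regime %in% c("monostable", "inconclusive")))
})

test_that("boundary classification flips across each refined boundary", {
  rb <- regime_boundaries(preset("AM"))
  expect_equal(rb$overall, "bistable")
  for (edge in c(rb$bistable_lo, rb$bistable_hi)) {
    inner <- classify_regime(preset("AM"), nt = edge + ifelse(edge < 4, 0.05, -0.05))
    outer <- classify_regime(preset("AM"), nt = edge + ifelse(edge < 4, -0.05, 0.05))
    expect_equal(inner$regime, "bistable")
    expect_false(outer$regime == "bistable")
  }
})

test_that("hysteresis: the realized branch depends on the sweep direction", {
  m <- preset("AM")
  rb <- regime_boundaries(m)
  # forward continuation from the off state stays on the off branch inside
  # the window; backward continuation from the on state stays on the on branch
  nt_mid <- round((rb$bistable_lo + rb$bistable_hi) / 2, 2)
  fwd <- simulate_timecourse(m, init = c(OO = 4), nt = nt_mid, t_end = 3000)
  bwd <- simulate_timecourse(m, init = c(PP = 4), nt = nt_mid, t_end = 3000)
  expect_gt(fwd$OO[nrow(fwd)], 2) # still off
  expect_gt(bwd$PP[nrow(bwd)], 2) # still on
  expect_gt(abs(fwd$OO[nrow(fwd)] - bwd$OO[nrow(bwd)]), 1)
})

test_that("the phospho-swap mirrors the diagram with nt and nd exchanged", {
  m <- preset("TI")
  m$nd <- 2
  for (nt in c(1, 3)) {
    a <- steady_states(m, nt = nt)
    sm <- phospho_swap(m) # nt and nd roles exchanged
    sm$nd <- nt
    b <- steady_states(sm, nt = 2)
    expect_equal(nrow(a), nrow(b))
    # states map OO<->PP, OP<->PO
    a_sorted <- a[order(a$OO), ]
    b_sorted <- b[order(b$PP), ]
    expect_equal(a_sorted$OO, b_sorted$PP, tolerance = 1e-8)
    expect_equal(a_sorted$OP, b_sorted$PO, tolerance = 1e-8)
    expect_equal(a_sorted$stability, b_sorted$stability)
  }
})

test_that("tidy, glance and autoplot work on a sweep", {
  bd <- bifurcation_sweep(preset("AM"), nt_range = c(3, 5), step = 0.5)
  expect_s3_class(tidy(bd), "tbl_df")
  expect_true(all(c("nt", "OO", "PP", "stability") %in% names(tidy(bd))))
  g <- glance(bd)
  expect_equal(nrow(g), 5)
  p <- autoplot(bd)
  expect_s3_class(p, "ggplot")
})
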