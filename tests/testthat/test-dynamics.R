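test_that("a dead network yields a constant trajectory", {
  m <- sw_model(topology = character(0), name = "null")
  traj <- simulate_timecourse(m, init = c(OO = 1, OP = 1, PO = 1, PP = 1), t_end = 50)
  expect_true(all(abs(traj$OO - 1) < 1e-12))
  expect_true(all(abs(traj$PP - 1) < 1e-12))
  expect_equal(check_conservation(traj), 0, tolerance = 1e-12)
})

test_that("mass is conserved along long trajectories", {
  pts <- random_simplex_points(3, seed = 5)
  for (k in seq_len(nrow(pts))) {
    traj <- simulate_timecourse(preset("TI", nt = 4),
      init = c(OO = pts[k, 1], PP = pts[k, 2], PO = pts[k, 3]),
      t_end = 500
    )
    expect_lt(check_conservation(traj), 1e-8)
    expect_gt(min(traj$OO, traj$OP, traj$PO, traj$PP), -1e-9)
  }
})

test_that("check_conservation reports an injected defect exactly", {
  traj <- simulate_timecourse(preset("TI", nt = 2), t_end = 10)
  base <- check_conservation(traj)
  traj$PP[5] <- traj$PP[5] + 0.25
  expect_equal(check_conservation(traj), 0.25, tolerance = 1e-6)
  expect_lt(base, 1e-9)
})

test_that("a trajectory started at a stable steady state stays there", {
  m <- preset("AM", nt = 4)
  ss <- steady_states(m)
  st <- ss[ss$stability == "stable", ][1, ]
  traj <- simulate_timecourse(m,
    init = c(OO = st$OO, OP = st$OP, PO = st$PO, PP = st$PP), t_end = 200
  )
  final <- unlist(traj[nrow(traj), c("OO", "OP", "PO", "PP")])
  expect_lt(max(abs(final - c(st$OO, st$OP, st$PO, st$PP))), 1e-6)
})

test_that("halving the integration tolerances barely moves the endpoint", {
  m <- preset("TI", nt = 4)
  init <- c(OO = 2.5, PP = 1, PO = 0.5)
  t1 <- simulate_timecourse(m, init = init, t_end = 100)
  t2 <- simulate_timecourse(m, init = init, t_end = 100, rtol = 5e-9, atol = 5e-11)
  d <- max(abs(unlist(t1[nrow(t1), -1]) - unlist(t2[nrow(t2), -1])))
  expect_lt(d, 1e-6)
})

test_that("compiled and plain-R derivative routes agree", {
  m <- preset("BP", nt = 2.2)
  init <- c(OO = 2.1, PP = 1.9)
  tc <- simulate_timecourse(m, init = init, t_end = 60)
  tr <- simulate_timecourse(build_rhs(m),
    init = init, t_end = 60,
    tot = m$tot
  )
  expect_lt(max(abs(tc$PP - tr$PP)), 1e-5)
  expect_lt(max(abs(tc$OO - tr$OO)), 1e-5)
})

test_that("site-swap maps trajectories onto each other point-for-point", {
  m <- preset("BP", nt = 4)
  ms <- site_swap(m)
  init <- c(OO = 1.2, OP = 0.3, PO = 0.9, PP = 1.6)
  t1 <- simulate_timecourse(m, init = init, t_end = 100)
  t2 <- simulate_timecourse(ms, init = site_swap_state(init), t_end = 100)
  expect_lt(max(abs(t1$OP - t2$PO)), 1e-6)
  expect_lt(max(abs(t1$PO - t2$OP)), 1e-6)
  expect_lt(max(abs(t1$OO - t2$OO)), 1e-6)
  expect_lt(max(abs(t1$PP - t2$PP)), 1e-6)
})

test_that("trajectories restricted to the AM topology match the AM preset", {
  # AM as a TI restriction: PO-path rates zero, PO(0) = 0
  am <- preset("AM", nt = 4)
  ti_cut <- drop_paths(sw_model("TI", nt = 4), c("p1", "p2", "d1", "d2"))
  init <- c(OO = 3, PP = 1)
  t1 <- simulate_timecourse(am, init = init, t_end = 100)
  t2 <- simulate_timecourse(ti_cut, init = init, t_end = 100)
  expect_lt(max(abs(t1$OO - t2$OO)), 1e-7)
  expect_lt(max(abs(t1$PP - t2$PP)), 1e-7)
  expect_true(all(t2$PO == 0))
})

test_that("initial conditions are validated", {
  m <- preset("TI")
  expect_error(
    simulate_timecourse(m, init = c(OO = 3, OP = 3)),
    "conservation|OP"
  )
  expect_error(simulate_timecourse(m, init = c(XX = 1)), "named")
  expect_error(simulate_timecourse(build_rhs(m), t_end = 10), "tot")
})

test_that("trajectory TSV writer clamps integrator noise only", {
  traj <- simulate_timecourse(preset("TI", nt = 2), t_end = 5)
  traj$PO[2] <- -5e-10 # sub-tolerance undershoot
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(traj, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# model: TI", lines)))
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(tab$PO[2], 0)
  expect_equal(nrow(tab), nrow(traj))
})
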