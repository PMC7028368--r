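test_that("net displacement is the signed endpoint difference", {
  expect_equal(net_displacement(c(5, 5), c(0, 100)), 0)
  expect_equal(net_displacement(c(0, 3, 2.5), c(0, 50, 100)), 2.5)
  t <- 0:100
  expect_equal(net_displacement(0.05 * t, t), 5.0)
})

test_that("lateral maximal displacement is the position range", {
  expect_equal(lateral_max_displacement(c(2, 2, 2), c(0, 1, 2)), 0)
  expect_equal(
    lateral_max_displacement(c(0, 1.8, -0.2, 0.1), c(0, 30, 60, 100)), 2.0
  )
})

test_that("travel distance is the spatial path length", {
  expect_equal(travel_distance(c(1, 1, 1), c(0, 1, 2)), 0)
  expect_equal(travel_distance(c(0, 2, 0), c(0, 50, 100)), 4.0)
  # monotone trace: travel distance equals |ND|
  x <- cumsum(c(0, runif(20)))
  expect_equal(travel_distance(x), abs(net_displacement(x)))
})

test_that("segment velocities are signed slopes, one per segment", {
  expect_equal(segment_velocities(c(0, 10), c(0, 1)), 0.1)
  expect_equal(segment_velocities(c(0, 1, 2, 5), rep(3, 4)), c(0, 0, 0))
  expect_length(segment_velocities(0:9, rnorm(10)), 9)
})

test_that("maximal velocity is the largest absolute segment speed", {
  # velocities 0.1, -0.3, 0.2
  t <- c(0, 10, 20, 30)
  x <- c(0, 1, -2, 0)
  expect_equal(segment_velocities(t, x), c(0.1, -0.3, 0.2))
  expect_equal(max_velocity(t, x), 0.3)
  expect_equal(max_velocity(c(0, 4), c(1, 1)), 0)
})

test_that("maximal run length finds the longest constant-velocity block", {
  t <- 0:100
  expect_equal(max_run_length(t, 0.05 * t), 5.0) # one block = whole trace
  expect_equal(max_run_length(t, rep(2, 101)), 0) # no moving segment
  # velocities 0.1, 0.1, -0.1 over 10 s segments: first two form the run
  expect_equal(max_run_length(c(0, 10, 20, 30), c(0, 1, 2, 1),
    velocity_tol = 0.01), 2.0)
  # pause splits an otherwise constant run
  expect_equal(max_run_length(c(0, 10, 20, 30), c(0, 1, 1, 2),
    velocity_tol = 0.01), 1.0)
  # sign change always terminates a run even within tolerance
  expect_equal(max_run_length(c(0, 10, 20), c(0, 0.05, 0), velocity_tol = 1),
    0.05)
  expect_error(max_run_length(c(0, 1), c(0, 1), velocity_tol = -1),
    "velocity_tol")
})

test_that("five-way motion rules assign the published labels", {
  expect_equal(classify_motion(3, 3), "anterograde")
  expect_equal(classify_motion(0, 0.4), "stationary")
  expect_equal(classify_motion(-0.5, 2.3), "bidirectional")
  expect_equal(classify_motion(-2.1, 2.1), "retrograde")
  expect_equal(classify_motion(2, 2), "anterograde")   # ND boundary
  expect_equal(classify_motion(0, 1), "oscillatory")   # LMD 1 boundary
  expect_equal(classify_motion(0, 2), "bidirectional") # LMD 2 boundary
  expect_equal(classify_motion(1.99, 1.99), "oscillatory")
})

test_that("trace validation rejects malformed polylines", {
  expect_error(net_displacement(1), "at least 2")
  expect_error(net_displacement(c(0, 1), c(5, 5)), "strictly increasing")
  expect_error(segment_velocities(c(0, 0, 1), c(0, 1, 2)),
    "strictly increasing")
  expect_error(classify_motion(3, 1), "exceed")
})

test_that("metric inequalities hold on random traces", {
  paths <- random_trace_matrix(300, seed = 11)
  t <- seq_len(nrow(paths)) - 1
  for (j in seq_len(ncol(paths))) {
    x <- paths[, j]
    nd <- net_displacement(x, t)
    lmd <- lateral_max_displacement(x, t)
    trav <- travel_distance(x, t)
    run <- max_run_length(t, x)
    vmax <- max_velocity(t, x)
    expect_lte(abs(nd), lmd)
    expect_lte(lmd, trav)
    expect_lte(run, trav)
    expect_gte(vmax, trav / (max(t) - min(t)) - 1e-12)
  }
})

test_that("time reversal negates ND and preserves LMD, travel and max velocity", {
  paths <- random_trace_matrix(50, seed = 12)
  t <- seq_len(nrow(paths)) - 1
  for (j in seq_len(ncol(paths))) {
    x <- paths[, j]
    xr <- rev(x)
    expect_equal(net_displacement(xr, t), -net_displacement(x, t))
    expect_equal(lateral_max_displacement(xr, t),
      lateral_max_displacement(x, t))
    expect_equal(travel_distance(xr, t), travel_distance(x, t))
    expect_equal(max_velocity(t, xr), max_velocity(t, x))
  }
})

test_that("flipping soma_side swaps anterograde and retrograde only", {
  sim <- sim_trajectories(n_per_class = 5, seed = 21)
  traces <- sim$traces
  rec_left <- tibble::tibble(dendrite_id = "sim", soma_side = "left")
  rec_right <- tibble::tibble(dendrite_id = "sim", soma_side = "right")
  a <- classify_traces(traces, rec_left)
  b <- classify_traces(traces, rec_right)
  expect_equal(b$nd_um, -a$nd_um)
  expect_equal(b$lmd_um, a$lmd_um)
  swap <- c(
    stationary = "stationary", oscillatory = "oscillatory",
    bidirectional = "bidirectional",
    anterograde = "retrograde", retrograde = "anterograde"
  )
  expect_equal(as.character(b$motion_class),
    unname(swap[as.character(a$motion_class)]))
})

test_that("pixel coordinates are converted at ingest", {
  traces <- tibble::tibble(
    dendrite_id = "d1", granule_id = "g1",
    time_s = c(0, 50, 100), position_px = c(0, 20, 15)
  )
  rec <- tibble::tibble(dendrite_id = "d1", pixel_size_um = 0.2)
  out <- classify_traces(traces, rec)
  expect_equal(out$nd_um, 3.0)
  expect_equal(out$lmd_um, 4.0)
  expect_equal(as.character(out$motion_class), "anterograde")
})

test_that("granule densities partition the trace count", {
  cls <- tibble::tibble(
    dendrite_id = "d1",
    motion_class = c(rep("stationary", 5), "anterograde")
  )
  lengths <- tibble::tibble(dendrite_id = "d1", length_um = 60)
  dens <- granule_density(cls, lengths, scale = 10)
  expect_equal(dens$density[dens$motion_class == "stationary"], 5 / 60 * 10)
  expect_equal(dens$n[dens$motion_class == "motile"], 1)
  per_class <- dens[dens$motion_class != "motile", ]
  expect_equal(sum(per_class$n), nrow(cls))
  # empty dendrite gets all-zero rows
  dens0 <- granule_density(cls[0, ], lengths)
  expect_true(all(dens0$n == 0))
})
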