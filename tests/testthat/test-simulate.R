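test_that("generators are pure functions of their seed", {
  a <- sim_trajectories(n_per_class = 3, seed = 101)
  b <- sim_trajectories(n_per_class = 3, seed = 101)
  c <- sim_trajectories(n_per_class = 3, seed = 102)
  expect_identical(a, b)
  expect_false(identical(a$traces$position_um, c$traces$position_um))

  expect_identical(sim_spine_population(seed = 4), sim_spine_population(seed = 4))
  expect_identical(
    sim_longitudinal_spines(n_spines = 40, seed = 4),
    sim_longitudinal_spines(n_spines = 40, seed = 4)
  )
  expect_identical(sim_puncta(seed = 4), sim_puncta(seed = 4))
})

test_that("stationary jitter stays well inside the 1 um band", {
  sim <- sim_trajectories(n_per_class = 100, classes = "stationary",
    jitter_sd_um = 0.05, seed = 8)
  lmd <- classify_traces(sim$traces)$lmd_um
  # the range of 100 N(0, 0.05) samples concentrates near 0.25 um
  expect_lt(stats::quantile(lmd, 0.99), 1)
})

test_that("a pause-free anterograde run covers v x duration", {
  sim <- sim_trajectories(n_per_class = 1, classes = "anterograde",
    run_velocity_um_s = 0.1, pause_prob = 0, jitter_sd_um = 0, seed = 2)
  nd <- classify_traces(sim$traces)$nd_um
  expect_equal(nd, 0.1 * 99)
})

test_that("trajectory regimes land inside their class bands", {
  sim <- sim_trajectories(n_per_class = 30, seed = 13)
  m <- dplyr::inner_join(classify_traces(sim$traces), sim$truth,
    by = "granule_id")
  osc <- m[m$true_class == "oscillatory", ]
  expect_true(all(osc$lmd_um >= 1 & osc$lmd_um < 2))
  bi <- m[m$true_class == "bidirectional", ]
  expect_true(all(bi$lmd_um >= 2 & abs(bi$nd_um) < 2))
  expect_true(all(m$nd_um[m$true_class == "anterograde"] >= 2))
  expect_true(all(m$nd_um[m$true_class == "retrograde"] <= -2))
})

test_that("interior sampling makes spine labels perfectly recoverable", {
  pop <- sim_spine_population(n = 400, seed = 3)
  got <- classify_spine(pop$length_um, pop$head_um, pop$neck_um)
  expect_identical(got, pop$true_class)
  solo <- sim_spine_population(n = 50,
    proportions = c(mushroom = 1, stubby = 0, thin = 0, filopodium = 0),
    seed = 3)
  expect_true(all(solo$true_class == "mushroom"))
})

test_that("longitudinal generator honours its event probabilities by construction", {
  none <- sim_longitudinal_spines(n_spines = 80, p_eliminate = 0, seed = 5)
  expect_equal(none$truth$n_eliminated_w1, 0)
  expect_equal(sum(none$events$event == "eliminated_w1"), 0)

  all_ref <- sim_longitudinal_spines(n_spines = 120, p_eliminate = 0.3,
    reformation_fraction = 1, seed = 6)
  ref <- all_ref$events[all_ref$events$event == "reformed_w2", ]
  elim <- all_ref$events[all_ref$events$event == "eliminated_w1", ]
  expect_equal(sum(all_ref$events$event == "formed_w2"), 0)
  for (i in seq_len(nrow(ref))) {
    expect_lte(min(abs(ref$position_um[i] - elim$position_um)), 2.0)
  }
  # elimination counts behave binomially across seeds
  counts <- vapply(1:6, function(s) {
    sim_longitudinal_spines(n_spines = 200, p_eliminate = 0.1,
      seed = s)$truth$n_eliminated_w1
  }, numeric(1))
  expect_true(all(abs(counts - 20) <= 4 * sqrt(200 * 0.1 * 0.9)))
})

test_that("puncta generator concentrates mass near the soma under decay", {
  p <- sim_puncta(dendrite_length_um = 100, mean_count = 300,
    profile = "exponential", decay_per_um = 0.1, seed = 9)
  expect_gt(sum(p$positions_um < 50), sum(p$positions_um >= 50))
  u <- sim_puncta(dendrite_length_um = 100, mean_count = 300,
    profile = "uniform", seed = 9)
  # uniform profile: roughly balanced halves
  expect_lt(abs(sum(u$positions_um < 50) - length(u$positions_um) / 2),
    4 * sqrt(300 / 4))
  expect_true(all(p$positions_um >= 0 & p$positions_um <= 100))
})

test_that("rendered kymographs round-trip a constant-velocity line", {
  expect_equal(sum(render_kymograph(tibble::tibble(
    granule_id = character(), time_s = numeric(), position_um = numeric()
  ))), 0)

  v <- 0.1
  trace <- tibble::tibble(
    granule_id = "g1", time_s = c(0, 99), position_um = c(2, 2 + 99 * v)
  )
  img <- render_kymograph(trace, n_frames = 100, pixel_size_um = 0.2)
  px <- (seq_len(ncol(img)) - 0.5) * 0.2
  centroid <- apply(img, 1, function(r) sum(px * r) / sum(r))
  fit <- stats::lm(centroid ~ I(0:99))
  expect_lt(abs(unname(stats::coef(fit)[2]) - v), 0.2 / 1) # 1 px/frame

  still <- render_kymograph(
    tibble::tibble(granule_id = "g1", time_s = c(0, 99),
      position_um = c(5, 5)),
    n_frames = 100, pixel_size_um = 0.2
  )
  expect_equal(length(unique(apply(still, 1, which.max))), 1)
})
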