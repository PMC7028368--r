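# Independent oracles: scalar, literal transcriptions of the published
# inequality tables, deliberately coded apart from the package's vectorized
# implementations.

oracle_spine_class <- function(hn, ln) {
  if (hn >= 1.5) {
    "mushroom"
  } else if (hn < 1.2 && ln > 3) {
    "filopodium"
  } else if (hn <= 1 && ln <= 1) {
    "stubby"
  } else if (hn >= 1 && hn < 1.5 && ln >= 1.5 && ln <= 3) {
    "thin"
  } else {
    "unclassified"
  }
}

oracle_motion_class <- function(nd, lmd) {
  if (abs(nd) >= 2) {
    if (nd > 0) "anterograde" else "retrograde"
  } else if (lmd < 1) {
    "stationary"
  } else if (lmd < 2) {
    "oscillatory"
  } else {
    "bidirectional"
  }
}

# random free traces (drifting random walks at mixed scales) that populate
# all five motion classes
random_trace_matrix <- function(n_traces, n_frames = 100, seed = 1) {
  withr::with_seed(seed, {
    drift <- rnorm(n_traces, 0, 0.03)
    step_sd <- runif(n_traces, 0.005, 0.25)
    steps <- matrix(rnorm((n_frames - 1) * n_traces), n_frames - 1, n_traces)
    steps <- sweep(steps, 2, step_sd, `*`)
    steps <- sweep(steps, 2, drift, `+`)
    apply(rbind(0, steps), 2, cumsum)
  })
}

make_trace <- function(time_s, position_um, id = "g1") {
  tibble::tibble(granule_id = id, time_s = time_s, position_um = position_um)
}
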