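#' Simulate class-conditioned granule trajectories
#'
#' Generates kymograph-style traces with known motion-class labels, one
#' position per frame (default 1 frame/s for 100 s), for recovery testing of
#' the motion classifier:
#'
#' * **stationary** — Gaussian jitter about a fixed position.
#' * **oscillatory** — a reflected random walk confined to a band of width
#'   `oscillation_amplitude_um` (or a sinusoid with `oscillation_mode =
#'   "sinusoid"`), resampled until its noiseless range lies well inside the
#'   1-2 um oscillatory band and its endpoints nearly coincide.
#' * **bidirectional** — a velocity sign-switching walk (speed
#'   `run_velocity_um_s`, per-frame switch probability `switch_prob`),
#'   resampled until the noiseless range is comfortably above 2 um while the
#'   endpoints stay within 2 um of each other.
#' * **anterograde / retrograde** — constant-velocity runs at
#'   `run_velocity_um_s` interrupted by pauses (per-frame probability
#'   `pause_prob`), signed away from / toward the soma.
#'
#' Moving-class paths additionally carry measurement jitter of
#' `jitter_sd_um`. Rejection margins are applied to the noiseless path, so
#' ground-truth labels do not depend on the realized noise. All randomness
#' is scoped to `seed`; equal seeds give byte-identical output.
#'
#' @param n_per_class Traces per class (single number or named vector over
#'   the five classes).
#' @param classes Which classes to generate.
#' @param n_frames Frames per trace (default 100).
#' @param frame_interval_s Seconds between frames (default 1).
#' @param jitter_sd_um Measurement jitter SD in um (default 0.05).
#' @param oscillation_amplitude_um Width of the oscillatory band (default 1.5).
#' @param oscillation_mode `"reflected_walk"` (default) or `"sinusoid"`.
#' @param run_velocity_um_s Run speed for directed/bidirectional classes.
#' @param pause_prob Per-frame pause probability for directed runs.
#' @param switch_prob Per-frame direction-switch probability (bidirectional).
#' @param seed Integer RNG seed.
#' @return List with `traces` (long tibble `dendrite_id`, `granule_id`,
#'   `time_s`, `position_um`) and `truth` (tibble `granule_id`,
#'   `true_class`).
#' @examples
#' sim <- sim_trajectories(n_per_class = 2, seed = 1)
#' table(sim$truth$true_class)
#' @export
sim_trajectories <- function(n_per_class = 10,
                             classes = c("stationary", "oscillatory",
                               "bidirectional", "anterograde", "retrograde"),
                             n_frames = 100, frame_interval_s = 1,
                             jitter_sd_um = 0.05,
                             oscillation_amplitude_um = 1.5,
                             oscillation_mode = c("reflected_walk", "sinusoid"),
                             run_velocity_um_s = 0.08,
                             pause_prob = 0.2, switch_prob = 0.1,
                             seed = 1) {
  oscillation_mode <- match.arg(oscillation_mode)
  classes <- match.arg(classes, several.ok = TRUE)
  assert_positive(n_frames, "n_frames")
  assert_positive(frame_interval_s, "frame_interval_s")
  assert_non_negative(jitter_sd_um, "jitter_sd_um")
  assert_positive(oscillation_amplitude_um, "oscillation_amplitude_um")
  assert_positive(run_velocity_um_s, "run_velocity_um_s")
  assert_probability(pause_prob, "pause_prob")
  assert_probability(switch_prob, "switch_prob")
  if (oscillation_amplitude_um >= 2) {
    abort("`oscillation_amplitude_um` must stay below the 2 um bidirectional bound.")
  }
  if (is.null(names(n_per_class))) {
    n_per_class <- setNames(rep_len(n_per_class, length(classes)), classes)
  }

  duration <- (n_frames - 1) * frame_interval_s
  time_s <- seq(0, duration, by = frame_interval_s)

  # noiseless path per class; rejection keeps the path well inside its band
  sample_path <- function(class) {
    for (attempt in seq_len(1000)) {
      path <- switch(class,
        stationary = rep(0, n_frames),
        oscillatory = if (oscillation_mode == "sinusoid") {
          oscillation_amplitude_um / 2 *
            (1 - cos(2 * pi * time_s / (duration / 3)))
        } else {
          reflected_walk(n_frames, step_sd = 0.15,
            upper = oscillation_amplitude_um)
        },
        bidirectional = switching_walk(n_frames, frame_interval_s,
          run_velocity_um_s, switch_prob),
        anterograde = paused_run(n_frames, frame_interval_s,
          run_velocity_um_s, pause_prob),
        retrograde = -paused_run(n_frames, frame_interval_s,
          run_velocity_um_s, pause_prob)
      )
      rng <- max(path) - min(path)
      nd <- path[n_frames] - path[1]
      ok <- switch(class,
        stationary = TRUE,
        oscillatory = rng >= 1.2 && rng <= 1.7 && abs(nd) <= 0.5,
        bidirectional = rng >= 2.3 && abs(nd) <= 1.4,
        anterograde = nd >= 2.5,
        retrograde = nd <= -2.5
      )
      if (ok) {
        return(path)
      }
    }
    abort(sprintf(
      "Could not generate an in-band '%s' path; regime parameters contradict the class bounds.",
      class
    ))
  }

  withr::with_seed(seed, {
    pieces <- list()
    truth <- list()
    k <- 0
    for (class in classes) {
      for (i in seq_len(n_per_class[[class]])) {
        k <- k + 1
        id <- sprintf("g%04d", k)
        pos <- sample_path(class) + runif(1, 0, 20) +
          rnorm(n_frames, 0, jitter_sd_um)
        pieces[[k]] <- tibble::tibble(
          dendrite_id = "sim", granule_id = id,
          time_s = time_s, position_um = pos
        )
        truth[[k]] <- tibble::tibble(granule_id = id, true_class = class)
      }
    }
    list(
      traces = dplyr::bind_rows(pieces),
      truth = dplyr::bind_rows(truth)
    )
  })
}

# random walk reflected into [0, upper]
reflected_walk <- function(n, step_sd, upper) {
  x <- cumsum(c(runif(1, 0, upper), rnorm(n - 1, 0, step_sd)))
  # fold into [0, 2*upper] then reflect the top half down
  x <- x %% (2 * upper)
  ifelse(x > upper, 2 * upper - x, x)
}

# +/- v walk with per-frame direction switching
switching_walk <- function(n, dt, v, switch_prob) {
  dir <- cumprod(c(
    sample(c(-1, 1), 1),
    ifelse(rbinom(n - 2, 1, switch_prob) == 1, -1, 1)
  ))
  c(0, cumsum(dir * v * dt))
}

# constant-velocity run with pauses
paused_run <- function(n, dt, v, pause_prob) {
  moving <- rbinom(n - 1, 1, 1 - pause_prob)
  c(0, cumsum(moving * v * dt))
}

#' Simulate a class-labelled spine measurement population
#'
#' Samples (L, H, N) geometries uniformly inside each morphological class's
#' ratio region, strictly interior to the decision boundaries, so
#' [classify_spine()] recovers the generating label for every draw. Neck
#' widths are drawn uniformly from `neck_range_um` and head width / length
#' follow from the sampled H/N and L/N ratios.
#'
#' @param n Total number of spines.
#' @param proportions Named numeric vector of class proportions over
#'   mushroom/stubby/thin/filopodium (need not sum to 1; normalized).
#' @param neck_range_um Range of neck widths in um.
#' @param seed Integer RNG seed.
#' @return Tibble `spine_id`, `neuron_id`, `dendrite_id`, `length_um`,
#'   `head_um`, `neck_um`, `true_class`.
#' @export
sim_spine_population <- function(n = 100,
    proportions = c(mushroom = 0.4, stubby = 0.2, thin = 0.3,
      filopodium = 0.1),
    neck_range_um = c(0.2, 0.8), seed = 1) {
  assert_positive(n, "n")
  assert_non_negative(proportions, "proportions")
  if (sum(proportions) <= 0) {
    abort("`proportions` must have positive mass.")
  }
  classes <- c("mushroom", "stubby", "thin", "filopodium")
  proportions <- proportions[classes]
  if (anyNA(proportions)) {
    abort("`proportions` must be named over mushroom/stubby/thin/filopodium.")
  }
  # ratio boxes strictly interior to the printed class regions
  boxes <- list(
    mushroom   = list(hn = c(1.60, 3.00), ln = c(0.50, 3.00)),
    stubby     = list(hn = c(0.40, 0.95), ln = c(0.30, 0.95)),
    thin       = list(hn = c(1.05, 1.45), ln = c(1.60, 2.90)),
    filopodium = list(hn = c(0.40, 1.10), ln = c(3.20, 6.00))
  )
  withr::with_seed(seed, {
    true_class <- sample(classes, n, replace = TRUE,
      prob = proportions / sum(proportions))
    hn <- ln <- numeric(n)
    for (cl in classes) {
      sel <- true_class == cl
      hn[sel] <- runif(sum(sel), boxes[[cl]]$hn[1], boxes[[cl]]$hn[2])
      ln[sel] <- runif(sum(sel), boxes[[cl]]$ln[1], boxes[[cl]]$ln[2])
    }
    neck <- runif(n, neck_range_um[1], neck_range_um[2])
    tibble::tibble(
      spine_id = sprintf("sp%04d", seq_len(n)),
      neuron_id = "sim", dendrite_id = "sim",
      length_um = ln * neck, head_um = hn * neck, neck_um = neck,
      true_class = true_class
    )
  })
}

#' Simulate a three-session longitudinal spine map
#'
#' Builds a dendrite observed at three imaging days (0/2/7 by default) with
#' known turnover events, for parameter-recovery testing of
#' [summarize_turnover()]:
#'
#' * Day-0 spines sit on a regular grid with `spacing_um` between neighbors
#'   (spacing is chosen much larger than the downstream match radius so the
#'   correspondence is unambiguous).
#' * Each day-0 spine is eliminated in window 1 with probability
#'   `p_eliminate`; new window-1 spines appear at gap midpoints with
#'   per-spine probability `p_form_w1`.
#' * Window-2 formations (probability `p_form_w2` per day-2 spine) are split:
#'   a fraction `reformation_fraction` re-forms within `proximity_um` of a
#'   distinct window-1 eliminated position (0.2-1.5 um offset); the rest
#'   appear at free gap midpoints, which lie farther than `proximity_um`
#'   from every eliminated position.
#' * Every observed arc position carries remeasurement noise
#'   (`remeasure_sd_um`); all day-2 spines persist to day 7.
#'
#' @param n_spines Day-0 spine count.
#' @param spacing_um Grid spacing between day-0 spines (um).
#' @param p_eliminate Window-1 per-spine elimination probability.
#' @param p_form_w1,p_form_w2 Per-spine formation probabilities for the two
#'   windows.
#' @param reformation_fraction Fraction of window-2 formations placed near
#'   eliminated positions.
#' @param proximity_um Re-formation proximity used for placement (um).
#' @param remeasure_sd_um SD of per-session position noise (um).
#' @param days Imaging days (length 3).
#' @param mouse_id,dendrite_id Identifiers stamped on the observations.
#' @param seed Integer RNG seed.
#' @return List with `observations` (protrusion table across the three
#'   days), `events` (ledger tibble `event`, `protrusion_id`,
#'   `position_um`, `ancestor_id`) and `truth` (named list of event counts
#'   and the generating parameters).
#' @export
sim_longitudinal_spines <- function(n_spines = 200, spacing_um = 5,
    p_eliminate = 0.10, p_form_w1 = 0.05, p_form_w2 = 0.05,
    reformation_fraction = 0.5,
    proximity_um = default_thresholds()$proximity_um,
    remeasure_sd_um = 0.05, days = c(0, 2, 7),
    mouse_id = "m1", dendrite_id = "d1", seed = 1) {
  assert_positive(n_spines, "n_spines")
  assert_positive(spacing_um, "spacing_um")
  assert_probability(p_eliminate, "p_eliminate")
  assert_probability(p_form_w1, "p_form_w1")
  assert_probability(p_form_w2, "p_form_w2")
  assert_probability(reformation_fraction, "reformation_fraction")
  assert_positive(proximity_um, "proximity_um")
  assert_non_negative(remeasure_sd_um, "remeasure_sd_um")
  if (length(days) != 3) {
    abort("`days` must have length 3.")
  }
  max_offset <- min(0.75 * proximity_um, spacing_um / 2 - 1)
  if (max_offset <= 0.2) {
    abort("`spacing_um` too small relative to `proximity_um` for unambiguous placement.")
  }

  withr::with_seed(seed, {
    grid <- (seq_len(n_spines) - 0.5) * spacing_um
    ids0 <- sprintf("s%04d", seq_len(n_spines))
    eliminated <- rbinom(n_spines, 1, p_eliminate) == 1

    midpoints <- seq_len(n_spines - 1) * spacing_um
    n_form1 <- rbinom(1, n_spines, p_form_w1)
    gaps1 <- sample(n_spines - 1, n_form1)
    ids_f1 <- sprintf("f1_%03d", seq_len(n_form1))

    day2_pos <- c(grid[!eliminated], midpoints[gaps1])
    day2_ids <- c(ids0[!eliminated], ids_f1)
    n_day2 <- length(day2_pos)

    n_form2 <- rbinom(1, n_day2, p_form_w2)
    n_reform <- min(rbinom(1, n_form2, reformation_fraction), sum(eliminated))
    elim_idx <- sample(which(eliminated), n_reform)
    offsets <- runif(n_reform, 0.2, max_offset) *
      sample(c(-1, 1), n_reform, replace = TRUE)
    reform_pos <- grid[elim_idx] + offsets
    ids_r2 <- sprintf("r2_%03d", seq_len(n_reform))

    n_new2 <- n_form2 - n_reform
    free_gaps <- setdiff(seq_len(n_spines - 1), gaps1)
    gaps2 <- sample(free_gaps, n_new2)
    ids_n2 <- sprintf("f2_%03d", seq_len(n_new2))

    day7_pos <- c(day2_pos, reform_pos, midpoints[gaps2])
    day7_ids <- c(day2_ids, ids_r2, ids_n2)

    observe <- function(ids, pos, day) {
      tibble::tibble(
        mouse_id = mouse_id, dendrite_id = dendrite_id, day = day,
        protrusion_id = ids,
        arc_position_um = pos + rnorm(length(pos), 0, remeasure_sd_um),
        length_um = 1.0, head_um = 0.6, neck_um = 0.4,
        shaft_diameter_um = 1.0
      )
    }
    observations <- dplyr::bind_rows(
      observe(ids0, grid, days[1]),
      observe(day2_ids, day2_pos, days[2]),
      observe(day7_ids, day7_pos, days[3])
    )
    events <- dplyr::bind_rows(
      tibble::tibble(event = "eliminated_w1",
        protrusion_id = ids0[eliminated],
        position_um = grid[eliminated], ancestor_id = NA_character_),
      tibble::tibble(event = "formed_w1", protrusion_id = ids_f1,
        position_um = midpoints[gaps1], ancestor_id = NA_character_),
      tibble::tibble(event = "reformed_w2", protrusion_id = ids_r2,
        position_um = reform_pos, ancestor_id = ids0[elim_idx]),
      tibble::tibble(event = "formed_w2", protrusion_id = ids_n2,
        position_um = midpoints[gaps2], ancestor_id = NA_character_)
    )
    truth <- list(
      n_day0 = n_spines, n_day2 = n_day2, n_day7 = length(day7_pos),
      n_eliminated_w1 = sum(eliminated), n_formed_w1 = n_form1,
      n_formed_w2 = n_form2, n_reformed_w2 = n_reform,
      params = list(p_eliminate = p_eliminate, p_form_w1 = p_form_w1,
        p_form_w2 = p_form_w2, reformation_fraction = reformation_fraction,
        proximity_um = proximity_um, spacing_um = spacing_um)
    )
    list(observations = observations, events = events, truth = truth)
  })
}

#' Simulate puncta positions along a dendrite
#'
#' Draws a Poisson number of puncta (`mean_count` expected) and places them
#' along the dendrite either uniformly or with an exponential distance decay
#' of rate `decay_per_um` from the cell body (an inhomogeneous Poisson
#' process with intensity proportional to `exp(-decay_per_um * x)`,
#' truncated at the dendrite tip).
#'
#' @param dendrite_length_um Dendrite length in um.
#' @param mean_count Expected puncta count.
#' @param profile `"exponential"` (default) or `"uniform"`.
#' @param decay_per_um Exponential decay rate (ignored for uniform).
#' @param seed Integer RNG seed.
#' @return List `positions_um`, `dendrite_length_um`, `profile`,
#'   `decay_per_um`.
#' @export
sim_puncta <- function(dendrite_length_um = 60, mean_count = 30,
                       profile = c("exponential", "uniform"),
                       decay_per_um = 0.05, seed = 1) {
  profile <- match.arg(profile)
  assert_positive(dendrite_length_um, "dendrite_length_um")
  assert_non_negative(mean_count, "mean_count")
  assert_non_negative(decay_per_um, "decay_per_um")
  withr::with_seed(seed, {
    n <- rpois(1, mean_count)
    u <- runif(n)
    positions <- if (profile == "uniform" || decay_per_um == 0) {
      u * dendrite_length_um
    } else {
      # inverse CDF of the truncated exponential
      -log(1 - u * (1 - exp(-decay_per_um * dendrite_length_um))) / decay_per_um
    }
    list(
      positions_um = positions, dendrite_length_um = dendrite_length_um,
      profile = profile, decay_per_um = decay_per_um
    )
  })
}

#' Rasterize traces into a synthetic kymograph image
#'
#' Renders traces as bright lines on a position x time raster (rows =
#' frames, columns = pixels along the dendrite) with a Gaussian intensity
#' profile across each line, for visualization and round-trip tests of the
#' trace metrics. Positions outside the raster are clipped with a warning.
#'
#' @param traces Long tibble `granule_id`, `time_s`, `position_um`.
#' @param n_frames Number of rows (frames).
#' @param frame_interval_s Seconds per frame.
#' @param pixel_size_um Pixel size in um.
#' @param width_um Raster width in um (default spans the traces).
#' @param line_sd_px Gaussian line profile SD in pixels.
#' @return Numeric matrix `n_frames` x `width_px`.
#' @export
render_kymograph <- function(traces, n_frames = 100, frame_interval_s = 1,
                             pixel_size_um = 0.2, width_um = NULL,
                             line_sd_px = 1) {
  assert_positive(pixel_size_um, "pixel_size_um")
  if (is.null(width_um)) {
    width_um <- if (nrow(traces) > 0) max(traces$position_um) + 2 else 10
  }
  width_px <- max(2L, ceiling(width_um / pixel_size_um))
  img <- matrix(0, nrow = n_frames, ncol = width_px)
  if (nrow(traces) == 0) {
    return(img)
  }
  assert_columns(traces, c("granule_id", "time_s", "position_um"), "traces")
  frame_times <- (seq_len(n_frames) - 1) * frame_interval_s
  px_centers <- (seq_len(width_px) - 0.5) * pixel_size_um
  clipped <- FALSE
  for (df in split(traces, traces$granule_id)) {
    pos <- stats::approx(df$time_s, df$position_um, xout = frame_times,
      rule = 1)$y
    for (r in which(!is.na(pos))) {
      px <- pos[r] / pixel_size_um
      if (px < 0 || px > width_px) {
        clipped <- TRUE
        next
      }
      img[r, ] <- img[r, ] +
        exp(-((px_centers / pixel_size_um - px)^2) / (2 * line_sd_px^2))
    }
  }
  if (clipped) {
    warn("Some trace points fall outside the raster and were clipped.")
  }
  img
}
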