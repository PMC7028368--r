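#' Trajectory metrics for kymograph-derived granule traces
#'
#' A granule trace is an ordered polyline of (time, position) points read off
#' a kymograph, with position measured in micrometres along the dendrite and
#' oriented so that positive displacement points away from the soma. The
#' scalar metrics below are the building blocks of motion classification:
#'
#' * `net_displacement()` (ND): last position minus first position, signed.
#' * `lateral_max_displacement()` (LMD): range of positions visited,
#'   `max(position) - min(position)`, i.e. the distance between the most
#'   proximal and most distal points of the trace.
#' * `travel_distance()`: total spatial path length, the sum of
#'   `|delta position|` over consecutive points. A granule that moves out and
#'   back accumulates distance both ways.
#' * `segment_velocities()`: signed velocity of each polyline segment,
#'   `delta position / delta time`.
#' * `max_velocity()`: maximum of `|segment velocity|`.
#' * `max_run_length()`: largest `|position change|` over a maximal block of
#'   consecutive segments moving in one direction at (near-)constant
#'   velocity; see Details.
#'
#' For every trace `|ND| <= LMD <= travel distance`,
#' `max run length <= travel distance`, and
#' `max velocity >= travel distance / duration`.
#'
#' @details
#' Manual polyline traces are piecewise-constant in velocity, so a "period of
#' movement with constant velocity" is detected as a maximal block of
#' consecutive segments whose velocities share one sign and lie within
#' `velocity_tol` (um/s, absolute) of the block's first segment velocity.
#' Zero-velocity (pause) segments terminate runs. The default tolerance of
#' 0.02 um/s merges only near-identical segments.
#'
#' @param time_s Numeric vector of time stamps in seconds, strictly
#'   increasing, length >= 2.
#' @param position_um Numeric vector of positions in micrometres, same
#'   length as `time_s`.
#' @param velocity_tol Absolute tolerance in um/s for run detection.
#' @return A single numeric value (`segment_velocities()` returns one value
#'   per segment).
#' @examples
#' t <- c(0, 50, 100)
#' x <- c(0, 2, 0)
#' net_displacement(x)          # 0
#' lateral_max_displacement(x)  # 2
#' travel_distance(x)           # 4
#' max_velocity(t, x)           # 0.04
#' @name trace-metrics
NULL

validate_trace <- function(time_s, position_um) {
  if (length(time_s) != length(position_um)) {
    abort("`time_s` and `position_um` must have the same length.")
  }
  if (length(time_s) < 2) {
    abort("A trace needs at least 2 points.")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(position_um))) {
    abort("Trace coordinates must be finite.")
  }
  if (any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  invisible(NULL)
}

#' @rdname trace-metrics
#' @export
net_displacement <- function(position_um, time_s = seq_along(position_um) - 1) {
  validate_trace(time_s, position_um)
  position_um[length(position_um)] - position_um[1]
}

#' @rdname trace-metrics
#' @export
lateral_max_displacement <- function(position_um,
                                     time_s = seq_along(position_um) - 1) {
  validate_trace(time_s, position_um)
  max(position_um) - min(position_um)
}

#' @rdname trace-metrics
#' @export
travel_distance <- function(position_um, time_s = seq_along(position_um) - 1) {
  validate_trace(time_s, position_um)
  sum(abs(diff(position_um)))
}

#' @rdname trace-metrics
#' @export
segment_velocities <- function(time_s, position_um) {
  validate_trace(time_s, position_um)
  diff(position_um) / diff(time_s)
}

#' @rdname trace-metrics
#' @export
max_velocity <- function(time_s, position_um) {
  max(abs(segment_velocities(time_s, position_um)))
}

#' @rdname trace-metrics
#' @export
max_run_length <- function(time_s, position_um,
                           velocity_tol = default_thresholds()$run_velocity_tol_um_s) {
  assert_non_negative(velocity_tol, "velocity_tol")
  v <- segment_velocities(time_s, position_um)
  moving <- v != 0
  if (!any(moving)) {
    return(0)
  }
  n_seg <- length(v)
  best <- 0
  i <- 1L
  while (i <= n_seg) {
    if (!moving[i]) {
      i <- i + 1L
      next
    }
    v0 <- v[i]
    j <- i
    while (j < n_seg && moving[j + 1L] &&
      sign(v[j + 1L]) == sign(v0) &&
      abs(v[j + 1L] - v0) <= velocity_tol) {
      j <- j + 1L
    }
    best <- max(best, abs(position_um[j + 1L] - position_um[i]))
    i <- j + 1L
  }
  best
}

#' Five-way motion classification of granule traces
#'
#' Classifies a trace from its net displacement (ND, signed, positive =
#' anterograde, away from the soma) and lateral maximal displacement (LMD):
#' traces with `|ND| >= 2` um are unidirectional — **anterograde** when
#' ND > 0 and **retrograde** when ND < 0. Among the rest, LMD < 1 um is
#' **stationary**, 1 <= LMD < 2 um is **oscillatory**, and LMD >= 2 um is
#' **bidirectional**. Every trace receives exactly one label.
#'
#' @param nd_um Numeric vector of net displacements in um (signed).
#' @param lmd_um Numeric vector of lateral maximal displacements in um.
#' @param thresholds Named list of cutoffs, see [default_thresholds()].
#' @return Character vector of labels in `c("stationary", "oscillatory",
#'   "bidirectional", "anterograde", "retrograde")`.
#' @examples
#' classify_motion(nd_um = 3, lmd_um = 3)      # anterograde
#' classify_motion(nd_um = -0.5, lmd_um = 2.3) # bidirectional
#' @export
classify_motion <- function(nd_um, lmd_um, thresholds = default_thresholds()) {
  if (length(nd_um) != length(lmd_um)) {
    abort("`nd_um` and `lmd_um` must have the same length.")
  }
  if (any(abs(nd_um) > lmd_um + 1e-9)) {
    abort("|nd_um| cannot exceed lmd_um.")
  }
  th <- thresholds
  uni <- abs(nd_um) >= th$nd_unidirectional_um
  label <- character(length(nd_um))
  label[uni & nd_um > 0] <- "anterograde"
  label[uni & nd_um < 0] <- "retrograde"
  label[!uni & lmd_um < th$lmd_oscillatory_um] <- "stationary"
  label[!uni & lmd_um >= th$lmd_oscillatory_um &
    lmd_um < th$lmd_bidirectional_um] <- "oscillatory"
  label[!uni & lmd_um >= th$lmd_bidirectional_um] <- "bidirectional"
  label
}

motion_class_levels <- function() {
  c("stationary", "oscillatory", "bidirectional", "anterograde", "retrograde")
}

#' Classify a long-format table of granule traces
#'
#' The workhorse of kymograph analysis: takes every traced granule, computes
#' ND, LMD, travel distance, maximal run length and maximal velocity, and
#' assigns the five-way motion label. Positions may arrive in pixels (scaled
#' by each recording's `pixel_size_um`) and in either dendrite orientation
#' (`soma_side = "right"` flips the axis so positive always points distal).
#'
#' @param traces Data frame with columns `granule_id`, `time_s`, `position_um`
#'   (or `position_px` when `recordings` carries `pixel_size_um`), optionally
#'   `dendrite_id`.
#' @param recordings Optional data frame keyed by `dendrite_id` with any of
#'   `pixel_size_um` (px -> um conversion) and `soma_side` (`"left"` or
#'   `"right"`; `"right"` negates positions so positive = away from soma).
#' @param velocity_tol Run-detection tolerance in um/s.
#' @param thresholds Named list of cutoffs, see [default_thresholds()].
#' @return One row per granule: `granule_id` (and `dendrite_id`), `n_points`,
#'   `duration_s`, `nd_um`, `lmd_um`, `travel_um`, `max_run_um`,
#'   `max_velocity_um_s`, `motion_class` (factor).
#' @examples
#' traces <- tibble::tibble(
#'   granule_id = rep("g1", 3), time_s = c(0, 50, 100),
#'   position_um = c(0, 3, 2.5)
#' )
#' classify_traces(traces)
#' @export
classify_traces <- function(traces, recordings = NULL,
                            velocity_tol = default_thresholds()$run_velocity_tol_um_s,
                            thresholds = default_thresholds()) {
  assert_columns(traces, c("granule_id", "time_s"), "traces")
  traces <- tibble::as_tibble(traces)
  if (!"dendrite_id" %in% names(traces)) {
    traces$dendrite_id <- "dendrite"
  }

  if (!is.null(recordings)) {
    assert_columns(recordings, "dendrite_id", "recordings")
    keep <- intersect(c("dendrite_id", "pixel_size_um", "soma_side"),
      names(recordings))
    traces <- dplyr::left_join(traces, recordings[keep], by = "dendrite_id")
    if ("pixel_size_um" %in% names(traces)) {
      if (!"position_px" %in% names(traces)) {
        abort("`recordings` has pixel_size_um but `traces` lacks position_px.")
      }
      traces$position_um <- traces$position_px * traces$pixel_size_um
    }
    if ("soma_side" %in% names(traces)) {
      flip <- traces$soma_side %in% "right"
      traces$position_um[flip] <- -traces$position_um[flip]
    }
  }
  assert_columns(traces, "position_um", "traces")

  traces <- dplyr::arrange(traces, .data$granule_id, .data$time_s)
  per_granule <- function(df) {
    t <- df$time_s
    x <- df$position_um
    validate_trace(t, x)
    tibble::tibble(
      dendrite_id = df$dendrite_id[1],
      n_points = length(t),
      duration_s = t[length(t)] - t[1],
      nd_um = net_displacement(x, t),
      lmd_um = lateral_max_displacement(x, t),
      travel_um = travel_distance(x, t),
      max_run_um = max_run_length(t, x, velocity_tol),
      max_velocity_um_s = max_velocity(t, x)
    )
  }
  out <- dplyr::group_modify(
    dplyr::group_by(traces, .data$granule_id),
    ~ per_granule(.x)
  )
  out <- dplyr::ungroup(out)
  out$motion_class <- factor(
    classify_motion(out$nd_um, out$lmd_um, thresholds),
    levels = motion_class_levels()
  )
  dplyr::select(
    out, "dendrite_id", "granule_id", "n_points", "duration_s",
    "nd_um", "lmd_um", "travel_um", "max_run_um", "max_velocity_um_s",
    "motion_class"
  )
}

#' Granule counts and densities per motion class
#'
#' @param classified Output of [classify_traces()] (needs `dendrite_id` and
#'   `motion_class`).
#' @param dendrite_lengths Data frame `dendrite_id`, `length_um`.
#' @param scale Reporting scale (granules per `scale` um, default 10).
#' @return One row per dendrite x class plus a `"motile"` aggregate row (all
#'   classes except stationary): `dendrite_id`, `motion_class`, `n`,
#'   `density`.
#' @export
granule_density <- function(classified, dendrite_lengths, scale = 10) {
  assert_columns(classified, c("dendrite_id", "motion_class"), "classified")
  assert_columns(dendrite_lengths, c("dendrite_id", "length_um"),
    "dendrite_lengths")
  assert_positive(dendrite_lengths$length_um, "dendrite_lengths$length_um")
  assert_positive(scale, "scale")

  levels_out <- c(motion_class_levels(), "motile")
  grid <- tidyr::expand_grid(
    dendrite_id = dendrite_lengths$dendrite_id,
    motion_class = factor(levels_out, levels = levels_out)
  )
  counts <- dplyr::count(
    dplyr::mutate(classified,
      motion_class = factor(as.character(.data$motion_class),
        levels = levels_out)),
    .data$dendrite_id, .data$motion_class, name = "n"
  )
  motile <- dplyr::count(
    dplyr::filter(classified, .data$motion_class != "stationary"),
    .data$dendrite_id, name = "n"
  )
  if (nrow(motile) > 0) {
    motile$motion_class <- factor("motile", levels = levels_out)
    counts <- dplyr::bind_rows(counts, motile)
  }
  out <- dplyr::left_join(grid, counts, by = c("dendrite_id", "motion_class"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::left_join(out, dendrite_lengths, by = "dendrite_id")
  out$density <- out$n / out$length_um * scale
  dplyr::select(out, "dendrite_id", "motion_class", "n", "density")
}
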