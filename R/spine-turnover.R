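#' Eligibility filter for in vivo protrusions
#'
#' Transcranial two-photon quantification only scores protrusions whose
#' length exceeds one third of the local dendritic shaft diameter; shorter
#' bumps are not counted. The inequality is strict: a protrusion exactly at
#' one third is dropped.
#'
#' @param obs Data frame with columns `length_um` and `shaft_diameter_um`.
#' @param shaft_fraction Minimum length as a fraction of shaft diameter.
#' @return The eligible rows, as a tibble.
#' @export
filter_eligible_protrusions <- function(obs,
    shaft_fraction = default_thresholds()$protrusion_shaft_fraction) {
  obs <- tibble::as_tibble(obs)
  if (nrow(obs) == 0) {
    return(obs)
  }
  assert_columns(obs, c("length_um", "shaft_diameter_um"), "obs")
  if (any(is.na(obs$shaft_diameter_um))) {
    abort("`shaft_diameter_um` has missing values.")
  }
  assert_positive(obs$shaft_diameter_um, "shaft_diameter_um")
  dplyr::filter(obs, .data$length_um > .data$shaft_diameter_um * shaft_fraction)
}

#' Spine vs filopodium call for in vivo protrusions
#'
#' In longitudinal imaging, filopodia are long thin protrusions identified by
#' head/neck diameter ratio < 1.2 together with length/neck ratio > 3;
#' everything else is a spine. Filopodia are also generally longer than twice
#' the average spine length; because that criterion is a tendency rather
#' than a rule, it is applied only when `require_length_criterion = TRUE`
#' and a cohort mean spine length is supplied.
#'
#' @param obs Data frame with `length_um`, `head_um`, `neck_um`.
#' @param mean_spine_length_um Cohort average spine length in um (required
#'   when `require_length_criterion` is `TRUE`).
#' @param require_length_criterion Also require
#'   `length_um > 2 * mean_spine_length_um` for a filopodium call.
#' @return The input tibble with a `kind` column, `"spine"` or
#'   `"filopodium"`.
#' @export
classify_protrusions_invivo <- function(obs, mean_spine_length_um = NULL,
                                        require_length_criterion = FALSE) {
  obs <- tibble::as_tibble(obs)
  if (nrow(obs) == 0) {
    obs$kind <- character()
    return(obs)
  }
  assert_columns(obs, c("length_um", "head_um", "neck_um"), "obs")
  assert_positive(obs$neck_um, "neck_um")
  th <- default_thresholds()
  filo <- obs$head_um / obs$neck_um < th$filopodium_hn_max &
    obs$length_um / obs$neck_um > th$filopodium_ln_min
  if (require_length_criterion) {
    if (is.null(mean_spine_length_um)) {
      abort("`mean_spine_length_um` is required when the length criterion is on.")
    }
    assert_positive(mean_spine_length_um, "mean_spine_length_um")
    filo <- filo &
      obs$length_um > th$invivo_filopodium_length_factor * mean_spine_length_um
  }
  obs$kind <- ifelse(filo, "filopodium", "spine")
  obs
}

#' Match protrusions between two imaging sessions by arc position
#'
#' Longitudinal turnover analysis needs a correspondence between the spines
#' seen at two time points on the same dendritic segment. Matching is greedy
#' nearest-neighbor on arc position: all cross-view pairs within
#' `match_radius_um` are sorted by distance and accepted one-to-one in that
#' order. The procedure is deterministic, symmetric in the two views up to
#' transposition, and `match(A, A)` is the identity.
#'
#' @param view_a,view_b Data frames with columns `protrusion_id` and
#'   `arc_position_um`, one row per protrusion, for the earlier and later
#'   session.
#' @param match_radius_um Maximum arc distance for a match (um).
#' @return A list with elements `matches` (tibble `id_a`, `id_b`,
#'   `distance_um`), `unmatched_a` and `unmatched_b` (character vectors of
#'   protrusion ids).
#' @export
match_protrusions <- function(view_a, view_b,
    match_radius_um = default_thresholds()$match_radius_um) {
  assert_non_negative(match_radius_um, "match_radius_um")
  for (nm in c("view_a", "view_b")) {
    v <- get(nm)
    if (nrow(v) > 0) {
      assert_columns(v, c("protrusion_id", "arc_position_um"), nm)
      if (anyDuplicated(v$protrusion_id)) {
        abort(sprintf("Duplicate protrusion_id within `%s`.", nm))
      }
    }
  }
  empty <- tibble::tibble(
    id_a = character(), id_b = character(), distance_um = numeric()
  )
  if (nrow(view_a) == 0 || nrow(view_b) == 0) {
    return(list(
      matches = empty,
      unmatched_a = if (nrow(view_a)) as.character(view_a$protrusion_id) else character(),
      unmatched_b = if (nrow(view_b)) as.character(view_b$protrusion_id) else character()
    ))
  }
  d <- abs(outer(view_a$arc_position_um, view_b$arc_position_um, `-`))
  idx <- which(d <= match_radius_um, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    # sort candidate pairs by distance; ties broken by (row, col) index so the
    # result does not depend on which() enumeration order
    ord <- order(d[idx], idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    used_a <- logical(nrow(view_a))
    used_b <- logical(nrow(view_b))
    keep <- logical(nrow(idx))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]
      j <- idx[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        keep[k] <- TRUE
      }
    }
    idx <- idx[keep, , drop = FALSE]
    matches <- tibble::tibble(
      id_a = as.character(view_a$protrusion_id[idx[, 1]]),
      id_b = as.character(view_b$protrusion_id[idx[, 2]]),
      distance_um = d[idx]
    )
  } else {
    matches <- empty
  }
  list(
    matches = matches,
    unmatched_a = setdiff(as.character(view_a$protrusion_id), matches$id_a),
    unmatched_b = setdiff(as.character(view_b$protrusion_id), matches$id_b)
  )
}

#' Formation and elimination rates between two sessions
#'
#' Spines present at the first view but unmatched at the second are
#' eliminated; spines at the second view unmatched at the first are formed.
#' Both percentages use the first-view spine count as denominator.
#' Total turnover defaults to `formation_pct + elimination_pct`; the
#' alternative `"pooled"` convention divides formed + eliminated by twice
#' the first-view count.
#'
#' @inheritParams match_protrusions
#' @param turnover Either `"sum"` (default) or `"pooled"`.
#' @return A one-row tibble: `n_first`, `n_second`, `n_persistent`,
#'   `n_formed`, `n_eliminated`, `formation_pct`, `elimination_pct`,
#'   `turnover_pct`, plus list-columns `formed_ids`, `eliminated_ids`,
#'   `persistent_ids`. With zero first-view spines the percentages are `NA`
#'   (flagged with a warning), never silently zero.
#' @examples
#' a <- tibble::tibble(protrusion_id = c("s1", "s2"), arc_position_um = c(1, 5))
#' b <- tibble::tibble(protrusion_id = c("s1", "s9"), arc_position_um = c(1.2, 9))
#' turnover_rates(a, b, match_radius_um = 0.7)
#' @export
turnover_rates <- function(view_a, view_b,
    match_radius_um = default_thresholds()$match_radius_um,
    turnover = c("sum", "pooled")) {
  turnover <- match.arg(turnover)
  m <- match_protrusions(view_a, view_b, match_radius_um)
  n_first <- nrow(view_a)
  n_second <- nrow(view_b)
  n_pers <- nrow(m$matches)
  n_elim <- length(m$unmatched_a)
  n_form <- length(m$unmatched_b)
  stopifnot(n_first == n_elim + n_pers, n_second == n_form + n_pers)
  if (n_first == 0) {
    warn("Zero spines at first view: formation/elimination rates undefined.")
    f_pct <- e_pct <- t_pct <- NA_real_
  } else {
    f_pct <- 100 * n_form / n_first
    e_pct <- 100 * n_elim / n_first
    t_pct <- if (turnover == "sum") {
      f_pct + e_pct
    } else {
      100 * (n_form + n_elim) / (2 * n_first)
    }
  }
  tibble::tibble(
    n_first = n_first, n_second = n_second, n_persistent = n_pers,
    n_formed = n_form, n_eliminated = n_elim,
    formation_pct = f_pct, elimination_pct = e_pct, turnover_pct = t_pct,
    formed_ids = list(m$unmatched_b),
    eliminated_ids = list(m$unmatched_a),
    persistent_ids = list(m$matches$id_a)
  )
}

#' Survival of newly formed spines at a later session
#'
#' @param formed_view Data frame (`protrusion_id`, `arc_position_um`) of the
#'   spines formed in an earlier window.
#' @param later_view Data frame of all protrusions at the later session.
#' @inheritParams match_protrusions
#' @return A one-row tibble `n_formed`, `n_surviving`, `survival_pct`
#'   (`NA` with a warning when nothing was formed).
#' @export
survival_rate <- function(formed_view, later_view,
    match_radius_um = default_thresholds()$match_radius_um) {
  n_formed <- nrow(formed_view)
  if (n_formed == 0) {
    warn("No spines formed: survival rate undefined.")
    return(tibble::tibble(
      n_formed = 0L, n_surviving = 0L, survival_pct = NA_real_
    ))
  }
  m <- match_protrusions(formed_view, later_view, match_radius_um)
  tibble::tibble(
    n_formed = n_formed,
    n_surviving = nrow(m$matches),
    survival_pct = 100 * nrow(m$matches) / n_formed
  )
}

#' Re-formation of eliminated spines in close proximity
#'
#' Counts how many spines formed in a later window appear within
#' `proximity_um` of the arc position of a spine eliminated in an earlier
#' window — the "re-formation in close proximity" readout of longitudinal
#' plasticity. The percentage is taken over the later window's formed spines
#' by default (`denominator = "formed"`); `"eliminated"` expresses it
#' relative to the earlier eliminations instead.
#'
#' @param eliminated_positions_um Numeric vector of arc positions of
#'   eliminated spines (earlier window).
#' @param formed_view Data frame (`protrusion_id`, `arc_position_um`) of
#'   spines formed in the later window.
#' @param proximity_um Maximum arc distance counting as "close proximity".
#' @param denominator `"formed"` (default) or `"eliminated"`.
#' @return One-row tibble `n_eliminated`, `n_formed`, `n_reformed`,
#'   `reformation_pct`, plus list-column `reformed_ids`.
#' @export
reformation_in_proximity <- function(eliminated_positions_um, formed_view,
    proximity_um = default_thresholds()$proximity_um,
    denominator = c("formed", "eliminated")) {
  denominator <- match.arg(denominator)
  assert_non_negative(proximity_um, "proximity_um")
  if (length(proximity_um) != 1 || proximity_um < 0) {
    abort("`proximity_um` must be a single non-negative number.")
  }
  n_formed <- nrow(formed_view)
  n_elim <- length(eliminated_positions_um)
  if (n_formed > 0) {
    assert_columns(formed_view, c("protrusion_id", "arc_position_um"),
      "formed_view")
  }
  if (n_elim == 0 || n_formed == 0) {
    reformed <- character()
  } else {
    d <- vapply(
      formed_view$arc_position_um,
      function(p) min(abs(p - eliminated_positions_um)),
      numeric(1)
    )
    reformed <- as.character(formed_view$protrusion_id[d <= proximity_um])
  }
  denom <- if (denominator == "formed") n_formed else n_elim
  tibble::tibble(
    n_eliminated = n_elim, n_formed = n_formed,
    n_reformed = length(reformed),
    reformation_pct = if (denom > 0) 100 * length(reformed) / denom else NA_real_,
    reformed_ids = list(reformed)
  )
}

#' Three-session turnover summary per dendrite
#'
#' Runs the full longitudinal pipeline on an observation table covering
#' three imaging days (e.g. 0/2/7): eligibility filtering, spine/filopodium
#' calling (filopodia are tallied separately and excluded from turnover
#' counts), window-1 and window-2 formation/elimination rates, survival of
#' window-1 formed spines at the last day, and re-formation of window-1
#' eliminated spines in proximity among window-2 formations.
#'
#' @param obs Data frame with columns `mouse_id`, `dendrite_id`, `day`,
#'   `protrusion_id`, `arc_position_um`, `length_um`, `head_um`, `neck_um`,
#'   `shaft_diameter_um`.
#' @param days Length-3 sorted vector of imaging days present in `obs`.
#' @inheritParams match_protrusions
#' @inheritParams reformation_in_proximity
#' @param turnover Turnover convention, see [turnover_rates()].
#' @return A tibble with one row per (mouse, dendrite, window) for the two
#'   windows, carrying the [turnover_rates()] columns plus `survival_pct`
#'   (window 1 row) and `reformation_pct` (window 2 row).
#' @export
summarize_turnover <- function(obs, days = c(0, 2, 7),
    match_radius_um = default_thresholds()$match_radius_um,
    proximity_um = default_thresholds()$proximity_um,
    turnover = c("sum", "pooled")) {
  turnover <- match.arg(turnover)
  assert_columns(obs, c("mouse_id", "dendrite_id", "day", "protrusion_id",
    "arc_position_um", "length_um", "head_um", "neck_um",
    "shaft_diameter_um"), "obs")
  if (length(days) != 3) {
    abort("`days` must list exactly three imaging days.")
  }
  days <- sort(days)
  obs <- filter_eligible_protrusions(obs)
  obs <- classify_protrusions_invivo(obs)
  spines <- dplyr::filter(obs, .data$kind == "spine")

  one_dendrite <- function(df, key) {
    va <- dplyr::filter(df, .data$day == days[1])
    vb <- dplyr::filter(df, .data$day == days[2])
    vc <- dplyr::filter(df, .data$day == days[3])
    w1 <- turnover_rates(va, vb, match_radius_um, turnover)
    w2 <- turnover_rates(vb, vc, match_radius_um, turnover)
    formed_w1 <- dplyr::filter(vb, .data$protrusion_id %in% w1$formed_ids[[1]])
    eliminated_w1 <- dplyr::filter(va,
      .data$protrusion_id %in% w1$eliminated_ids[[1]])
    formed_w2 <- dplyr::filter(vc, .data$protrusion_id %in% w2$formed_ids[[1]])
    surv <- if (nrow(formed_w1) > 0) {
      survival_rate(formed_w1, vc, match_radius_um)$survival_pct
    } else {
      NA_real_
    }
    ref <- reformation_in_proximity(
      eliminated_w1$arc_position_um, formed_w2, proximity_um
    )
    w1$window <- sprintf("day%g-day%g", days[1], days[2])
    w2$window <- sprintf("day%g-day%g", days[2], days[3])
    w1$survival_pct <- surv
    w2$survival_pct <- NA_real_
    w1$reformation_pct <- NA_real_
    w2$reformation_pct <- ref$reformation_pct
    w2$n_reformed <- ref$n_reformed
    w1$n_reformed <- NA_integer_
    dplyr::bind_rows(w1, w2)
  }

  out <- dplyr::group_modify(
    dplyr::group_by(spines, .data$mouse_id, .data$dendrite_id),
    one_dendrite
  )
  out <- dplyr::ungroup(out)
  dplyr::select(
    out, "mouse_id", "dendrite_id", "window", dplyr::everything()
  )
}
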