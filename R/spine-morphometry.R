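#' Classify dendritic protrusions by head/neck and length/neck ratios
#'
#' Assigns each protrusion to one of the four morphological classes used in
#' confocal spine quantification, from manually measured length (L), head
#' width (H) and neck width (N). The rules are purely ratio-based, so the
#' classification is invariant under a common rescaling of all three
#' measurements:
#'
#' * **mushroom**: H/N >= 1.5
#' * **filopodium**: H/N < 1.2 and L/N > 3
#' * **stubby**: H/N <= 1 and L/N <= 1
#' * **thin**: 1 <= H/N < 1.5 and 1.5 <= L/N <= 3
#'
#' The rules are evaluated in that fixed order; the regions only touch at
#' ratio boundaries, and the order makes boundary behavior deterministic.
#' Ratio combinations covered by none of the four published regions (e.g.
#' H/N = 1.3 with L/N = 4) receive the explicit label `"unclassified"`:
#' they are excluded from per-class densities but still counted in totals,
#' rather than being silently dropped or forced into a class.
#'
#' @param length_um,head_um,neck_um Numeric vectors of spine length, head
#'   width and neck width in micrometres; recycled to a common length. All
#'   values must be strictly positive.
#' @param thresholds Named list of cutoffs, see [default_thresholds()].
#' @return A character vector of labels in
#'   `c("mushroom", "stubby", "thin", "filopodium", "unclassified")`.
#' @examples
#' classify_spine(length_um = 2, head_um = 1.5, neck_um = 1) # mushroom
#' classify_spine(length_um = 4, head_um = 1.0, neck_um = 1) # filopodium
#' @seealso [classify_spines()] for the data-frame interface,
#'   [spine_density()] for per-dendrite densities.
#' @export
classify_spine <- function(length_um, head_um, neck_um,
                           thresholds = default_thresholds()) {
  assert_positive(length_um, "length_um")
  assert_positive(head_um, "head_um")
  assert_positive(neck_um, "neck_um")
  n <- max(length(length_um), length(head_um), length(neck_um))
  length_um <- rep_len(length_um, n)
  head_um <- rep_len(head_um, n)
  neck_um <- rep_len(neck_um, n)

  hn <- head_um / neck_um
  ln <- length_um / neck_um
  th <- thresholds

  label <- rep("unclassified", n)
  mushroom <- hn >= th$mushroom_hn_min
  filopodium <- !mushroom & hn < th$filopodium_hn_max & ln > th$filopodium_ln_min
  stubby <- !mushroom & !filopodium &
    hn <= th$stubby_hn_max & ln <= th$stubby_ln_max
  thin <- !mushroom & !filopodium & !stubby &
    hn >= th$thin_hn_min & hn < th$thin_hn_max &
    ln >= th$thin_ln_min & ln <= th$thin_ln_max
  label[mushroom] <- "mushroom"
  label[filopodium] <- "filopodium"
  label[stubby] <- "stubby"
  label[thin] <- "thin"
  label
}

spine_class_levels <- function() {
  c("mushroom", "stubby", "thin", "filopodium", "unclassified")
}

#' Classify a table of spine measurements
#'
#' @param spines A data frame with columns `length_um`, `head_um`, `neck_um`
#'   (identifier columns such as `spine_id`, `dendrite_id`, `neuron_id` are
#'   carried through unchanged).
#' @inheritParams classify_spine
#' @return The input as a tibble with added columns `hn_ratio`, `ln_ratio`
#'   and `spine_class` (factor over the five labels).
#' @export
classify_spines <- function(spines, thresholds = default_thresholds()) {
  assert_columns(spines, c("length_um", "head_um", "neck_um"), "spines")
  spines <- tibble::as_tibble(spines)
  dplyr::mutate(
    spines,
    hn_ratio = .data$head_um / .data$neck_um,
    ln_ratio = .data$length_um / .data$neck_um,
    spine_class = factor(
      classify_spine(.data$length_um, .data$head_um, .data$neck_um, thresholds),
      levels = spine_class_levels()
    )
  )
}

#' Per-dendrite spine counts and densities by class
#'
#' Counts spines of each morphological class on each dendrite and converts
#' counts to linear densities, `count / dendrite_length_um * scale`.
#' Densities are reported per `scale` micrometres (default 10, figure-style);
#' dendrites are flagged as eligible when longer than `min_length_um`
#' (quantification conventionally restricts to dendrites over 50 um).
#' Unclassified protrusions appear as their own row so that class counts
#' always sum to the total number of measurements.
#'
#' @param spines Data frame of measurements with a `dendrite_id` column;
#'   classified on the fly with [classify_spines()] unless a `spine_class`
#'   column is already present.
#' @param dendrites Data frame with columns `dendrite_id`, `length_um` and
#'   optionally `neuron_id`.
#' @param scale Reporting scale in um (density = spines per `scale` um).
#' @param min_length_um Eligibility cutoff for dendrite length.
#' @inheritParams classify_spine
#' @return A tibble with one row per dendrite x class: columns `dendrite_id`
#'   (and `neuron_id` if supplied), `length_um`, `eligible`, `spine_class`,
#'   `n`, `density`.
#' @examples
#' spines <- tibble::tibble(
#'   dendrite_id = "d1",
#'   length_um = rep(2, 10), head_um = rep(1.6, 10), neck_um = rep(1, 10)
#' )
#' dendrites <- tibble::tibble(dendrite_id = "d1", length_um = 50)
#' spine_density(spines, dendrites, scale = 10) # mushroom density 2 per 10 um
#' @export
spine_density <- function(spines, dendrites, scale = 10,
                          min_length_um = default_thresholds()$dendrite_min_um,
                          thresholds = default_thresholds()) {
  assert_columns(dendrites, c("dendrite_id", "length_um"), "dendrites")
  assert_positive(dendrites$length_um, "dendrites$length_um")
  assert_positive(scale, "scale")
  if (anyDuplicated(dendrites$dendrite_id)) {
    abort("`dendrites` has duplicated dendrite_id rows.")
  }
  if (nrow(spines) > 0) {
    assert_columns(spines, "dendrite_id", "spines")
    unknown <- setdiff(unique(spines$dendrite_id), dendrites$dendrite_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "Spines reference dendrite_id(s) absent from `dendrites`: %s.",
        paste(unknown, collapse = ", ")
      ))
    }
    if (!"spine_class" %in% names(spines)) {
      spines <- classify_spines(spines, thresholds)
    }
    counts <- dplyr::count(spines, .data$dendrite_id, .data$spine_class,
      .drop = FALSE, name = "n"
    )
  } else {
    counts <- tibble::tibble(
      dendrite_id = character(),
      spine_class = factor(character(), levels = spine_class_levels()),
      n = integer()
    )
  }

  grid <- tidyr::expand_grid(
    dendrite_id = dendrites$dendrite_id,
    spine_class = factor(spine_class_levels(), levels = spine_class_levels())
  )
  out <- dplyr::left_join(grid, counts, by = c("dendrite_id", "spine_class"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::left_join(out, dendrites, by = "dendrite_id")
  out$eligible <- out$length_um > min_length_um
  out$density <- out$n / out$length_um * scale
  id_cols <- intersect(c("neuron_id", "dendrite_id", "length_um", "eligible"), names(out))
  dplyr::select(out, dplyr::all_of(id_cols), "spine_class", "n", "density")
}

#' Average per-dendrite densities within neurons
#'
#' One to three dendrites are typically quantified per neuron and the
#' experimental unit ("n") is the neuron, so group densities are means of
#' per-dendrite densities within each neuron and class.
#'
#' @param density_tbl Output of [spine_density()]; must contain `neuron_id`.
#' @param eligible_only Drop dendrites below the length cutoff first
#'   (default `TRUE`).
#' @return Tibble with `neuron_id`, `spine_class`, `n_dendrites`,
#'   `mean_density`.
#' @export
neuron_spine_density <- function(density_tbl, eligible_only = TRUE) {
  assert_columns(density_tbl, c("neuron_id", "spine_class", "density"),
    "density_tbl")
  if (eligible_only && "eligible" %in% names(density_tbl)) {
    density_tbl <- dplyr::filter(density_tbl, .data$eligible)
  }
  dplyr::summarise(
    dplyr::group_by(density_tbl, .data$neuron_id, .data$spine_class),
    n_dendrites = dplyr::n(),
    mean_density = mean(.data$density),
    .groups = "drop"
  )
}
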