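#' Bin mRNA puncta positions along a dendrite
#'
#' Positions are distances from the cell body along the straightened
#' dendrite. Bins are half-open `[i*w, (i+1)*w)` so each punctum falls in
#' exactly one bin; the last bin is closed at the dendrite length so a
#' punctum exactly at the tip is kept. The number of bins is
#' `ceiling(length / w)`.
#'
#' @param positions_um Numeric vector of puncta positions (um from soma).
#' @param dendrite_length_um Dendrite length in um.
#' @param bin_width_um Bin width in um (default 5).
#' @return A tibble with `bin` (1-based index), `start_um`, `end_um`,
#'   `count`.
#' @examples
#' bin_puncta(c(1, 4.9, 5.0, 12), dendrite_length_um = 15, bin_width_um = 5)
#' @export
bin_puncta <- function(positions_um, dendrite_length_um,
                       bin_width_um = default_thresholds()$bin_width_um) {
  assert_positive(dendrite_length_um, "dendrite_length_um")
  assert_positive(bin_width_um, "bin_width_um")
  if (length(positions_um) > 0) {
    assert_non_negative(positions_um, "positions_um")
    if (any(positions_um > dendrite_length_um)) {
      abort("Puncta positions beyond the dendrite length.")
    }
  }
  n_bins <- ceiling(dendrite_length_um / bin_width_um)
  idx <- pmin(floor(positions_um / bin_width_um), n_bins - 1) + 1
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    bin = seq_len(n_bins),
    start_um = (seq_len(n_bins) - 1) * bin_width_um,
    end_um = pmin(seq_len(n_bins) * bin_width_um, dendrite_length_um),
    count = counts
  )
}

#' Normalize a binned puncta profile to its first bin
#'
#' Distribution profiles are compared across dendrites after setting the
#' count in the first (most proximal, next to the cell body) bin to 1.
#' A dendrite whose first bin is empty has no defined normalization; it is
#' flagged (`NA` profile with a warning) so downstream group averaging can
#' exclude it, rather than dividing by zero.
#'
#' @param counts Integer vector of per-bin counts (first element = bin
#'   adjacent to the cell body), or the tibble returned by [bin_puncta()].
#' @return Numeric vector of normalized counts (`counts / counts[1]`), or
#'   all-`NA` when the first bin is empty.
#' @examples
#' normalize_first_bin(c(4, 2, 1)) # 1, 0.5, 0.25
#' @export
normalize_first_bin <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- counts$count
  }
  assert_non_negative(counts, "counts")
  if (length(counts) == 0) {
    return(numeric())
  }
  if (counts[1] == 0) {
    warn("First bin is empty; normalized profile undefined for this dendrite.")
    return(rep(NA_real_, length(counts)))
  }
  counts / counts[1]
}

#' Linear puncta density
#'
#' @inheritParams bin_puncta
#' @param scale Reporting scale in um (default 10: puncta per 10 um).
#' @return Puncta count per `scale` um of dendrite.
#' @export
puncta_density <- function(positions_um, dendrite_length_um, scale = 10) {
  assert_positive(dendrite_length_um, "dendrite_length_um")
  assert_positive(scale, "scale")
  length(positions_um) / dendrite_length_um * scale
}

#' Group puncta distribution profile across dendrites
#'
#' Bins each dendrite at `bin_width_um`, normalizes to the first bin, and
#' averages the normalized profiles bin-wise across dendrites (mean and
#' SEM), matching the per-bin mean +/- SEM presentation of distribution
#' figures. Dendrites with an empty first bin are excluded from the group
#' profile and reported in the `excluded` element.
#'
#' @param puncta Data frame with columns `dendrite_id`, `position_um`.
#' @param dendrites Data frame with `dendrite_id`, `length_um`.
#' @inheritParams bin_puncta
#' @return A list with `per_dendrite` (tibble of binned, normalized counts),
#'   `profile` (tibble `bin`, `start_um`, `n_dendrites`, `mean_norm`,
#'   `sem_norm`) and `excluded` (dendrite ids with empty first bins).
#' @export
puncta_profile <- function(puncta, dendrites,
                           bin_width_um = default_thresholds()$bin_width_um) {
  assert_columns(dendrites, c("dendrite_id", "length_um"), "dendrites")
  if (nrow(puncta) > 0) {
    assert_columns(puncta, c("dendrite_id", "position_um"), "puncta")
  }
  per <- lapply(seq_len(nrow(dendrites)), function(i) {
    id <- dendrites$dendrite_id[i]
    pos <- if (nrow(puncta) > 0) {
      puncta$position_um[puncta$dendrite_id == id]
    } else {
      numeric()
    }
    b <- bin_puncta(pos, dendrites$length_um[i], bin_width_um)
    b$dendrite_id <- id
    b$norm <- suppressWarnings(normalize_first_bin(b$count))
    b
  })
  per <- dplyr::bind_rows(per)
  excluded <- unique(per$dendrite_id[is.na(per$norm)])
  kept <- dplyr::filter(per, !is.na(.data$norm))
  profile <- dplyr::summarise(
    dplyr::group_by(kept, .data$bin, .data$start_um),
    n_dendrites = dplyr::n(),
    mean_norm = mean(.data$norm),
    sem_norm = sd(.data$norm) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  list(per_dendrite = per, profile = profile, excluded = excluded)
}
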