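#' Canonical analysis thresholds
#'
#' All decision thresholds used across the package live in this one table so
#' that every classifier and summary pulls its defaults from the same place,
#' and any override can be echoed into run metadata next to the value it
#' replaced.
#'
#' The morphometric and motion thresholds are the published cutoffs applied
#' throughout the quantification: mushroom spines require a head/neck ratio of
#' at least 1.5; filopodia a head/neck ratio below 1.2 together with a
#' length/neck ratio above 3; stubby spines head/neck and length/neck both at
#' most 1; thin spines head/neck in [1, 1.5) with length/neck in [1.5, 3].
#' Granule traces with |net displacement| of at least 2 um are unidirectional
#' (anterograde when positive, retrograde when negative); the remainder are
#' split by lateral maximal displacement at 1 um (stationary vs oscillatory)
#' and 2 um (oscillatory vs bidirectional). Kymographs are recorded at one
#' frame per second for 100 s; puncta are binned at 5 um from the cell body.
#' Conventions this package introduces (run-velocity tolerance, matching
#' radius, re-formation proximity) are listed alongside and documented in the
#' vignette.
#'
#' @return A named list of numeric constants.
#' @examples
#' default_thresholds()$mushroom_hn_min
#' @export
default_thresholds <- function() {
  list(
    # spine morphometry (ratio cutoffs)
    mushroom_hn_min    = 1.5,
    stubby_hn_max      = 1.0,
    stubby_ln_max      = 1.0,
    thin_hn_min        = 1.0,
    thin_hn_max        = 1.5,
    thin_ln_min        = 1.5,
    thin_ln_max        = 3.0,
    filopodium_hn_max  = 1.2,
    filopodium_ln_min  = 3.0,
    dendrite_min_um    = 50,
    # granule motion (um)
    nd_unidirectional_um = 2.0,
    lmd_oscillatory_um   = 1.0,
    lmd_bidirectional_um = 2.0,
    frame_interval_s     = 1.0,
    n_frames             = 100,
    run_velocity_tol_um_s = 0.02,
    # in vivo turnover
    protrusion_shaft_fraction = 1 / 3,
    invivo_filopodium_length_factor = 2.0,
    match_radius_um    = 0.5,
    proximity_um       = 2.0,
    # puncta
    bin_width_um       = 5.0,
    # reporting
    density_scale_um   = 10
  )
}
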