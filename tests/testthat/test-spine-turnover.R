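obs_row <- function(id, pos, day = 0, length = 1, head = 0.6, neck = 0.4,
                    shaft = 1) {
  tibble::tibble(
    mouse_id = "m1", dendrite_id = "d1", day = day, protrusion_id = id,
    arc_position_um = pos, length_um = length, head_um = head,
    neck_um = neck, shaft_diameter_um = shaft
  )
}

test_that("protrusions shorter than a third of the shaft are excluded", {
  obs <- dplyr::bind_rows(
    obs_row("p1", 1, length = 0.5, shaft = 1.2),  # 0.5 > 0.4 -> kept
    obs_row("p2", 2, length = 0.3, shaft = 0.9)   # 0.3 = 0.3, strict -> drop
  )
  kept <- filter_eligible_protrusions(obs)
  expect_equal(kept$protrusion_id, "p1")
  expect_equal(nrow(filter_eligible_protrusions(obs[0, ])), 0)
  obs$shaft_diameter_um[1] <- NA
  expect_error(filter_eligible_protrusions(obs), "shaft")
})

test_that("in vivo filopodium rule uses head/neck and length/neck ratios", {
  filo <- obs_row("p1", 1, length = 4, head = 1.0, neck = 1.0)
  wide_head <- obs_row("p2", 1, length = 4, head = 1.5, neck = 1.0)
  expect_equal(classify_protrusions_invivo(filo)$kind, "filopodium")
  expect_equal(classify_protrusions_invivo(wide_head)$kind, "spine")
  # optional 2x-average-length criterion demotes short candidates
  expect_equal(
    classify_protrusions_invivo(filo, mean_spine_length_um = 3,
      require_length_criterion = TRUE)$kind,
    "spine" # 4 um is only 1.33x the 3 um cohort mean
  )
  expect_equal(
    classify_protrusions_invivo(filo, mean_spine_length_um = 1.5,
      require_length_criterion = TRUE)$kind,
    "filopodium"
  )
  expect_error(
    classify_protrusions_invivo(filo, require_length_criterion = TRUE),
    "mean_spine_length_um"
  )
})

test_that("greedy position matching is exact on the 2x2 case and at the identity", {
  a <- tibble::tibble(protrusion_id = c("a1", "a2"),
    arc_position_um = c(1.0, 5.0))
  b <- tibble::tibble(protrusion_id = c("b1", "b2"),
    arc_position_um = c(1.2, 9.0))
  m <- match_protrusions(a, b, match_radius_um = 0.7)
  expect_equal(m$matches$id_a, "a1")
  expect_equal(m$matches$id_b, "b1")
  expect_equal(m$unmatched_a, "a2")
  expect_equal(m$unmatched_b, "b2")

  ident <- match_protrusions(a, a, match_radius_um = 0.5)
  expect_equal(ident$matches$id_a, ident$matches$id_b)
  expect_length(ident$unmatched_a, 0)

  # radius 0: only exact coincidences
  exact <- match_protrusions(a, b, match_radius_um = 0)
  expect_equal(nrow(exact$matches), 0)

  dup <- dplyr::bind_rows(a, a[1, ])
  expect_error(match_protrusions(dup, b), "Duplicate")
})

test_that("matching is symmetric under view exchange", {
  withr::with_seed(9, {
    a <- tibble::tibble(
      protrusion_id = sprintf("a%02d", 1:30),
      arc_position_um = sort(runif(30, 0, 100))
    )
    b <- tibble::tibble(
      protrusion_id = sprintf("b%02d", 1:28),
      arc_position_um = sort(runif(28, 0, 100))
    )
  })
  ab <- match_protrusions(a, b, 1.5)$matches
  ba <- match_protrusions(b, a, 1.5)$matches
  expect_setequal(paste(ab$id_a, ab$id_b), paste(ba$id_b, ba$id_a))
})

test_that("turnover percentages use the first-view denominator", {
  # 100 spines at day 0; 10 lost, 6 gained by day 2
  a <- tibble::tibble(
    protrusion_id = sprintf("s%03d", 1:100),
    arc_position_um = (1:100) * 10
  )
  survivors <- a[-(1:10), ]
  formed <- tibble::tibble(
    protrusion_id = sprintf("n%02d", 1:6),
    arc_position_um = (1:6) * 10 + 5
  )
  b <- dplyr::bind_rows(survivors, formed)
  r <- turnover_rates(a, b, match_radius_um = 0.5)
  expect_equal(r$elimination_pct, 10)
  expect_equal(r$formation_pct, 6)
  expect_equal(r$turnover_pct, 16)
  expect_equal(r$n_first, r$n_eliminated + r$n_persistent)
  expect_equal(r$n_second, r$n_formed + r$n_persistent)
  r2 <- turnover_rates(a, b, match_radius_um = 0.5, turnover = "pooled")
  expect_equal(r2$turnover_pct, 8)

  same <- turnover_rates(a, a)
  expect_equal(same$formation_pct, 0)
  expect_equal(same$elimination_pct, 0)

  gone <- turnover_rates(a, a[0, ])
  expect_equal(gone$elimination_pct, 100)
  expect_equal(gone$formation_pct, 0)

  expect_warning(r0 <- turnover_rates(a[0, ], b), "undefined")
  expect_true(is.na(r0$formation_pct))
})

test_that("survival rate counts formed spines still present later", {
  formed <- tibble::tibble(
    protrusion_id = sprintf("f%d", 1:4), arc_position_um = c(1, 5, 9, 13)
  )
  later <- tibble::tibble(
    protrusion_id = sprintf("l%d", 1:3), arc_position_um = c(1.1, 5.2, 13)
  )
  s <- survival_rate(formed, later, match_radius_um = 0.5)
  expect_equal(s$survival_pct, 75)
  expect_equal(survival_rate(formed, formed)$survival_pct, 100)
  expect_warning(s0 <- survival_rate(formed[0, ], later), "undefined")
  expect_true(is.na(s0$survival_pct))
})

test_that("re-formation counts formed spines near eliminated positions", {
  formed <- tibble::tibble(protrusion_id = "f1", arc_position_um = 5.8)
  r <- reformation_in_proximity(5.0, formed, proximity_um = 1.0)
  expect_equal(r$n_reformed, 1)
  expect_equal(r$reformation_pct, 100)
  expect_equal(
    reformation_in_proximity(numeric(), formed, 1.0)$n_reformed, 0
  )
  expect_equal(
    reformation_in_proximity(5.0, formed, proximity_um = 0)$n_reformed, 0
  )
  exact <- reformation_in_proximity(5.8, formed, proximity_um = 0)
  expect_equal(exact$n_reformed, 1)
  r2 <- reformation_in_proximity(c(5, 20), formed, 1.0,
    denominator = "eliminated")
  expect_equal(r2$reformation_pct, 50)
})

test_that("the pipeline recovers the generator's event ledger exactly", {
  sim <- sim_longitudinal_spines(n_spines = 150, seed = 17)
  res <- summarize_turnover(sim$observations)
  w1 <- res[res$window == "day0-day2", ]
  w2 <- res[res$window == "day2-day7", ]
  expect_equal(w1$n_eliminated, sim$truth$n_eliminated_w1)
  expect_equal(w1$n_formed, sim$truth$n_formed_w1)
  expect_equal(w2$n_formed, sim$truth$n_formed_w2)
  expect_equal(w2$n_reformed, sim$truth$n_reformed_w2)
  expect_equal(w1$survival_pct, 100) # generated formations all persist
  # conservation at each window
  expect_equal(w1$n_first, w1$n_eliminated + w1$n_persistent)
  expect_equal(w1$n_second, w1$n_formed + w1$n_persistent)
  expect_equal(w2$n_first, w2$n_eliminated + w2$n_persistent)
  expect_equal(w2$n_second, w2$n_formed + w2$n_persistent)
})

test_that("filopodia are excluded from turnover spine counts", {
  base <- dplyr::bind_rows(
    obs_row(c("s1", "s2"), c(10, 20), day = 0),
    obs_row(c("s1", "s2"), c(10, 20), day = 2),
    obs_row(c("s1", "s2"), c(10, 20), day = 7)
  )
  with_filo <- dplyr::bind_rows(
    base,
    obs_row("f1", 30, day = 0, length = 4, head = 0.4, neck = 0.4)
  )
  res <- summarize_turnover(with_filo)
  expect_equal(res$n_first[res$window == "day0-day2"], 2)
  expect_equal(res$elimination_pct[res$window == "day0-day2"], 0)
})
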