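test_that("oxygen-state classification applies phase-specific criteria", {
  th <- oxygen_state_thresholds()
  sat <- o2_saturation(35, 28)
  # at equilibrium the light phase is far below the 200% ceiling
  expect_false(classify_oxygen_state(sat, 35, 28, "light", th))
  expect_true(classify_oxygen_state(2.2 * sat, 35, 28, "light", th))
  expect_false(classify_oxygen_state(1.99 * sat, 35, 28, "light", th))
  # dark: anoxia floor by default
  expect_true(classify_oxygen_state(0, 35, 28, "dark", th))
  expect_true(classify_oxygen_state(4.9, 35, 28, "dark", th))
  expect_false(classify_oxygen_state(40, 35, 28, "dark", th))
  # stricter relative hypoxia criterion on request
  th_h <- oxygen_state_thresholds(dark_criterion = "hypoxia")
  expect_true(classify_oxygen_state(0.29 * sat, 35, 28, "dark", th_h))
  expect_false(classify_oxygen_state(0.31 * sat, 35, 28, "dark", th_h))
  expect_error(classify_oxygen_state(-1, 35, 28, "dark", th), "o2")
})

test_that("threshold constructor enforces its ordering invariants", {
  expect_error(oxygen_state_thresholds(anoxia_umol_l = 0), "anoxia")
  expect_error(oxygen_state_thresholds(hypoxia_pct = 120), "hypoxia")
  expect_error(oxygen_state_thresholds(supersaturation_pct = 90),
               "supersaturation")
})

test_that("detectable change uses a strict k-sigma rule", {
  expect_false(detectable_change(0, precision = 2))
  expect_true(detectable_change(20, precision = 2))      # 20 > 6
  expect_true(detectable_change(-20, precision = 2))
  expect_false(detectable_change(6, precision = 2))      # boundary
  expect_false(detectable_change(3 * 0.05, precision = 0.05))
  expect_error(detectable_change(1, precision = 0), "positive")
  # combined rule needs BOTH analytes above detection
  expect_true(detectable_met_change(20, 1))
  expect_false(detectable_met_change(20, 0.1))
  expect_false(detectable_met_change(5, 1))
})

test_that("consensus codes unanimity and is permutation invariant", {
  expect_equal(consensus(c(FALSE, FALSE, FALSE)), "-")
  expect_equal(consensus(c(TRUE, TRUE, TRUE)), "+")
  expect_equal(consensus(c(TRUE, FALSE, TRUE)), "±")
  set.seed(5)
  for (i in 1:10) {
    flags <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    expect_equal(consensus(flags), consensus(sample(flags)))
  }
  expect_error(consensus(logical(0)), "logical")
  expect_error(consensus(c(TRUE, NA)), "logical")
})

test_that("packaged decision matrix yields accepted volumes 1000 and 1250", {
  m <- read_decision_matrix()
  expect_equal(nrow(m), 48)  # 6 volumes x 4 hours x 2 phases
  res <- accept_volumes(m, decision_hour = 3)
  expect_equal(res$accepted, c(1000, 1250))
  expect_equal(res$minimum, 1000)
  # 250 mL fails on oxygen state, 1500 mL on detectability
  at3 <- dplyr::filter(m, hour == 3)
  expect_true(all(dplyr::filter(at3, volume_ml == 250)$o2_state == "+"))
  expect_equal(dplyr::filter(at3, volume_ml == 1500,
                             phase == "light")$met_change, "±")
  expect_false(dplyr::filter(res$table, volume_ml == 250)$accepted)
  expect_false(dplyr::filter(res$table, volume_ml == 1500)$accepted)
})

test_that("acceptance requires codes from both phases at the decision hour", {
  m <- read_decision_matrix()
  expect_error(accept_volumes(m, decision_hour = 7), "decision hour")
  light_only <- dplyr::filter(m, phase == "light")
  expect_error(accept_volumes(light_only, 3), "both light and dark")
  expect_error(accept_volumes(dplyr::mutate(m, o2_state = "?"), 3),
               "invalid consensus")
})

test_that("build_decision_matrix aggregates replicate flags to codes", {
  flags <- tidyr::crossing(volume_ml = c(500, 1000), hour = 3,
                           phase = c("light", "dark"), replicate = 1:3)
  flags$o2_unsafe <- flags$volume_ml == 500
  flags$met_detect <- TRUE
  flags$met_detect[1] <- FALSE  # one mixed cell
  m <- build_decision_matrix(flags)
  expect_equal(nrow(m), 4)
  expect_true(all(m$n_replicates == 3))
  expect_setequal(m$o2_state[m$volume_ml == 500], "+")
  expect_setequal(m$o2_state[m$volume_ml == 1000], "-")
  expect_true("±" %in% m$met_change)
})

test_that("extraction error is linear with the documented bounds", {
  expect_equal(extraction_error(0)$mean_pct, 0)
  one_ml <- extraction_error(1, reference_ml = 250)
  expect_equal(one_ml$per_sample_pct, 0.4)     # 1/250, below 0.5%/mL
  expect_equal(one_ml$per_ml_pct, 0.4)
  bench <- extraction_error(c(0.5, 2.0, 5.0), reference_ml = 250)
  expect_equal(bench$mean_pct, 1)
  expect_equal(bench$max_pct, 2)
  # linearity in the unaccounted volume
  expect_equal(extraction_error(c(2, 4))$per_sample_pct,
               2 * extraction_error(c(1, 2))$per_sample_pct)
  expect_error(extraction_error(-1), "non-negative")
  expect_error(extraction_error(1, reference_ml = 0), "positive")
})

test_that("simulated volume ladder shows the non-monotone acceptance
           trade-off", {
  # fixed biomass: identical replicates, analytic noise only
  vs <- simulate_volume_series(rate_cv = 0, seed = 77)
  frac <- vs$flags |>
    dplyr::filter(phase == "light") |>
    dplyr::group_by(volume_ml, hour) |>
    dplyr::summarise(unsafe = mean(o2_unsafe), .groups = "drop") |>
    tidyr::pivot_wider(names_from = volume_ml, values_from = unsafe)
  # light-phase unsafe fraction is non-increasing in volume at every hour
  for (r in seq_len(nrow(frac))) {
    expect_true(all(diff(as.numeric(frac[r, -1])) <= 0))
  }
  # seeded reproducibility of the consensus codes (biological variation on)
  m1 <- simulate_volume_series(seed = 78)$matrix
  m2 <- simulate_volume_series(seed = 78)$matrix
  expect_identical(m1, m2)
})

test_that("zero-noise ladder reproduces the optimum mid-volume window", {
  vs <- simulate_volume_series(noise_ta = 0, noise_o2 = 0, rate_cv = 0,
                               seed = 1)
  res <- accept_volumes(vs$matrix, decision_hour = 3)
  expect_equal(res$accepted, c(1000, 1250))
  # small dark volumes hit the anoxia floor within the first hour
  dark250 <- dplyr::filter(vs$trajectories, volume_ml == 250,
                           phase == "dark", hour == 1)
  expect_true(all(dark250$o2 < 5))
  # larger volumes dilute the hourly concentration change
  light1 <- dplyr::filter(vs$trajectories, phase == "light", hour == 1,
                          replicate == 1)
  expect_true(all(diff(light1$o2[order(light1$volume_ml)]) < 0))
})
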