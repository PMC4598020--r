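test_that("noise-free simulate -> reduce recovers the generating rates", {
  set.seed(21)
  for (i in 1:25) {
    colonies <- make_colonies(
      n = sample(1:3, 1),
      g = runif(1, 0.5, 20), p_net = runif(1, 0.5, 15),
      respiration = runif(1, 0.5, 10), sa = runif(1, 5e-4, 5e-3))
    out <- reduce_noiseless(colonies, make_schedule(dur = runif(1, 1, 4)),
                            volume_l = runif(1, 0.5, 2))
    expect_equal(out$colonies$g, colonies$g, tolerance = 1e-9)
    expect_equal(out$colonies$p_net, colonies$p_net, tolerance = 1e-9)
    expect_equal(out$colonies$respiration, colonies$respiration,
                 tolerance = 1e-9)
  }
})

test_that("gross photosynthesis equals net plus respiration on every row", {
  cs <- simulate_case_study(seed = 31, day_sd = 0.3, residual_sd = 0.4)
  out <- process_incubation_set(cs$samples, cs$colonies, cs$volumes)
  expect_equal(out$colonies$p_gross,
               out$colonies$p_net + out$colonies$respiration)
})

test_that("a shared background drift cancels through the blank correction", {
  colonies <- make_colonies()
  base <- reduce_noiseless(colonies)
  drifted <- reduce_noiseless(colonies, control_drift_ta = -4,
                              control_drift_o2 = 7)
  expect_equal(drifted$colonies$g, base$colonies$g, tolerance = 1e-9)
  expect_equal(drifted$colonies$p_net, base$colonies$p_net,
               tolerance = 1e-9)
  expect_equal(drifted$colonies$respiration, base$colonies$respiration,
               tolerance = 1e-9)
})

test_that("rates are homogeneous of degree one in the generating drifts", {
  colonies <- make_colonies(g = 4, p_net = 3, respiration = 2)
  scaled <- make_colonies(g = 4 * 2.5, p_net = 3 * 2.5,
                          respiration = 2 * 2.5)
  out1 <- reduce_noiseless(colonies)
  out2 <- reduce_noiseless(scaled)
  expect_equal(out2$colonies$g, 2.5 * out1$colonies$g, tolerance = 1e-9)
  expect_equal(out2$colonies$p_net, 2.5 * out1$colonies$p_net,
               tolerance = 1e-9)
  expect_equal(out2$colonies$respiration,
               2.5 * out1$colonies$respiration, tolerance = 1e-9)
})

test_that("daily integrals equal the stepwise sums over measured windows", {
  colonies <- make_colonies(g = 6, p_net = 4, respiration = 3)
  out <- reduce_noiseless(colonies, make_schedule(n_light = 2, n_dark = 2))
  expect_equal(out$daily$p_net_daily, 4 * 6, tolerance = 1e-9)  # 2 x 3 h
  expect_equal(out$daily$r_daily, 3 * 6, tolerance = 1e-9)
  expect_equal(out$daily$light_coverage_h, 6)
  expect_equal(out$daily$dark_coverage_h, 6)
})

test_that("a treatment cycle without any control is an error, never zero", {
  colonies <- make_colonies()
  s <- simulate_incubation(colonies, make_schedule(), noise_ta = 0,
                           noise_o2 = 0)
  no_ctl <- dplyr::filter(s, role == "treatment")
  expect_error(
    process_incubation_set(no_ctl, colonies, attr(s, "volumes")),
    "control")
})

test_that("unpaired and duplicated samples are rejected with identifiers", {
  colonies <- make_colonies()
  s <- simulate_incubation(colonies, make_schedule(), noise_ta = 0,
                           noise_o2 = 0)
  vols <- attr(s, "volumes")
  expect_error(process_incubation_set(s[-1, ], colonies, vols),
               "start and one end")
  dup <- dplyr::bind_rows(s, s[1, ])
  expect_error(process_incubation_set(dup, colonies, vols), "duplicate")
})

test_that("volume resolution prefers per-cycle accounting over defaults", {
  colonies <- make_colonies(g = 8, p_net = 5, respiration = 4)
  sched <- make_schedule()
  s <- simulate_incubation(colonies, sched, volume_l = 1.2,
                           noise_ta = 0, noise_o2 = 0)
  chambers <- unique(s$chamber_id)
  # correct per-cycle volumes override a wrong chamber-level default
  vols <- dplyr::bind_rows(
    tibble::tibble(chamber_id = rep(chambers, each = 2),
                   cycle = rep(sched$cycle, length(chambers)),
                   volume_l = 1.2),
    tibble::tibble(chamber_id = chambers, volume_l = 9.9))
  out <- process_incubation_set(s, colonies, vols)
  expect_equal(out$colonies$g, colonies$g, tolerance = 1e-9)
  # extracted + residual accounting works too
  vols2 <- tibble::tibble(chamber_id = chambers, extracted_l = 0.1,
                          residual_l = 1.1)
  expect_equal(process_incubation_set(s, colonies, vols2)$cycles$volume_l,
               rep(1.2, 2))
  expect_error(
    process_incubation_set(s, colonies,
                           tibble::tibble(chamber_id = "nope",
                                          volume_l = 1)),
    "volume")
})

test_that("an empty treatment set yields an empty result with a warning", {
  colonies <- make_colonies()
  s <- simulate_incubation(colonies, make_schedule(), noise_ta = 0,
                           noise_o2 = 0)
  ctl_only <- dplyr::filter(s, role == "control")
  expect_warning(
    out <- process_incubation_set(ctl_only, colonies, attr(s, "volumes")),
    "no treatment")
  expect_s3_class(out, "chamberflux_rates")
  expect_equal(nrow(out$colonies), 0)
})

test_that("anomalous cycles are flagged, not dropped", {
  colonies <- make_colonies(g = 2, p_net = 3, respiration = -1)  # O2 rises
  out <- reduce_noiseless(colonies)                              # in dark
  dark <- dplyr::filter(out$cycles, phase == "dark")
  expect_equal(dark$anomaly, "o2_rose_in_dark")
  expect_equal(nrow(out$colonies), 1)
})

test_that("provenance records density and control counts per cycle", {
  colonies <- make_colonies()
  out <- reduce_noiseless(colonies, salinity = 35.3, temperature = 28.6)
  expect_true(all(out$cycles$n_controls == 3))
  expect_equal(unique(out$cycles$rho), sw_density(35.3, 28.6))
  # constant-density override is honoured
  s <- simulate_incubation(colonies, make_schedule(), noise_ta = 0,
                           noise_o2 = 0)
  out2 <- process_incubation_set(s, colonies, attr(s, "volumes"),
                                 config = reduction_config(rho = 1.025))
  expect_equal(unique(out2$cycles$rho), 1.025)
})
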