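sample_row <- function(chamber = "F1", phase = "light", time_h = 0,
                       ta = 2300, o2 = 205) {
  tibble::tibble(chamber_id = chamber, phase = phase, time_h = time_h,
                 ta = ta, o2 = o2)
}

test_that("drift follows the field sign conventions", {
  s <- sample_row(ta = 2300, o2 = 200)
  e <- sample_row(time_h = 3, ta = 2280, o2 = 180)
  expect_equal(drift(s, e, "ta"), 20)    # TA fell: calcification positive
  expect_equal(drift(s, e, "o2"), -20)   # O2 fell (dark-type drift)
  expect_equal(drift(s, dplyr::mutate(s, time_h = 3), "ta"), 0)
  expect_equal(drift(s, dplyr::mutate(s, time_h = 3), "o2"), 0)
})

test_that("drift is antisymmetric and validates its pairing", {
  set.seed(11)
  for (i in 1:20) {
    s <- sample_row(ta = runif(1, 2200, 2400), o2 = runif(1, 100, 300))
    e <- sample_row(time_h = runif(1, 1, 6), ta = runif(1, 2200, 2400),
                    o2 = runif(1, 100, 300))
    fwd_ta <- drift(s, e, "ta")
    fwd_o2 <- drift(s, e, "o2")
    s2 <- dplyr::mutate(e, time_h = 10)  # reversed values, valid ordering
    e2 <- dplyr::mutate(s, time_h = 13)
    expect_equal(drift(s2, e2, "ta"), -fwd_ta)
    expect_equal(drift(s2, e2, "o2"), -fwd_o2)
  }
  expect_error(drift(sample_row(), sample_row(chamber = "F2", time_h = 3)),
               "chamber")
  expect_error(drift(sample_row(), sample_row(phase = "dark", time_h = 3)),
               "phase")
  expect_error(drift(sample_row(time_h = 3), sample_row(time_h = 3)),
               "duration")
})

test_that("control correction subtracts the blank mean", {
  expect_equal(as.numeric(control_corrected_drift(60, c(10, 10, 10))), 50)
  expect_equal(as.numeric(control_corrected_drift(20, c(2, 4))), 17)
  expect_equal(attr(control_corrected_drift(20, c(2, 4)), "n_controls"), 2)
  # blank identity: treatment drift equal to the control mean nulls out
  expect_equal(as.numeric(control_corrected_drift(7, c(6, 8))), 0)
  expect_error(control_corrected_drift(10, numeric(0)), "control")
  expect_error(control_corrected_drift(10, c(1, NA)), "control")
})

test_that("calcification rate implements the alkalinity-anomaly equation", {
  expect_equal(calcification_rate(100, 1, 3, 0.0012, 1.025),
               100 * 1.025 * 0.5 * 1 / (3 * 0.0012) / 1000)
  expect_equal(calcification_rate(100, 1, 3, 0.0012, 1.025), 14.236,
               tolerance = 1e-4)
  expect_equal(calcification_rate(0, 1, 3, 0.0012, 1.025), 0)
  g1 <- calcification_rate(50, 1, 3, 0.0015, 1.023)
  expect_equal(calcification_rate(50, 2, 3, 0.0015, 1.023), 2 * g1)
  expect_equal(calcification_rate(50, 1, 6, 0.0015, 1.023), g1 / 2)
  expect_equal(calcification_rate(100, 1, 3, 0.0015, 1.023), 2 * g1)
  expect_error(calcification_rate(50, 0, 3, 0.0015, 1.023), "volume")
  expect_error(calcification_rate(50, 1, -3, 0.0015, 1.023), "duration")
  expect_error(calcification_rate(50, 1, 3, 0, 1.023), "surface_area")
  expect_error(calcification_rate(50, 1, 3, 0.0015, 0), "rho")
})

test_that("oxygen flux rate has no density term and flips sign in the dark", {
  expect_equal(oxygen_flux_rate(50, 1, 3, 0.0012, "light"),
               50 * 1 / (3 * 0.0012) / 1000)
  expect_equal(oxygen_flux_rate(50, 1, 3, 0.0012, "light"), 13.889,
               tolerance = 1e-4)
  expect_equal(oxygen_flux_rate(0, 1, 3, 0.0012, "light"), 0)
  # dark decline (end - start = -20) reports positive respiration
  r <- oxygen_flux_rate(-20, 1, 3, 0.0012, "dark")
  expect_gt(r, 0)
  expect_equal(r, 20 * 1 / (3 * 0.0012) / 1000)
})

test_that("gross photosynthesis is the sum of net and respiration", {
  expect_equal(gross_photosynthesis(6.4, 5.0), 11.4)
  expect_equal(gross_photosynthesis(5.4, 3.0), 8.4)
  expect_equal(gross_photosynthesis(0, 0), 0)
})

test_that("daily integration is a stepwise sum with coverage reporting", {
  out <- integrate_daily(rep(2, 4), rep(3, 4), photoperiod_h = 12)
  expect_equal(as.numeric(out), 24)
  expect_equal(attr(out, "coverage_h"), 12)
  expect_equal(attr(out, "coverage_frac"), 1)
  expect_equal(as.numeric(integrate_daily(5, 3)), 15)
  expect_equal(as.numeric(integrate_daily(c(1, 2, 3), c(3, 3, 3))), 18)
  # partial coverage is reported, not extrapolated, unless asked
  part <- integrate_daily(c(2, 2), c(3, 3), photoperiod_h = 12)
  expect_equal(as.numeric(part), 12)
  expect_equal(attr(part, "coverage_frac"), 0.5)
  extr <- integrate_daily(c(2, 2), c(3, 3), photoperiod_h = 12,
                          extrapolate = TRUE)
  expect_equal(as.numeric(extr), 24)
  expect_error(integrate_daily(c(1, 2), c(3, 3), start_h = c(0, 2)),
               "overlap")
  expect_silent(integrate_daily(c(1, 2), c(3, 3), start_h = c(0, 3)))
  expect_error(integrate_daily(1, -1), "positive")
})
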