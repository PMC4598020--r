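library(dplyr)

case_study_rates <- function(seed, day_sd = 0.3, residual_sd = 0.4,
                             ...) {
  cs <- simulate_case_study(seed = seed, day_sd = day_sd,
                            residual_sd = residual_sd, ...)
  process_incubation_set(cs$samples, cs$colonies, cs$volumes)$colonies |>
    mutate(cell = interaction(species, site))
}

test_that("chamber comparison handles identical and shifted pairs", {
  x <- c(4.2, 5.1, 3.8, 4.9, 5.5)
  same <- compare_chambers(x, x, design = "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # constant shift: mean difference recovered exactly
  shift <- compare_chambers(x + 1.25, x, design = "paired")
  expect_equal(shift$mean_diff, 1.25)
  set.seed(3)
  for (i in 1:10) {
    y <- rnorm(8, 5)
    cc <- runif(1, -2, 2)
    expect_equal(compare_chambers(y + cc, y, design = "paired")$mean_diff,
                 cc)
  }
})

test_that("paired designs are matched by colony, not position", {
  a <- tibble(colony_id = c("c1", "c2", "c3"), value = c(1, 2, 3))
  b <- tibble(colony_id = c("c3", "c1", "c2"), value = c(3, 1, 2))
  out <- compare_chambers(a, b, design = "paired")
  expect_equal(out$mean_diff, 0)
  expect_equal(out$p_value, 1)
  bad <- tibble(colony_id = c("c1", "c2", "c9"), value = 1:3)
  expect_error(compare_chambers(a, bad, design = "paired"),
               "same colonies")
  expect_error(compare_chambers(1, 1:3, design = "independent"),
               "at least two")
})

test_that("power of the independent comparison increases with the shift", {
  set.seed(17)
  reject <- sapply(c(0, 0.5, 1.5), function(shift) {
    mean(replicate(200, {
      compare_chambers(rnorm(15, 5 + shift), rnorm(15, 5),
                       design = "independent")$p_value < 0.05
    }))
  })
  expect_true(all(diff(reject) > 0))
  expect_gt(reject[3], 0.9)
})

test_that("mixed model recovers fixed effects exactly in the noiseless
           limit", {
  cs <- simulate_case_study(day_sd = 0, residual_sd = 0, noise_ta = 0,
                            noise_o2 = 0)
  rates <- process_incubation_set(cs$samples, cs$colonies, cs$volumes)
  d <- mutate(rates$colonies, cell = interaction(species, site))
  truth <- cs$truth |>
    distinct(species, site, cell_g) |>
    mutate(cell = interaction(species, site))
  fit <- fit_metabolic_lme(d, "g", ~ 0 + cell)
  est <- setNames(fit$coefficients$estimate,
                  sub("^cell", "", fit$coefficients$term))
  expect_equal(est[as.character(truth$cell)],
               setNames(truth$cell_g, truth$cell), tolerance = 1e-9)
})

test_that("balanced-design lme fixed effects equal the normal-equations
           oracle", {
  d <- case_study_rates(seed = 5)
  fit <- fit_metabolic_lme(d, "p_net", ~ 0 + cell)
  X <- model.matrix(~ 0 + cell, d)
  ols <- drop(solve(crossprod(X), crossprod(X, d$p_net)))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-8)
})

test_that("rotating the reference level leaves fitted values unchanged", {
  d <- case_study_rates(seed = 9)
  f1 <- fit_metabolic_lme(d, "respiration", ~ species + site,
                          reference = list(species = "M. harttii"))
  f2 <- fit_metabolic_lme(d, "respiration", ~ species + site,
                          reference = list(species = "P. astreoides"))
  expect_false(identical(f1$coefficients$term, f2$coefficients$term))
  expect_equal(unname(fitted(f1$fit)), unname(fitted(f2$fit)),
               tolerance = 1e-8)
  # intercept rows name their reference level implicitly via the terms
  expect_true("(Intercept)" %in% f1$coefficients$term)
})

test_that("the day random intercept needs at least two days", {
  d <- filter(case_study_rates(seed = 13), day == 1)
  expect_error(fit_metabolic_lme(d, "g", ~ species),
               "two distinct days")
  expect_error(fit_metabolic_lme(d, "nope", ~ species), "response")
  expect_error(
    fit_metabolic_lme(case_study_rates(seed = 13), "g", ~ depth),
    "depth")
})

test_that("variance components are recovered at realistic magnitudes", {
  d <- case_study_rates(seed = 23, day_sd = 0.5, residual_sd = 0.4)
  fit <- fit_metabolic_lme(d, "g", ~ 0 + cell)
  expect_true(all(fit$variance >= 0))
  expect_gt(fit$variance["day_sd"], 0.1)   # generating value 0.5
  expect_lt(fit$variance["day_sd"], 1.5)
  expect_gt(fit$variance["residual_sd"], 0.2)  # generating value ~0.4
  expect_lt(fit$variance["residual_sd"], 0.8)
})

test_that("model selection compares nested fits under ML", {
  d <- case_study_rates(seed = 29)
  full <- fit_metabolic_lme(d, "p_net", ~ species * site)
  same <- select_model(full, full)
  expect_equal(same$lr_stat, 0)
  reduced <- fit_metabolic_lme(d, "p_net", ~ species)
  cmp <- select_model(full, reduced)
  expect_gt(cmp$lr_stat, 0)
  expect_equal(cmp$df, 3)  # site + 2 interaction contrasts
  expect_lt(cmp$p_value, 0.05)
  expect_true(is.finite(cmp$diagnostics$resid_fitted_cor))
  not_nested <- fit_metabolic_lme(d, "p_net", ~ site)
  expect_error(select_model(reduced, not_nested), "nested")
})

test_that("null likelihood-ratio statistic follows its chi-squared law", {
  set.seed(41)
  n_sim <- 150
  lr <- replicate(n_sim, {
    d <- tidyr::crossing(species = c("a", "b", "c"), day = 1:4,
                         rep = 1:3) |>
      mutate(y = rnorm(n(), 5, 1) + rep(rnorm(4, 0, 0.3), each = 3,
                                        times = 3))
    full <- fit_metabolic_lme(d, "y", ~ species)
    reduced <- fit_metabolic_lme(d, "y", ~ 1)
    select_model(full, reduced)$lr_stat
  })
  # empirical rejection at nominal 5% stays near nominal under the null
  rej <- mean(stats::pchisq(lr, 2, lower.tail = FALSE) < 0.05)
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.15)
  # quartiles of the LR agree with chi-squared(2) within Monte Carlo slack
  expect_equal(stats::median(lr), stats::qchisq(0.5, 2), tolerance = 0.35)
})
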