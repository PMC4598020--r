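#' Compare metabolic rates between two chamber designs
#'
#' Two-sided t comparison of one metabolic metric measured in two chamber
#' designs, either paired (the same colonies measured in both designs,
#' matched by colony) or independent (different colonies per design).
#'
#' @param rates_a,rates_b Numeric rate vectors, one value per colony; or
#'   data frames with columns `colony_id` and `value` (paired designs are
#'   then matched by `colony_id`).
#' @param design `"paired"` or `"independent"`.
#' @param metric Optional label carried into the result.
#' @return A one-row tibble of class `"chamber_comparison"`: `metric`,
#'   `design`, `n_a`, `n_b`, `mean_diff` (a minus b), `se_diff`,
#'   `statistic` (t), `df`, `p_value`.
#' @examples
#' set.seed(1)
#' x <- rnorm(10, 5); compare_chambers(x, x + 0.2, design = "paired")
#' @export
compare_chambers <- function(rates_a, rates_b,
                             design = c("paired", "independent"),
                             metric = NA_character_) {
  design <- match.arg(design)
  ab <- align_rates(rates_a, rates_b, design)
  if (length(ab$a) < 2 || length(ab$b) < 2) {
    stop("at least two observations per group are required",
         call. = FALSE)
  }
  if (design == "paired" &&
      stats::sd(ab$a - ab$b) <=
        1e-10 * max(abs(ab$a - ab$b), 1)) {
    # degenerate but well-defined: constant difference between designs
    d <- mean(ab$a - ab$b)
    return(tibble::new_tibble(tibble::tibble(
      metric = metric, design = design,
      n_a = length(ab$a), n_b = length(ab$b),
      mean_diff = d, se_diff = 0,
      statistic = if (d == 0) 0 else sign(d) * Inf,
      df = length(ab$a) - 1,
      p_value = if (d == 0) 1 else 0), class = "chamber_comparison"))
  }
  fit <- stats::t.test(ab$a, ab$b, paired = design == "paired",
                       var.equal = FALSE)
  se <- unname(fit$stderr)
  tibble::new_tibble(tibble::tibble(
    metric = metric, design = design,
    n_a = length(ab$a), n_b = length(ab$b),
    mean_diff = mean(ab$a) - mean(ab$b), se_diff = se,
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value), class = "chamber_comparison")
}

align_rates <- function(a, b, design) {
  pull <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("colony_id", "value") %in% names(x)))
      stats::setNames(x$value, x$colony_id)
    } else as.numeric(x)
  }
  a <- pull(a); b <- pull(b)
  if (design == "paired") {
    if (!is.null(names(a)) && !is.null(names(b))) {
      if (!setequal(names(a), names(b))) {
        stop("paired design requires the same colonies in both groups",
             call. = FALSE)
      }
      b <- b[names(a)]
    } else if (length(a) != length(b)) {
      stop("paired design requires matched vectors of equal length",
           call. = FALSE)
    }
  }
  list(a = unname(a), b = unname(b))
}

#' Fit a random-intercept mixed model to colony metabolic rates
#'
#' Fits the species/habitat comparison model: one metabolic response per
#' colony-day modelled by fixed effects (species, site, or any formula
#' over the metadata) plus a random intercept for sampling day, estimated
#' by restricted maximum likelihood (REML) via [nlme::lme()]. The
#' intercept's reference level is explicit and rotatable, since contrasts
#' against different reference species are often reported side by side.
#'
#' @param data Long-format data frame: one row per colony-day with the
#'   response column, the fixed-effect factors, and a `day` column
#'   (>= 2 distinct days).
#' @param response Name of the response column (e.g. `"p_net"`).
#' @param fixed One-sided formula of fixed effects, e.g.
#'   `~ species * site`; use `~ 0 + cell` forms for direct cell-mean
#'   estimates.
#' @param reference Optional named list of factor reference levels, e.g.
#'   `list(species = "M. harttii")`; factors are releveled before
#'   fitting.
#' @param method `"REML"` (default) or `"ML"`.
#' @param random_group Column defining the random-intercept grouping;
#'   default `"day"`. When several sites are deployed on the same
#'   calendar day, each site-day shares one blank correction and one
#'   water mass, so a `deployment` (site x day) column is the
#'   exchangeable unit and should be supplied here.
#' @return An object of class `"metabolic_lme"`: the `nlme::lme` fit plus
#'   tidied `coefficients` (estimate, se, df, t, p per fixed effect),
#'   `variance` (day and residual sd), the formula and reference levels.
#'   Rows with missing values are dropped and counted in `n_dropped`.
#' @export
fit_metabolic_lme <- function(data, response, fixed = ~ species * site,
                              reference = NULL, method = "REML",
                              random_group = "day") {
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    stop("response column `", response, "` not found", call. = FALSE)
  }
  if (!random_group %in% names(data)) {
    stop("a `", random_group,
         "` column is required for the random intercept", call. = FALSE)
  }
  vars <- all.vars(fixed)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("fixed-effect variable(s) not in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  use <- stats::complete.cases(data[, c(response, vars, random_group)])
  n_dropped <- sum(!use)
  data <- data[use, , drop = FALSE]
  data$.grp <- factor(data[[random_group]])
  if (nlevels(data$.grp) < 2) {
    stop("at least two distinct days are required to estimate the day ",
         "random intercept; refusing to fit", call. = FALSE)
  }
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2) {
      stop("fixed factor `", v, "` has fewer than two levels",
           call. = FALSE)
    }
  }
  if (!is.null(reference)) {
    for (v in names(reference)) {
      data[[v]] <- stats::relevel(factor(data[[v]]), ref = reference[[v]])
    }
  }
  fml <- stats::as.formula(paste(response, paste(deparse(fixed),
                                                 collapse = "")))
  fit <- nlme::lme(fixed = fml, random = ~ 1 | .grp, data = data,
                   method = method,
                   control = nlme::lmeControl(opt = "optim"))
  tt <- summary(fit)$tTable
  coefs <- tibble::tibble(term = rownames(tt),
                          estimate = unname(tt[, "Value"]),
                          se = unname(tt[, "Std.Error"]),
                          df = unname(tt[, "DF"]),
                          statistic = unname(tt[, "t-value"]),
                          p_value = unname(tt[, "p-value"]))
  vc <- as.numeric(nlme::VarCorr(fit)[, "StdDev"])
  structure(list(fit = fit, coefficients = coefs,
                 variance = c(day_sd = vc[1], residual_sd = vc[2]),
                 response = response, fixed = fixed,
                 reference = reference, method = method,
                 random_group = random_group,
                 n_obs = nrow(data), n_dropped = n_dropped,
                 data = data),
            class = "metabolic_lme")
}

#' @export
print.metabolic_lme <- function(x, ...) {
  cat("Random-intercept (day) mixed model, ", x$method, " fit\n",
      sep = "")
  cat("  response:", x$response, " fixed:", deparse(x$fixed), "\n")
  cat("  n =", x$n_obs, "(", x$n_dropped, "incomplete rows dropped )\n")
  cat(sprintf("  day sd = %.4g, residual sd = %.4g\n",
              x$variance["day_sd"], x$variance["residual_sd"]))
  print(x$coefficients)
  invisible(x)
}

#' Fixed-effect confidence intervals from a metabolic_lme fit
#'
#' @param object A [fit_metabolic_lme()] result.
#' @param level Confidence level; default 0.95.
#' @return Tibble: `term`, `estimate`, `lower`, `upper`.
#' @export
lme_intervals <- function(object, level = 0.95) {
  ci <- nlme::intervals(object$fit, level = level, which = "fixed")$fixed
  tibble::tibble(term = rownames(ci), estimate = ci[, "est."],
                 lower = ci[, "lower"], upper = ci[, "upper"])
}

#' Design-based confidence intervals for cell means
#'
#' Confidence intervals for species-site cell means with the deployment
#' (one site on one day, sharing a single blank correction and water
#' mass) as the unit of replication: each cell's per-deployment means are
#' independent replicates, so a t-interval on them is exactly calibrated
#' regardless of how the within-deployment variance decomposes. This
#' complements the mixed model's intervals, whose fixed residual degrees
#' of freedom overstate precision when the shared blank-correction noise
#' dominates.
#'
#' @param data Per colony-day rates with the grouping columns, a
#'   `deployment` identifier and the metric column.
#' @param metric Name of the rate column to summarise.
#' @param cell_cols Columns defining a cell; default
#'   `c("species", "site")`.
#' @param level Confidence level; default 0.95.
#' @return Tibble: cell columns, `estimate` (grand mean of deployment
#'   means), `lower`, `upper`, `n_deployments`.
#' @export
deployment_mean_intervals <- function(data, metric,
                                      cell_cols = c("species", "site"),
                                      level = 0.95) {
  data <- tibble::as_tibble(data)
  need <- c(cell_cols, "deployment", metric)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_dep <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(cell_cols,
                                                  "deployment")))) |>
    dplyr::summarise(m = mean(.data[[metric]]), .groups = "drop")
  per_dep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
    dplyr::summarise(
      estimate = mean(.data$m),
      se = stats::sd(.data$m) / sqrt(dplyr::n()),
      n_deployments = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      lower = .data$estimate - stats::qt((1 + level) / 2,
                                         .data$n_deployments - 1) *
        .data$se,
      upper = .data$estimate + stats::qt((1 + level) / 2,
                                         .data$n_deployments - 1) *
        .data$se,
      se = NULL)
}

#' Likelihood-ratio comparison of nested fixed-effect structures
#'
#' Compares a full and a reduced fixed-effect specification of the same
#' mixed model by a likelihood-ratio test. Because REML likelihoods are
#' not comparable across fixed-effect structures, both models are refit
#' under maximum likelihood internally. Residual diagnostics (residuals
#' versus fitted summary) are attached for the full model.
#'
#' @param full,reduced Two [fit_metabolic_lme()] objects on the same data
#'   and response; `reduced`'s fixed terms must be a subset of `full`'s.
#' @return A list of class `"lme_model_comparison"`: `lr_stat`, `df`,
#'   `p_value`, the two ML log-likelihoods, and `diagnostics` (quartiles
#'   of the full model's standardised residuals and the
#'   residual-vs-fitted correlation).
#' @export
select_model <- function(full, reduced) {
  stopifnot(inherits(full, "metabolic_lme"),
            inherits(reduced, "metabolic_lme"))
  if (!identical(full$response, reduced$response)) {
    stop("models have different responses", call. = FALSE)
  }
  terms_full <- attr(stats::terms(full$fixed), "term.labels")
  terms_red <- attr(stats::terms(reduced$fixed), "term.labels")
  if (!all(terms_red %in% terms_full)) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  refit <- function(m) {
    if (m$method == "ML") m$fit else
      fit_metabolic_lme(m$data, m$response, m$fixed, m$reference,
                        method = "ML",
                        random_group = m$random_group)$fit
  }
  f_ml <- refit(full)
  r_ml <- refit(reduced)
  ll_f <- as.numeric(stats::logLik(f_ml))
  ll_r <- as.numeric(stats::logLik(r_ml))
  df <- attr(stats::logLik(f_ml), "df") - attr(stats::logLik(r_ml), "df")
  lr <- max(0, 2 * (ll_f - ll_r))
  p <- if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_
  res <- stats::resid(f_ml, type = "pearson")
  fitted <- stats::fitted(f_ml)
  structure(list(
    lr_stat = lr, df = df, p_value = p,
    logLik_full = ll_f, logLik_reduced = ll_r,
    diagnostics = list(
      residual_quartiles = stats::quantile(res, c(0.25, 0.5, 0.75)),
      resid_fitted_cor = suppressWarnings(stats::cor(res, fitted))),
    shapiro_p = tryCatch(
      stats::shapiro.test(res)$p.value, error = function(e) NA_real_)),
    class = "lme_model_comparison")
}

#' @export
print.lme_model_comparison <- function(x, ...) {
  cat(sprintf("LR = %.4g on %d df, p = %.4g (ML refits)\n", x$lr_stat,
              x$df, x$p_value))
  invisible(x)
}
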