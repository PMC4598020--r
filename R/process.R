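#' Reduction configuration
#'
#' Bundles the tunable constants of the reduction pipeline. Defaults follow
#' the instrument precisions of the titration and optode systems the
#' pipeline was designed around and a 12 h tropical photoperiod.
#'
#' @param rho Optional constant seawater density (kg L^-1). `NULL`
#'   (default) evaluates [sw_density()] at each treatment interval's mean
#'   salinity and temperature.
#' @param precision_ta Analytic precision of total alkalinity
#'   (umol kg^-1); default 2.
#' @param precision_o2 Analytic precision of dissolved oxygen
#'   (umol L^-1); default 0.05.
#' @param k_detect Multiple of the analytic precision a drift must exceed
#'   to count as detectable; default 3.
#' @param photoperiod_h Declared photoperiod (h) for daily-coverage
#'   reporting; default 12.
#' @param extrapolate_daily Scale daily sums to the full photoperiod by the
#'   mean measured rate; default `FALSE` (report coverage instead).
#' @return A list of class `"reduction_config"`.
#' @export
reduction_config <- function(rho = NULL, precision_ta = 2,
                             precision_o2 = 0.05, k_detect = 3,
                             photoperiod_h = 12,
                             extrapolate_daily = FALSE) {
  if (!is.null(rho) && (!is.finite(rho) || rho <= 0)) {
    stop("`rho` override must be positive", call. = FALSE)
  }
  stopifnot(precision_ta > 0, precision_o2 > 0, k_detect > 0,
            photoperiod_h > 0)
  structure(list(rho = rho, precision_ta = precision_ta,
                 precision_o2 = precision_o2, k_detect = k_detect,
                 photoperiod_h = photoperiod_h,
                 extrapolate_daily = isTRUE(extrapolate_daily)),
            class = "reduction_config")
}

#' Reduce a sample log to per-colony metabolic rates
#'
#' The full reduction pipeline: pairs start/end samples into incubation
#' cycles, computes TA and O2 drifts, blank-corrects each treatment drift
#' against the mean of the same-cycle, same-phase seawater controls,
#' applies the alkalinity-anomaly and oxygen-flux equations, and assembles
#' per-colony hourly rates (G, P_N, R, P_G) plus daily light/dark
#' integrals.
#'
#' Anomalies (oxygen rising in the dark, alkalinity rising during a cycle,
#' i.e. negative rates after the sign conventions) are flagged in the
#' output, never dropped.
#'
#' @param samples A sample log (see [validate_sample_log()]); exactly two
#'   rows (start and end) per chamber per cycle. An optional `day` column
#'   groups cycles into deployment days.
#' @param colonies Colony metadata (see [validate_colony_metadata()])
#'   mapping treatment chambers to colonies, species/site and surface
#'   area.
#' @param volumes Chamber volume table: `chamber_id` plus either
#'   `volume_l` or `extracted_l` + `residual_l`, and optionally `cycle`
#'   for per-deployment accounting. Resolution order: per-(chamber, cycle)
#'   row, then per-chamber row, then error.
#' @param config A [reduction_config()].
#' @return A list of class `"chamberflux_rates"` with tibbles
#'   \describe{
#'     \item{cycles}{one row per treatment chamber x cycle: corrected
#'       drifts, density used, number of controls, G and the phase's O2
#'       flux, anomaly flags;}
#'     \item{colonies}{one row per colony (x day when present): hourly
#'       G, P_N, R and P_G = P_N + R;}
#'     \item{daily}{per colony (x day): daily P_N, R and light/dark G
#'       integrals with window coverage (h).}
#'   }
#'   Provenance (config and control counts) is attached as attribute
#'   `provenance`.
#' @export
process_incubation_set <- function(samples, colonies, volumes,
                                   config = reduction_config()) {
  samples <- tibble::as_tibble(samples)
  validate_sample_log(samples)
  validate_colony_metadata(colonies)
  colonies <- tibble::as_tibble(colonies)
  if (!inherits(config, "reduction_config")) {
    stop("`config` must be a reduction_config()", call. = FALSE)
  }

  empty <- chamberflux_rates(
    cycles = cycle_template(), colonies = colony_template(),
    daily = daily_template(), config = config)
  if (nrow(samples) == 0 || !any(samples$role == "treatment")) {
    warning("no treatment samples to reduce; returning empty rates",
            call. = FALSE)
    return(empty)
  }

  pairs <- pair_cycles(samples)
  pairs <- resolve_volumes(pairs, samples, volumes)

  ctl <- pairs |>
    dplyr::filter(.data$role == "control") |>
    dplyr::group_by(.data$cycle, .data$phase) |>
    dplyr::summarise(ctl_dta = mean(.data$delta_ta),
                     ctl_do2 = mean(.data$delta_o2),
                     n_controls = dplyr::n(), .groups = "drop")

  trt <- pairs |>
    dplyr::filter(.data$role == "treatment") |>
    dplyr::left_join(ctl, by = c("cycle", "phase"))
  if (any(is.na(trt$n_controls))) {
    miss <- unique(trt$cycle[is.na(trt$n_controls)])
    stop("no same-phase control chamber for cycle(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }

  trt <- trt |>
    dplyr::inner_join(
      dplyr::select(colonies, dplyr::any_of(c(
        "chamber_id", "colony_id", "species", "site", "surface_area_m2"))),
      by = "chamber_id")
  if (nrow(trt) == 0) {
    warning("no treatment chamber matches the colony metadata",
            call. = FALSE)
    return(empty)
  }

  rho <- if (is.null(config$rho)) {
    sw_density(trt$mean_salinity, trt$mean_temperature)
  } else {
    rep(config$rho, nrow(trt))
  }

  cycles <- trt |>
    dplyr::mutate(
      rho = rho,
      delta_ta_corr = .data$delta_ta - .data$ctl_dta,
      delta_o2_corr = .data$delta_o2 - .data$ctl_do2,
      g = calcification_rate(.data$delta_ta_corr, .data$volume_l,
                             .data$duration_h, .data$surface_area_m2,
                             .data$rho),
      o2_flux = .data$delta_o2_corr * .data$volume_l /
        (.data$duration_h * .data$surface_area_m2) / 1000,
      o2_flux = ifelse(.data$phase == "dark", -.data$o2_flux,
                       .data$o2_flux),
      anomaly = dplyr::case_when(
        .data$phase == "dark" & .data$o2_flux < 0 ~ "o2_rose_in_dark",
        .data$g < 0 ~ "ta_rose",
        TRUE ~ NA_character_)) |>
    dplyr::select(dplyr::any_of(c(
      "colony_id", "chamber_id", "species", "site", "day", "cycle",
      "phase", "start_h", "end_h", "duration_h", "volume_l", "rho",
      "n_controls", "delta_ta_corr", "delta_o2_corr", "g", "o2_flux",
      "anomaly")))

  group_cols <- intersect(c("colony_id", "species", "site", "day"),
                          names(cycles))
  colony_rates <- cycles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      g = mean(.data$g),
      p_net = mean(.data$o2_flux[.data$phase == "light"]),
      respiration = mean(.data$o2_flux[.data$phase == "dark"]),
      n_cycles = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p_gross = gross_photosynthesis(.data$p_net,
                                                 .data$respiration))

  dark_period <- 24 - config$photoperiod_h
  daily <- cycles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      p_net_daily = daily_sum(.data$o2_flux, .data$duration_h,
                              .data$start_h, .data$phase, "light",
                              config$photoperiod_h,
                              config$extrapolate_daily),
      r_daily = daily_sum(.data$o2_flux, .data$duration_h, .data$start_h,
                          .data$phase, "dark", dark_period,
                          config$extrapolate_daily),
      g_light_daily = daily_sum(.data$g, .data$duration_h, .data$start_h,
                                .data$phase, "light", config$photoperiod_h,
                                config$extrapolate_daily),
      g_dark_daily = daily_sum(.data$g, .data$duration_h, .data$start_h,
                               .data$phase, "dark", dark_period,
                               config$extrapolate_daily),
      light_coverage_h = sum(.data$duration_h[.data$phase == "light"]),
      dark_coverage_h = sum(.data$duration_h[.data$phase == "dark"]),
      .groups = "drop")

  chamberflux_rates(cycles = cycles, colonies = colony_rates,
                    daily = daily, config = config)
}

# pair the two samples of each (chamber, cycle) into one interval row
pair_cycles <- function(samples) {
  keep <- intersect("day", names(samples))  # site/species come from metadata
  pairs <- samples |>
    dplyr::group_by(.data$chamber_id, .data$cycle) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_phases = dplyr::n_distinct(.data$phase),
      role = .data$role[1], phase = .data$phase[1],
      start_h = .data$time_h[1], end_h = .data$time_h[dplyr::n()],
      delta_ta = .data$ta[1] - .data$ta[dplyr::n()],
      delta_o2 = .data$o2[dplyr::n()] - .data$o2[1],
      mean_salinity = mean(.data$salinity),
      mean_temperature = mean(.data$temperature),
      dplyr::across(dplyr::all_of(keep), ~ .x[1]),
      .groups = "drop")
  bad <- pairs$n_samples != 2
  if (any(bad)) {
    stop("chamber/cycle pair(s) without exactly one start and one end ",
         "sample: ",
         paste(utils::head(paste(pairs$chamber_id[bad], pairs$cycle[bad]),
                           5), collapse = ", "), call. = FALSE)
  }
  if (any(pairs$n_phases != 1)) {
    stop("a cycle mixes light and dark samples", call. = FALSE)
  }
  dplyr::mutate(pairs, duration_h = .data$end_h - .data$start_h,
                n_samples = NULL, n_phases = NULL)
}

# per-(chamber, cycle) accounting first, then per-chamber default, else error
resolve_volumes <- function(pairs, samples, volumes) {
  volumes <- tibble::as_tibble(volumes)
  if (!("chamber_id" %in% names(volumes))) {
    stop("`volumes` must have a `chamber_id` column", call. = FALSE)
  }
  if (!("volume_l" %in% names(volumes))) {
    if (!all(c("extracted_l", "residual_l") %in% names(volumes))) {
      stop("`volumes` needs `volume_l` or `extracted_l` + `residual_l`",
           call. = FALSE)
    }
    volumes$volume_l <- chamber_volume(volumes$extracted_l,
                                       volumes$residual_l)
  }
  if (!("cycle" %in% names(volumes))) volumes$cycle <- NA_character_
  per_cycle <- volumes |>
    dplyr::filter(!is.na(.data$cycle)) |>
    dplyr::select("chamber_id", "cycle", vol_cycle = "volume_l")
  per_chamber <- volumes |>
    dplyr::filter(is.na(.data$cycle)) |>
    dplyr::distinct(.data$chamber_id, .keep_all = TRUE) |>
    dplyr::select("chamber_id", vol_chamber = "volume_l")
  out <- pairs |>
    dplyr::left_join(per_cycle, by = c("chamber_id", "cycle")) |>
    dplyr::left_join(per_chamber, by = "chamber_id") |>
    dplyr::mutate(volume_l = dplyr::coalesce(.data$vol_cycle,
                                             .data$vol_chamber),
                  vol_cycle = NULL, vol_chamber = NULL)
  if (any(is.na(out$volume_l))) {
    miss <- unique(out$chamber_id[is.na(out$volume_l)])
    stop("no volume resolvable for chamber(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  out
}

daily_sum <- function(rate, dt, start_h, phase, which_phase, period_h,
                      extrapolate) {
  sel <- phase == which_phase
  if (!any(sel)) return(NA_real_)
  as.numeric(integrate_daily(rate[sel], dt[sel], start_h = start_h[sel],
                             photoperiod_h = period_h,
                             extrapolate = extrapolate))
}

chamberflux_rates <- function(cycles, colonies, daily, config) {
  structure(list(cycles = cycles, colonies = colonies, daily = daily),
            provenance = list(config = config,
                              reduced_at = format(Sys.time(), tz = "UTC")),
            class = "chamberflux_rates")
}

cycle_template <- function() {
  tibble::tibble(colony_id = character(), chamber_id = character(),
                 cycle = character(), phase = character(),
                 start_h = numeric(), end_h = numeric(),
                 duration_h = numeric(), volume_l = numeric(),
                 rho = numeric(), n_controls = integer(),
                 delta_ta_corr = numeric(), delta_o2_corr = numeric(),
                 g = numeric(), o2_flux = numeric(), anomaly = character())
}
colony_template <- function() {
  tibble::tibble(colony_id = character(), g = numeric(), p_net = numeric(),
                 respiration = numeric(), n_cycles = integer(),
                 p_gross = numeric())
}
daily_template <- function() {
  tibble::tibble(colony_id = character(), p_net_daily = numeric(),
                 r_daily = numeric(), g_light_daily = numeric(),
                 g_dark_daily = numeric(), light_coverage_h = numeric(),
                 dark_coverage_h = numeric())
}

#' @export
print.chamberflux_rates <- function(x, ...) {
  cat("<chamberflux_rates>\n")
  cat("  cycles:  ", nrow(x$cycles), " treatment chamber-cycles\n",
      sep = "")
  cat("  colonies:", nrow(x$colonies), "colony rate rows\n")
  cat("  daily:   ", nrow(x$daily), " daily integral rows\n", sep = "")
  invisible(x)
}
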