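#' Simulate one set of sealed chamber incubations
#'
#' Forward model of the reduction pipeline: given true area-specific rates
#' per colony, chamber geometry and an incubation schedule, generates the
#' start/end water samples a field campaign would log. The model treats
#' rates as constant within each sealed window (a start/end design cannot
#' resolve within-window dynamics), inverts the alkalinity-anomaly and
#' oxygen-flux equations to obtain end concentrations, adds a shared
#' background drift (the microbial water-column activity that control
#' chambers exist to remove) and Gaussian analytic noise on every measured
#' value, at the titration and optode precisions by default.
#'
#' Chambers are flushed between cycles, so each cycle restarts from the
#' ambient concentrations. Simulated oxygen is floored at zero and such
#' events are flagged (attribute `anoxia_events`): a schedule that exhausts
#' the chamber is a finding, not an error.
#'
#' @param colonies Tibble of true rates: `colony_id`, `chamber_id`,
#'   `surface_area_m2`, `g`, `p_net`, `respiration`
#'   (mmol m^-2 h^-1; R positive).
#' @param schedule Tibble of sealed windows: `cycle`, `phase`
#'   (`"light"`/`"dark"`), `start_h`, `end_h`.
#' @param volume_l Chamber water volume (L), scalar applied to all
#'   chambers or a tibble `chamber_id`, `volume_l`.
#' @param start_ta,start_o2 Ambient concentrations at flush
#'   (umol kg^-1, umol L^-1).
#' @param salinity,temperature Ambient water properties.
#' @param control_drift_ta,control_drift_o2 Background water-column drift
#'   rates (umol kg^-1 h^-1, umol L^-1 h^-1); default 0.
#' @param noise_ta,noise_o2 Analytic noise sd applied to every measured
#'   value; defaults 2 umol kg^-1 and 0.05 umol L^-1.
#' @param n_controls Number of coral-free control chambers; default 3.
#' @param temp_drift_per_h Linear temperature drift inside a sealed
#'   chamber (degC h^-1); default 0 (a 1.4 degC rise over 8 h, i.e.
#'   0.175, reproduces the worst-case bench finding).
#' @param seed Integer seed; mandatory whenever any noise sd is positive.
#' @return A sample-log tibble (drop-in input for
#'   [process_incubation_set()]) with attributes `truth` (the `colonies`
#'   input), `volumes` (resolved per-chamber volumes) and
#'   `anoxia_events`.
#' @export
simulate_incubation <- function(colonies, schedule, volume_l = 1.05,
                                start_ta = 2300, start_o2 = 205,
                                salinity = 35.3, temperature = 28.6,
                                control_drift_ta = 0,
                                control_drift_o2 = 0,
                                noise_ta = 2, noise_o2 = 0.05,
                                n_controls = 3, temp_drift_per_h = 0,
                                seed = NULL) {
  colonies <- tibble::as_tibble(colonies)
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(c("colony_id", "chamber_id", "surface_area_m2", "g",
                  "p_net", "respiration") %in% names(colonies)),
            all(c("cycle", "phase", "start_h", "end_h") %in%
                  names(schedule)))
  if (any(schedule$end_h <= schedule$start_h)) {
    stop("schedule windows must have positive duration", call. = FALSE)
  }
  require_seed(seed, noise_ta, noise_o2)

  chambers <- dplyr::bind_rows(
    dplyr::transmute(colonies, chamber_id = .data$chamber_id,
                     role = "treatment", sa = .data$surface_area_m2,
                     g = .data$g, p_net = .data$p_net,
                     respiration = .data$respiration),
    tibble::tibble(chamber_id = sprintf("ctl%02d", seq_len(n_controls)),
                   role = "control", sa = NA_real_, g = 0, p_net = 0,
                   respiration = 0))
  vols <- resolve_sim_volumes(chambers$chamber_id, volume_l)
  grid <- tidyr::crossing(chambers, schedule) |>
    dplyr::left_join(vols, by = "chamber_id") |>
    dplyr::mutate(start_ta = start_ta, start_o2 = start_o2,
                  salinity = salinity, temperature = temperature,
                  drift_ta = control_drift_ta,
                  drift_o2 = control_drift_o2)
  out <- forward_samples(grid, noise_ta, noise_o2, temp_drift_per_h)
  attr(out$samples, "truth") <- colonies
  attr(out$samples, "volumes") <- vols
  attr(out$samples, "anoxia_events") <- out$anoxia
  out$samples
}

# vectorised forward kernel: one input row per chamber x cycle, two sample
# rows out; expects columns chamber_id, role, phase, cycle, start_h, end_h,
# sa, volume_l, g, p_net, respiration, start_ta, start_o2, salinity,
# temperature, drift_ta, drift_o2 (+ optional passthrough site, day)
forward_samples <- function(grid, noise_ta, noise_o2, temp_drift_per_h) {
  dur <- grid$end_h - grid$start_h
  t_start <- grid$temperature
  t_end <- grid$temperature + temp_drift_per_h * dur
  rho <- sw_density(grid$salinity, (t_start + t_end) / 2)
  scale <- ifelse(grid$role == "treatment",
                  1000 * dur * grid$sa / grid$volume_l, 0)
  dta_bio <- ifelse(grid$role == "treatment",
                    grid$g * scale / (rho * 0.5), 0)
  do2_bio <- ifelse(grid$role == "treatment",
                    ifelse(grid$phase == "light",
                           grid$p_net, -grid$respiration) * scale, 0)
  ta_end <- grid$start_ta - dta_bio + grid$drift_ta * dur
  o2_end <- grid$start_o2 + do2_bio + grid$drift_o2 * dur

  n <- nrow(grid)
  noise <- function(sd, k) if (sd > 0) stats::rnorm(k, 0, sd) else
    numeric(k)
  ta_obs_s <- grid$start_ta + noise(noise_ta, n)
  ta_obs_e <- ta_end + noise(noise_ta, n)
  o2_obs_s <- grid$start_o2 + noise(noise_o2, n)
  o2_obs_e <- o2_end + noise(noise_o2, n)
  floored <- o2_obs_e < 0 | o2_end < 0
  o2_obs_s <- pmax(o2_obs_s, 0)
  o2_obs_e <- pmax(o2_obs_e, 0)

  keep <- intersect(c("site", "day"), names(grid))
  base <- dplyr::select(grid, dplyr::all_of(c(
    "chamber_id", "role", "phase", "cycle", keep)))
  samples <- dplyr::bind_rows(
    dplyr::mutate(base, time_h = grid$start_h, ta = ta_obs_s,
                  o2 = o2_obs_s, salinity = grid$salinity,
                  temperature = t_start),
    dplyr::mutate(base, time_h = grid$end_h, ta = ta_obs_e,
                  o2 = o2_obs_e, salinity = grid$salinity,
                  temperature = t_end)) |>
    dplyr::arrange(.data$cycle, .data$chamber_id, .data$time_h)
  anoxia <- base[floored, c("chamber_id", "cycle", "phase")]
  list(samples = samples, anoxia = tibble::as_tibble(anoxia))
}

resolve_sim_volumes <- function(chamber_ids, volume_l) {
  if (is.data.frame(volume_l)) {
    vols <- tibble::as_tibble(volume_l)
    stopifnot(all(c("chamber_id", "volume_l") %in% names(vols)))
    missing <- setdiff(chamber_ids, vols$chamber_id)
    if (length(missing) > 0) {
      stop("no simulated volume for chamber(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    vols[vols$chamber_id %in% chamber_ids, ]
  } else {
    if (!(is.numeric(volume_l) && length(volume_l) == 1 && volume_l > 0)) {
      stop("`volume_l` must be a positive scalar or a chamber table",
           call. = FALSE)
    }
    tibble::tibble(chamber_id = unique(chamber_ids), volume_l = volume_l)
  }
}

require_seed <- function(seed, ...) {
  sds <- c(...)
  if (any(sds > 0)) {
    if (is.null(seed)) {
      stop("`seed` is mandatory when any noise sd is positive",
           call. = FALSE)
    }
    set.seed(seed)
  } else if (!is.null(seed)) {
    set.seed(seed)
  }
  invisible(TRUE)
}

#' Simulate a multi-species, two-site field campaign
#'
#' Generates a complete field dataset with the structure of a two-site,
#' three-species, five-colony, five-day chamber survey: per colony-day
#' true rates are drawn from the generative mixed model (species-site cell
#' mean + a shared day random intercept + a colony-day residual), then
#' each colony-day is forward-simulated as one 3 h light and one 3 h dark
#' sealed cycle alongside coral-free controls, with analytic noise on
#' every sample.
#'
#' @param means Cell-mean table with columns `site`, `species`, `p_net`,
#'   `respiration`, `g` (mmol m^-2 h^-1); default [reef_rate_means()].
#' @param n_colonies Colonies per species per site; default 5.
#' @param n_days Consecutive sampling days; default 5.
#' @param day_sd Sd of the shared day random intercept (applied to each
#'   metric); default 0.
#' @param residual_sd Sd of the colony-day biological residual; default 0.
#' @param surface_area_m2 Colony surface area (m^2); default 0.0012
#'   (~12 cm^2 nubbins).
#' @param volume_l Chamber working volume (L); default 1.05 (0.100 L
#'   extracted + 0.95 L residual).
#' @param salinity Named per-site salinities; default
#'   `c(northern = 30.8, southern = 35.3)` (a nearshore site freshened by
#'   run-off versus an offshore site).
#' @param temperature Ambient temperature (degC); default 28.6.
#' @inheritParams simulate_incubation
#' @return A list: `samples` (sample log), `colonies` (metadata),
#'   `volumes`, and `truth` (per colony-day generating rates plus the
#'   cell means and drawn day effects).
#' @export
simulate_case_study <- function(means = reef_rate_means(),
                                n_colonies = 5, n_days = 5,
                                day_sd = 0, residual_sd = 0,
                                surface_area_m2 = 0.0012,
                                volume_l = 1.05,
                                salinity = c(northern = 30.8,
                                             southern = 35.3),
                                temperature = 28.6,
                                start_ta = 2300, start_o2 = 205,
                                noise_ta = 2, noise_o2 = 0.05,
                                n_controls = 3, seed = NULL) {
  means <- tibble::as_tibble(means)
  stopifnot(all(c("site", "species", "p_net", "respiration", "g") %in%
                  names(means)))
  if (dplyr::n_distinct(means$species) < 2) {
    stop("at least two species are required", call. = FALSE)
  }
  require_seed(seed, noise_ta, noise_o2, day_sd, residual_sd)
  sites <- unique(means$site)
  if (is.null(names(salinity))) {
    salinity <- stats::setNames(rep_len(salinity, length(sites)), sites)
  }

  colonies <- tidyr::crossing(
    dplyr::select(means, "site", "species"),
    colony_no = seq_len(n_colonies)) |>
    dplyr::mutate(
      colony_id = sprintf("%s_%s_c%02d", substr(.data$site, 1, 1),
                          gsub("[^A-Za-z]", "", substr(.data$species, 1, 4)),
                          .data$colony_no),
      chamber_id = .data$colony_id,
      surface_area_m2 = surface_area_m2) |>
    dplyr::select("colony_id", "chamber_id", "species", "site",
                  "surface_area_m2")

  day_eff <- tidyr::crossing(day = seq_len(n_days),
                             metric = c("p_net", "respiration", "g")) |>
    dplyr::mutate(effect = if (day_sd > 0)
      stats::rnorm(dplyr::n(), 0, day_sd) else 0) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "effect",
                       names_prefix = "day_")

  truth <- tidyr::crossing(colonies, day = seq_len(n_days)) |>
    dplyr::left_join(means, by = c("site", "species")) |>
    dplyr::left_join(day_eff, by = "day") |>
    dplyr::mutate(
      true_p_net = .data$p_net + .data$day_p_net +
        resid_or_zero(dplyr::n(), residual_sd),
      true_respiration = .data$respiration + .data$day_respiration +
        resid_or_zero(dplyr::n(), residual_sd),
      true_g = .data$g + .data$day_g +
        resid_or_zero(dplyr::n(), residual_sd))

  ctl <- tidyr::crossing(
    site = sites, ctl_no = seq_len(n_controls)) |>
    dplyr::mutate(chamber_id = sprintf("%s_ctl%d", substr(.data$site, 1, 1),
                                       .data$ctl_no),
                  role = "control", sa = NA_real_)
  ctl_days <- tidyr::crossing(dplyr::select(ctl, "site", "chamber_id",
                                            "role", "sa"),
                              day = seq_len(n_days)) |>
    dplyr::mutate(g = 0, p_net = 0, respiration = 0)

  trt_days <- truth |>
    dplyr::transmute(.data$site, .data$chamber_id, role = "treatment",
                     sa = .data$surface_area_m2, .data$day,
                     g = .data$true_g, p_net = .data$true_p_net,
                     respiration = .data$true_respiration)

  grid <- dplyr::bind_rows(trt_days, ctl_days) |>
    tidyr::crossing(tibble::tibble(phase = c("light", "dark"),
                                   offset_h = c(11, 15.5))) |>
    dplyr::mutate(
      cycle = sprintf("%s_d%d_%s", substr(.data$site, 1, 1), .data$day,
                      .data$phase),
      start_h = (.data$day - 1) * 24 + .data$offset_h,
      end_h = .data$start_h + 3,
      volume_l = volume_l,
      start_ta = start_ta, start_o2 = start_o2,
      salinity = unname(salinity[.data$site]),
      temperature = temperature, drift_ta = 0, drift_o2 = 0,
      offset_h = NULL)

  out <- forward_samples(grid, noise_ta, noise_o2, 0)
  list(samples = out$samples,
       colonies = colonies,
       volumes = tibble::tibble(chamber_id = unique(grid$chamber_id),
                                volume_l = volume_l),
       truth = dplyr::select(truth, "colony_id", "species", "site",
                             "day", "true_p_net", "true_respiration",
                             "true_g", cell_p_net = "p_net",
                             cell_respiration = "respiration",
                             cell_g = "g"))
}

resid_or_zero <- function(n, sd) {
  if (sd > 0) stats::rnorm(n, 0, sd) else rep(0, n)
}

#' Illustrative fast-metabolism rate preset
#'
#' Area-specific rates for a fast-metabolising branching coral used by
#' [simulate_volume_series()] to exercise the chamber-volume safety
#' analysis. The values are illustrative: they are chosen so that a small
#' chamber volume exhausts or supersaturates its water within hours while
#' the alkalinity drift in a large volume falls below titration detection
#' -- the qualitative trade-off the volume ladder is designed to expose --
#' not as measurements of any real colony.
#'
#' @return List with `g`, `p_net`, `respiration` (mmol m^-2 h^-1).
#' @export
acropora_rate_preset <- function() {
  list(g = 1.2, p_net = 45, respiration = 42)
}

#' Simulate a chamber-volume sensitivity ladder
#'
#' Runs replicate colonies at a ladder of chamber volumes through sealed
#' light and dark incubations sampled hourly (no flushing), classifies
#' each sample's oxygen state and each cumulative drift's detectability,
#' and returns per-replicate flags ready for [build_decision_matrix()].
#' Replicate colonies differ by a lognormal biological scaling of the
#' preset rates.
#'
#' @param volumes_ml Candidate internal volumes (mL); default
#'   `c(250, 500, 750, 1000, 1250, 1500)`.
#' @param hours Hourly sampling times (h); default `1:4`.
#' @param n_replicates Replicate colonies per volume; default 3.
#' @param rates True rate preset, as [acropora_rate_preset()].
#' @param rate_cv Lognormal coefficient of variation of between-replicate
#'   rates; default 0.1.
#' @param surface_area_m2 Colony surface area (m^2); default 0.0012.
#' @param thresholds An [oxygen_state_thresholds()].
#' @inheritParams simulate_incubation
#' @param precision_ta,precision_o2,k Detection parameters for
#'   [detectable_met_change()].
#' @return A list: `flags` (per volume x hour x phase x replicate
#'   `o2_unsafe`, `met_detect`), `trajectories` (simulated O2 and TA), and
#'   `matrix` (the consensus [build_decision_matrix()] output).
#' @export
simulate_volume_series <- function(volumes_ml = c(250, 500, 750, 1000,
                                                  1250, 1500),
                                   hours = 1:4, n_replicates = 3,
                                   rates = acropora_rate_preset(),
                                   rate_cv = 0.1,
                                   surface_area_m2 = 0.0012,
                                   start_ta = 2300, start_o2 = 205,
                                   salinity = 35, temperature = 28,
                                   noise_ta = 2, noise_o2 = 0.05,
                                   thresholds = oxygen_state_thresholds(),
                                   precision_ta = 2, precision_o2 = 0.05,
                                   k = 3, seed = NULL) {
  stopifnot(all(volumes_ml > 0), all(hours > 0))
  require_seed(seed, noise_ta, noise_o2, rate_cv)
  rho <- sw_density(salinity, temperature)

  reps <- tidyr::crossing(volume_ml = volumes_ml,
                          replicate = seq_len(n_replicates)) |>
    dplyr::mutate(scale_bio = if (rate_cv > 0)
      exp(stats::rnorm(dplyr::n(), 0, rate_cv)) else 1)

  traj <- tidyr::crossing(reps, phase = c("light", "dark"),
                          hour = hours) |>
    dplyr::mutate(
      v_l = .data$volume_ml / 1000,
      conc_scale = 1000 * surface_area_m2 * .data$scale_bio / .data$v_l,
      dta_true = rates$g * .data$conc_scale / (rho * 0.5) * .data$hour,
      do2_true = ifelse(.data$phase == "light", rates$p_net,
                        -rates$respiration) * .data$conc_scale *
        .data$hour)
  # observed values: noise on the start and on each hourly sample
  n <- nrow(traj)
  traj$ta <- start_ta - traj$dta_true +
    (if (noise_ta > 0) stats::rnorm(n, 0, noise_ta) else 0)
  traj$o2 <- pmax(start_o2 + traj$do2_true +
                    (if (noise_o2 > 0) stats::rnorm(n, 0, noise_o2)
                     else 0), 0)
  start_noise_ta <- if (noise_ta > 0)
    stats::rnorm(nrow(reps) * 2, 0, noise_ta) else rep(0, nrow(reps) * 2)
  start_noise_o2 <- if (noise_o2 > 0)
    stats::rnorm(nrow(reps) * 2, 0, noise_o2) else rep(0, nrow(reps) * 2)
  starts <- tidyr::crossing(reps, phase = c("light", "dark")) |>
    dplyr::mutate(ta0 = start_ta + start_noise_ta,
                  o20 = pmax(start_o2 + start_noise_o2, 0))

  flags <- traj |>
    dplyr::left_join(dplyr::select(starts, "volume_ml", "replicate",
                                   "phase", "ta0", "o20"),
                     by = c("volume_ml", "replicate", "phase")) |>
    dplyr::mutate(
      o2_unsafe = ifelse(
        .data$phase == "light",
        classify_oxygen_state(.data$o2, salinity, temperature, "light",
                              thresholds),
        classify_oxygen_state(.data$o2, salinity, temperature, "dark",
                              thresholds)),
      met_detect = detectable_met_change(.data$ta0 - .data$ta,
                                         .data$o2 - .data$o20,
                                         precision_ta, precision_o2, k)) |>
    dplyr::select("volume_ml", "hour", "phase", "replicate", "o2_unsafe",
                  "met_detect")

  list(flags = flags,
       trajectories = dplyr::select(traj, "volume_ml", "replicate",
                                    "phase", "hour", "ta", "o2"),
       matrix = build_decision_matrix(flags))
}
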