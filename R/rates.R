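#' Concentration drift between a start and end sample
#'
#' Signed concentration change over one sealed incubation cycle, with the
#' sign conventions the downstream rate equations expect:
#' * total alkalinity: `start - end`, so that calcification (which removes
#'   two equivalents of alkalinity per mole of CaCO3 precipitated) yields a
#'   positive drift;
#' * oxygen: `end - start`, so that net photosynthesis in the light yields a
#'   positive drift and dark respiration a negative one.
#'
#' @param start,end Single rows of a sample log (see
#'   [validate_sample_log()]) from the same chamber and phase, with
#'   `end$time_h > start$time_h`.
#' @param analyte `"ta"` (umol kg^-1) or `"o2"` (umol L^-1).
#' @return Signed drift in the analyte's concentration units.
#' @examples
#' s <- tibble::tibble(chamber_id = "F1", phase = "light", time_h = 0,
#'                     ta = 2300, o2 = 205)
#' e <- dplyr::mutate(s, time_h = 3, ta = 2280, o2 = 245)
#' drift(s, e, "ta")  # +20
#' drift(s, e, "o2")  # +40
#' @export
drift <- function(start, end, analyte = c("ta", "o2")) {
  analyte <- match.arg(analyte)
  if (!identical(start$chamber_id, end$chamber_id)) {
    stop("start and end samples come from different chambers",
         call. = FALSE)
  }
  if (!identical(start$phase, end$phase)) {
    stop("start and end samples come from different phases", call. = FALSE)
  }
  if (!(end$time_h > start$time_h)) {
    stop("incubation duration must be positive (end after start)",
         call. = FALSE)
  }
  if (analyte == "ta") start$ta - end$ta else end$o2 - start$o2
}

#' Blank-correct a treatment drift against seawater controls
#'
#' Subtracts the mean drift of coral-free control chambers (which tracks
#' microbial activity of the enclosed water) from a treatment chamber's
#' drift. Correction happens in concentration units, before any volume or
#' surface-area scaling, because controls carry no colony and in general
#' their own volume.
#'
#' @param treatment_drift Numeric drift(s) from treatment chambers.
#' @param control_drifts Numeric vector of drifts from same-phase,
#'   same-cycle control chambers; must be non-empty (a missing blank is an
#'   error, never a silent zero-correction).
#' @return Corrected drift(s); the number of controls used is attached as
#'   attribute `n_controls`.
#' @examples
#' control_corrected_drift(60, c(10, 10, 10))  # 50
#' control_corrected_drift(20, c(2, 4))        # 17
#' @export
control_corrected_drift <- function(treatment_drift, control_drifts) {
  if (length(control_drifts) == 0 || any(!is.finite(control_drifts))) {
    stop("at least one finite same-phase control drift is required",
         call. = FALSE)
  }
  out <- treatment_drift - mean(control_drifts)
  attr(out, "n_controls") <- length(control_drifts)
  out
}

#' Hourly calcification rate by the alkalinity-anomaly method
#'
#' Converts a control-corrected total-alkalinity drift to an area-specific
#' calcification rate:
#' \deqn{G = \frac{\Delta TA \cdot \rho \cdot 0.5 \cdot V}{I_t \cdot SA \cdot 1000}}
#' where \eqn{\Delta TA} is in umol kg^-1 (start minus end), \eqn{\rho} the
#' seawater density (kg L^-1) converting per-kilogram alkalinity to
#' per-litre, \eqn{V} the chamber water volume (L), \eqn{I_t} the
#' incubation duration (h), \eqn{SA} the colony surface area (m^2), the
#' factor 0.5 accounting for the two equivalents of alkalinity removed per
#' mole of CaCO3 precipitated, and the factor 1000 converting umol to mmol.
#'
#' @param delta_ta Control-corrected TA drift, start minus end
#'   (umol kg^-1).
#' @param volume_l Chamber water volume (L), > 0.
#' @param duration_h Incubation duration (h), > 0.
#' @param surface_area_m2 Colony surface area (m^2), > 0.
#' @param rho Seawater density (kg L^-1); see [sw_density()].
#' @return Calcification rate G (mmol CaCO3 m^-2 h^-1); positive when TA
#'   fell, i.e. net precipitation.
#' @examples
#' calcification_rate(100, volume_l = 1, duration_h = 3,
#'                    surface_area_m2 = 0.0012, rho = 1.025)  # ~14.24
#' @export
calcification_rate <- function(delta_ta, volume_l, duration_h,
                               surface_area_m2, rho) {
  check_interval_geometry(volume_l, duration_h, surface_area_m2)
  if (any(!is.finite(rho) | rho <= 0)) {
    stop("`rho` must be positive", call. = FALSE)
  }
  delta_ta * rho * 0.5 * volume_l / (duration_h * surface_area_m2) / 1000
}

#' Hourly oxygen flux rate (net photosynthesis or dark respiration)
#'
#' Converts a control-corrected dissolved-oxygen drift (end minus start,
#' umol L^-1) to an area-specific flux:
#' \deqn{P_N, R = \frac{\Delta O_2 \cdot V}{I_t \cdot SA \cdot 1000}}
#' Because O2 is measured per litre, no density term enters. In the light
#' the flux is reported as net photosynthesis \eqn{P_N}; in the dark the
#' oxygen decline is multiplied by -1 so that respiration \eqn{R} is
#' reported as a positive rate.
#'
#' @param delta_o2 Control-corrected O2 drift, end minus start
#'   (umol L^-1).
#' @inheritParams calcification_rate
#' @param phase `"light"` (returns P_N) or `"dark"` (returns R, sign
#'   flipped).
#' @return Flux in mmol O2 m^-2 h^-1.
#' @examples
#' oxygen_flux_rate(50, 1, 3, 0.0012, phase = "light")   # ~13.89
#' oxygen_flux_rate(-20, 1, 3, 0.0012, phase = "dark")   # positive R
#' @export
oxygen_flux_rate <- function(delta_o2, volume_l, duration_h,
                             surface_area_m2, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  check_interval_geometry(volume_l, duration_h, surface_area_m2)
  flux <- delta_o2 * volume_l / (duration_h * surface_area_m2) / 1000
  if (phase == "dark") -flux else flux
}

#' Gross photosynthesis
#'
#' Gross photosynthesis is the sum of net photosynthesis and dark
#' respiration (both in mmol O2 m^-2 h^-1, R reported positive).
#'
#' @param p_net Net photosynthesis P_N.
#' @param respiration Dark respiration R (positive).
#' @return P_G = P_N + R.
#' @examples
#' gross_photosynthesis(6.4, 5.0)  # 11.4
#' @export
gross_photosynthesis <- function(p_net, respiration) {
  p_net + respiration
}

#' Integrate hourly rates over a photoperiod
#'
#' Daily rates are the stepwise sum of the measured windows,
#' \eqn{\sum_t P(t)\,\Delta t}, never an extrapolation by default: if the
#' measured windows cover less than the declared photoperiod the shortfall
#' is reported via the `coverage_h` attribute and (optionally, behind an
#' explicit flag) scaled up by the mean measured rate.
#'
#' @param rate Hourly rates (mmol m^-2 h^-1), one per window.
#' @param dt Window durations (h), all > 0.
#' @param start_h Optional window start times (h); when given, overlapping
#'   windows are rejected.
#' @param photoperiod_h Optional declared photoperiod (h) for coverage
#'   reporting and extrapolation.
#' @param extrapolate If `TRUE` (and `photoperiod_h` is given), scale the
#'   sum by `photoperiod_h / sum(dt)`; default `FALSE`.
#' @return Daily rate (mmol m^-2 d^-1) with attributes `coverage_h` and,
#'   when a photoperiod is declared, `coverage_frac`.
#' @examples
#' integrate_daily(rep(2, 4), rep(3, 4), photoperiod_h = 12)  # 24
#' @export
integrate_daily <- function(rate, dt, start_h = NULL, photoperiod_h = NULL,
                            extrapolate = FALSE) {
  if (length(rate) != length(dt)) {
    stop("`rate` and `dt` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(dt) | dt <= 0)) {
    stop("window durations `dt` must be positive", call. = FALSE)
  }
  if (!is.null(start_h)) {
    ord <- order(start_h)
    s <- start_h[ord]
    e <- s + dt[ord]
    if (length(s) > 1 && any(s[-1] < e[-length(e)] - 1e-9)) {
      stop("integration windows overlap", call. = FALSE)
    }
  }
  total <- sum(rate * dt)
  coverage <- sum(dt)
  if (isTRUE(extrapolate)) {
    if (is.null(photoperiod_h)) {
      stop("`photoperiod_h` is required to extrapolate", call. = FALSE)
    }
    total <- total * photoperiod_h / coverage
  }
  attr(total, "coverage_h") <- coverage
  if (!is.null(photoperiod_h)) {
    attr(total, "coverage_frac") <- coverage / photoperiod_h
  }
  total
}

check_interval_geometry <- function(volume_l, duration_h, surface_area_m2) {
  if (any(!is.finite(volume_l) | volume_l <= 0)) {
    stop("`volume_l` must be positive", call. = FALSE)
  }
  if (any(!is.finite(duration_h) | duration_h <= 0)) {
    stop("`duration_h` must be positive", call. = FALSE)
  }
  if (any(!is.finite(surface_area_m2) | surface_area_m2 <= 0)) {
    stop("`surface_area_m2` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}
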