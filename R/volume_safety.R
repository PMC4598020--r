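#' Oxygen-state thresholds for chamber safety classification
#'
#' Thresholds used to flag a chamber water sample as metabolically unsafe.
#' Light incubations over a photosynthesising colony are flagged when
#' oxygen climbs above a supersaturation ceiling (zooxanthellae can raise
#' tissue O2 beyond 200% of air saturation, fuelling reactive-oxygen
#' stress); dark incubations are flagged when oxygen falls towards anoxia.
#' Only the 200% supersaturation anchor has a literature basis; the
#' hypoxia and anoxia defaults are package choices, exposed here and
#' stamped into outputs.
#'
#' @param supersaturation_pct Percent of air saturation above which a
#'   light-phase sample is unsafe; default 200.
#' @param hypoxia_pct Percent of air saturation below which a dark-phase
#'   sample is unsafe under the `"hypoxia"` criterion; default 30.
#' @param anoxia_umol_l Absolute O2 floor (umol L^-1) under the
#'   `"anoxia"` criterion; default 5.
#' @param dark_criterion Which dark-phase criterion applies: `"anoxia"`
#'   (absolute floor, the default, matching dark sensitivity trials that
#'   score anoxic conditions) or `"hypoxia"` (stricter, relative to
#'   saturation).
#' @return A validated list of class `"oxygen_thresholds"`.
#' @export
oxygen_state_thresholds <- function(supersaturation_pct = 200,
                                    hypoxia_pct = 30,
                                    anoxia_umol_l = 5,
                                    dark_criterion = c("anoxia",
                                                       "hypoxia")) {
  dark_criterion <- match.arg(dark_criterion)
  if (!(anoxia_umol_l > 0)) {
    stop("`anoxia_umol_l` must be positive", call. = FALSE)
  }
  if (!(hypoxia_pct > 0 && hypoxia_pct < 100)) {
    stop("`hypoxia_pct` must lie in (0, 100)", call. = FALSE)
  }
  if (!(supersaturation_pct > 100)) {
    stop("`supersaturation_pct` must exceed 100", call. = FALSE)
  }
  structure(list(supersaturation_pct = supersaturation_pct,
                 hypoxia_pct = hypoxia_pct,
                 anoxia_umol_l = anoxia_umol_l,
                 dark_criterion = dark_criterion),
            class = "oxygen_thresholds")
}

#' Classify a chamber oxygen state as safe or unsafe
#'
#' @param o2 Dissolved oxygen (umol L^-1), `>= 0`; vectorised.
#' @inheritParams sw_density
#' @param phase `"light"` (supersaturation criterion) or `"dark"`
#'   (anoxia or hypoxia criterion, per the thresholds).
#' @param thresholds An [oxygen_state_thresholds()].
#' @return Logical: `TRUE` = unsafe.
#' @examples
#' th <- oxygen_state_thresholds()
#' classify_oxygen_state(o2_saturation(35, 28), 35, 28, "light", th) # FALSE
#' classify_oxygen_state(0, 35, 28, "dark", th)                      # TRUE
#' @export
classify_oxygen_state <- function(o2, salinity, temperature,
                                  phase = c("light", "dark"),
                                  thresholds = oxygen_state_thresholds()) {
  phase <- match.arg(phase)
  if (any(o2 < 0, na.rm = TRUE)) {
    stop("`o2` must be non-negative", call. = FALSE)
  }
  sat <- o2_saturation(salinity, temperature)
  if (phase == "light") {
    o2 > thresholds$supersaturation_pct / 100 * sat
  } else if (thresholds$dark_criterion == "anoxia") {
    o2 < thresholds$anoxia_umol_l
  } else {
    o2 < thresholds$hypoxia_pct / 100 * sat
  }
}

#' Is a drift detectable above analytic noise?
#'
#' A concentration drift counts as detectable when its magnitude strictly
#' exceeds `k` times the analyte's analytic precision (default k = 3;
#' drifts exactly at the limit are not detectable).
#'
#' @param drift Signed concentration drift(s).
#' @param precision Analytic precision in the same units (> 0); e.g.
#'   2 umol kg^-1 for titration alkalinity, 0.05 umol L^-1 for optode
#'   oxygen.
#' @param k Detection multiple (> 0), default 3.
#' @return Logical, vectorised over `drift`.
#' @examples
#' detectable_change(20, precision = 2)   # TRUE  (20 > 6)
#' detectable_change(6, precision = 2)    # FALSE (boundary)
#' @export
detectable_change <- function(drift, precision, k = 3) {
  if (!(precision > 0) || !(k > 0)) {
    stop("`precision` and `k` must be positive", call. = FALSE)
  }
  abs(drift) > k * precision
}

#' Combined detectable metabolic change
#'
#' A chamber shows a detectable metabolic change only when **both** the
#' alkalinity and the oxygen drifts are individually detectable.
#'
#' @param delta_ta,delta_o2 Signed drifts (umol kg^-1, umol L^-1).
#' @param precision_ta,precision_o2 Analytic precisions; defaults 2 and
#'   0.05.
#' @param k Detection multiple, default 3.
#' @return Logical.
#' @export
detectable_met_change <- function(delta_ta, delta_o2, precision_ta = 2,
                                  precision_o2 = 0.05, k = 3) {
  detectable_change(delta_ta, precision_ta, k) &
    detectable_change(delta_o2, precision_o2, k)
}

#' Replicate consensus code
#'
#' Collapses boolean flags from replicate colonies into the three-level
#' consensus code used in volume sensitivity tables: `"-"` when all
#' replicates are negative, `"+"` when all are positive, `"±"` for a mixed
#' response. Order of replicates is immaterial.
#'
#' @param flags Logical vector (length >= 1, no missing values).
#' @return One of `"-"`, `"±"`, `"+"`.
#' @examples
#' consensus(c(FALSE, FALSE, FALSE))  # "-"
#' consensus(c(TRUE, FALSE, TRUE))    # "±"
#' @export
consensus <- function(flags) {
  if (length(flags) == 0 || !is.logical(flags) || anyNA(flags)) {
    stop("`flags` must be a non-empty logical vector without NA",
         call. = FALSE)
  }
  if (all(flags)) "+" else if (!any(flags)) "-" else "±"
}

#' Build a decision matrix from per-replicate safety flags
#'
#' Aggregates per-replicate oxygen-state and metabolic-change flags into
#' per-(volume, hour, phase) consensus codes, the structure on which
#' [accept_volumes()] operates.
#'
#' @param flags A data frame with columns `volume_ml`, `hour`, `phase`,
#'   `replicate`, `o2_unsafe` (logical), `met_detect` (logical).
#' @return A tibble with columns `volume_ml`, `hour`, `phase`,
#'   `o2_state`, `met_change` (consensus codes) and `n_replicates`.
#' @export
build_decision_matrix <- function(flags) {
  flags <- tibble::as_tibble(flags)
  need <- c("volume_ml", "hour", "phase", "replicate", "o2_unsafe",
            "met_detect")
  missing <- setdiff(need, names(flags))
  if (length(missing) > 0) {
    stop("`flags` is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  flags |>
    dplyr::group_by(.data$volume_ml, .data$hour, .data$phase) |>
    dplyr::summarise(o2_state = consensus(.data$o2_unsafe),
                     met_change = consensus(.data$met_detect),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Apply the chamber-volume acceptance rule
#'
#' A candidate water volume is accepted when, at the decision hour (the
#' flushing interval, default 3 h), the replicate consensus shows **no**
#' unsafe oxygen state (`"-"`) **and** a unanimous detectable metabolic
#' change (`"+"`) in *both* the light and the dark table. This trades off
#' signal strength (small volumes concentrate the signal but exhaust or
#' supersaturate the water) against detectability (large volumes dilute
#' the drift below analytic precision), so acceptance is not monotone in
#' volume.
#'
#' @param matrix A decision matrix: columns `volume_ml`, `hour`, `phase`,
#'   `o2_state`, `met_change` (codes `-`, `±`/`+/-`, `+`), e.g. from
#'   [build_decision_matrix()] or [read_decision_matrix()].
#' @param decision_hour Hour at which the rule is applied; default 3.
#' @return A list: `accepted` (sorted accepted volumes, mL), `minimum`
#'   (smallest accepted, `NA` if none), and `table` (the per-volume
#'   verdicts at the decision hour).
#' @export
accept_volumes <- function(matrix, decision_hour = 3) {
  matrix <- normalise_codes(tibble::as_tibble(matrix))
  at <- dplyr::filter(matrix, .data$hour == decision_hour)
  if (nrow(at) == 0) {
    stop("decision hour ", decision_hour, " is not present in the matrix",
         call. = FALSE)
  }
  verdict <- at |>
    dplyr::group_by(.data$volume_ml) |>
    dplyr::summarise(
      n_phases = dplyr::n_distinct(.data$phase),
      accepted = all(.data$o2_state == "-") &&
        all(.data$met_change == "+") &&
        dplyr::n_distinct(.data$phase) == 2,
      .groups = "drop")
  if (any(verdict$n_phases != 2)) {
    stop("both light and dark codes are required at the decision hour",
         call. = FALSE)
  }
  accepted <- sort(verdict$volume_ml[verdict$accepted])
  list(accepted = accepted,
       minimum = if (length(accepted) > 0) min(accepted) else NA_real_,
       table = dplyr::select(verdict, "volume_ml", "accepted"))
}

normalise_codes <- function(matrix) {
  need <- c("volume_ml", "hour", "phase", "o2_state", "met_change")
  missing <- setdiff(need, names(matrix))
  if (length(missing) > 0) {
    stop("decision matrix is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fix <- function(x) {
    x <- trimws(x)
    x[x %in% c("+/-", "-/+", "+-", "pm")] <- "±"
    x[x %in% c("–", "—")] <- "-"  # en/em dash transcriptions
    bad <- !x %in% c("-", "±", "+")
    if (any(bad)) {
      stop("invalid consensus code(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    x
  }
  matrix$o2_state <- fix(matrix$o2_state)
  matrix$met_change <- fix(matrix$met_change)
  matrix
}

#' Read a decision-matrix encoding from CSV
#'
#' Reads a consensus-code table (columns `volume_ml`, `hour`, `phase`,
#' `o2_state`, `met_change`; codes `-`, `+`, `±` or the ASCII alias
#' `+/-`). The package ships one such encoding,
#' `decision_matrix_acropora.csv`, transcribing a published volume-ladder
#' sensitivity trial on *Acropora* sp. (three replicate colonies, volumes
#' 250--1500 mL, hourly samples over 4 h, light and dark).
#'
#' @param path CSV file; defaults to the packaged *Acropora* encoding.
#' @return A validated decision-matrix tibble.
#' @examples
#' m <- read_decision_matrix()
#' accept_volumes(m, decision_hour = 3)$accepted  # 1000 1250
#' @export
read_decision_matrix <- function(path = system.file(
  "extdata", "decision_matrix_acropora.csv", package = "chamberflux")) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         volume_ml = readr::col_double(),
                         hour = readr::col_double(),
                         phase = readr::col_character(),
                         o2_state = readr::col_character(),
                         met_change = readr::col_character()))
  if (any(!m$phase %in% c("light", "dark"))) {
    stop("`phase` must be 'light' or 'dark'", call. = FALSE)
  }
  normalise_codes(m)
}

#' Water-extraction error budget
#'
#' The chamber volume enters every rate linearly, so water left
#' unaccounted for after syringe re-extraction biases each rate by its
#' fraction of the reference volume. This computes the per-sample relative
#' error (%) against the bench reference volume, plus its mean, maximum
#' and the per-millilitre error rate.
#'
#' @param unaccounted_ml Unaccounted water volumes (mL), `>= 0`.
#' @param reference_ml Bench reference volume (mL), > 0; default 250, the
#'   volume used in the 30-replicate extraction bench test.
#' @return A list: `per_sample_pct`, `mean_pct`, `max_pct`,
#'   `per_ml_pct` (= 100 / reference_ml).
#' @examples
#' extraction_error(c(0.5, 2, 5))$mean_pct  # 1%
#' @export
extraction_error <- function(unaccounted_ml, reference_ml = 250) {
  if (!(reference_ml > 0)) {
    stop("`reference_ml` must be positive", call. = FALSE)
  }
  if (any(unaccounted_ml < 0, na.rm = TRUE)) {
    stop("`unaccounted_ml` must be non-negative", call. = FALSE)
  }
  per <- unaccounted_ml / reference_ml * 100
  list(per_sample_pct = per,
       mean_pct = mean(per),
       max_pct = max(per),
       per_ml_pct = 100 / reference_ml)
}
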