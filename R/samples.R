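#' @importFrom rlang .data
NULL

# canonical sample-log schema shared by the reader, the simulator and the
# rate-reduction stage; one row = one chamber x time-point water sample
sample_log_cols <- c("chamber_id", "role", "phase", "cycle", "time_h",
                     "ta", "o2", "salinity", "temperature")

#' Validate a chamber sample log
#'
#' Checks the canonical sample-log schema used throughout the pipeline:
#' one row per chamber per sampled time point, carrying total alkalinity
#' (umol kg^-1), dissolved oxygen (umol L^-1), salinity and temperature.
#' Violations are reported with the offending row numbers; duplicate
#' (chamber, phase, time) keys are rejected outright because they make
#' start/end pairing ambiguous.
#'
#' @param samples A data frame with columns `chamber_id`, `role`
#'   (`"treatment"` or `"control"`), `phase` (`"light"` or `"dark"`),
#'   `cycle` (identifier of the sealed incubation cycle), `time_h`
#'   (fractional hours since incubation start), `ta`, `o2`, `salinity`,
#'   `temperature`. Extra columns (site, day, pH, volumes) pass through.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_sample_log <- function(samples) {
  samples <- tibble::as_tibble(samples)
  missing <- setdiff(sample_log_cols, names(samples))
  if (length(missing) > 0) {
    stop("sample log is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0) {
    warning("sample log is empty", call. = FALSE)
    return(samples)
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop("sample log: ", what, " in row(s) ",
           paste(utils::head(rows, 10), collapse = ", "), call. = FALSE)
    }
  }
  bad(!samples$role %in% c("treatment", "control"),
      "`role` must be 'treatment' or 'control'")
  bad(!samples$phase %in% c("light", "dark"),
      "`phase` must be 'light' or 'dark'")
  bad(!is.finite(samples$time_h) | samples$time_h < 0,
      "`time_h` must be finite and >= 0")
  bad(!is.finite(samples$ta) | samples$ta <= 0, "`ta` must be positive")
  bad(!is.finite(samples$o2) | samples$o2 < 0, "`o2` must be non-negative")
  bad(!is.finite(samples$salinity) |
        samples$salinity < 0 | samples$salinity > 45,
      "`salinity` must lie in [0, 45]")
  key <- paste(samples$chamber_id, samples$phase, samples$time_h)
  bad(duplicated(key), "duplicate (chamber, phase, time) key")
  invisible(samples)
}

#' Chamber water volume from volume accounting
#'
#' The working water volume of a flexible incubation chamber is determined
#' per deployment as the volume extracted for the sample aliquot (nominally
#' 0.100 L) plus the residual volume recovered when the chamber is emptied
#' by syringe. A bench-test shortfall (water unaccounted for after
#' re-extraction) may be recorded separately; it contributes to the error
#' budget (see [extraction_error()]), not to the working volume.
#'
#' @param extracted_l Extracted sample aliquot (L), `>= 0`.
#' @param residual_l Residual chamber water recovered on emptying (L),
#'   `>= 0`.
#' @return Total working volume (L), strictly positive; vectorised.
#' @examples
#' chamber_volume(0.100, 0.975)  # 1.075 L
#' @export
chamber_volume <- function(extracted_l, residual_l) {
  if (any(extracted_l < 0, na.rm = TRUE) ||
      any(residual_l < 0, na.rm = TRUE)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  total <- extracted_l + residual_l
  if (any(!is.finite(total) | total <= 0)) {
    stop("total chamber volume must be positive", call. = FALSE)
  }
  total
}

#' Validate a colony metadata table
#'
#' @param colonies A data frame with columns `colony_id`, `chamber_id`,
#'   `surface_area_m2` (> 0) and optionally `species` and `site`.
#' @return The validated tibble, invisibly.
#' @export
validate_colony_metadata <- function(colonies) {
  colonies <- tibble::as_tibble(colonies)
  missing <- setdiff(c("colony_id", "chamber_id", "surface_area_m2"),
                     names(colonies))
  if (length(missing) > 0) {
    stop("colony metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(colonies$surface_area_m2) |
            colonies$surface_area_m2 <= 0)) {
    stop("`surface_area_m2` must be positive for every colony",
         call. = FALSE)
  }
  if (anyDuplicated(colonies$chamber_id) > 0) {
    stop("each chamber may hold at most one colony", call. = FALSE)
  }
  invisible(colonies)
}
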