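#' Pseudo individual-patient data
#'
#' A minimal right-censored survival dataset: one row per patient with an
#' observation time in months and an event indicator (1 = progression/death
#' observed, 0 = censored). These records stand in for the patient-level
#' data behind published Kaplan-Meier curves, which are never deposited and
#' must be emulated when a published model is rebuilt.
#'
#' @param time Non-negative, finite observation times in months.
#' @param event Event indicators, each 0 or 1.
#' @return A `data.frame` of class `pseudo_ipd` with columns `time`, `event`.
#' @export
pseudo_ipd <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) < 1L) stop("pseudo_ipd: at least one record required",
                              call. = FALSE)
  if (length(time) != length(event)) {
    stop("pseudo_ipd: `time` and `event` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("pseudo_ipd: times must be finite and >= 0", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("pseudo_ipd: event indicators must be 0 or 1", call. = FALSE)
  }
  structure(data.frame(time = time, event = event),
            class = c("pseudo_ipd", "data.frame"))
}

#' Digitized Kaplan-Meier curve coordinates
#'
#' A set of (time, survival) points as produced by digitizing a published
#' Kaplan-Meier figure: times strictly increasing starting at 0, survival
#' starting at 1 and non-increasing.
#'
#' @param time Strictly increasing times in months, first element 0.
#' @param survival Non-increasing survival probabilities in \[0, 1\], first
#'   element 1.
#' @return A `data.frame` of class `km_points` with columns `time`,
#'   `survival`.
#' @export
km_points <- function(time, survival) {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) < 1L || length(time) != length(survival)) {
    stop("km_points: need equal-length, non-empty `time` and `survival`",
         call. = FALSE)
  }
  if (time[1] != 0) stop("km_points: first time must be 0", call. = FALSE)
  if (abs(survival[1] - 1) > 1e-12) {
    stop("km_points: survival at time 0 must be 1", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("km_points: times must be strictly increasing", call. = FALSE)
  }
  if (any(survival < 0 | survival > 1)) {
    stop("km_points: survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("km_points: survival must be non-increasing", call. = FALSE)
  }
  structure(data.frame(time = time, survival = survival),
            class = c("km_points", "data.frame"))
}

#' Read / write the two-column CSV dialects
#'
#' `pseudo_ipd` serializes as `time,event`; `km_points` as `time,survival`
#' (header row, times in months).
#'
#' @param x Object to write.
#' @param path File path.
#' @return `read_*` return the validated object; `write_*` return `path`
#'   invisibly.
#' @name ipd_io
NULL

#' @rdname ipd_io
#' @export
write_ipd <- function(x, path) {
  stopifnot(inherits(x, "pseudo_ipd"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  pseudo_ipd(d$time, d$event)
}

#' @rdname ipd_io
#' @export
write_km_points <- function(x, path) {
  stopifnot(inherits(x, "km_points"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_km_points <- function(path) {
  d <- utils::read.csv(path)
  km_points(d$time, d$survival)
}
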