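#' Saturation-offset schedules
#'
#' An offset schedule is the ordered set of saturation frequency offsets (in
#' ppm relative to water) at which a Z-spectrum is sampled, plus the far
#' off-resonance control offset used for normalization.
#'
#' @param offsets_ppm Numeric vector of offsets in ppm. Sorted ascending and
#'   deduplicated.
#' @param control_ppm Control (normalization) offset in ppm; must lie far
#'   outside the sampled range.
#' @return An `offset_schedule` object.
#' @seealso [build_offset_schedule()] for the default acquisition schedule.
#' @export
offset_schedule <- function(offsets_ppm, control_ppm = 500) {
  stopifnot(is.numeric(offsets_ppm), length(offsets_ppm) >= 1,
            all(is.finite(offsets_ppm)), is.numeric(control_ppm),
            length(control_ppm) == 1, is.finite(control_ppm))
  offsets_ppm <- sort(unique(offsets_ppm))
  # the control must sit far off-resonance; it may itself be a sampled offset
  if (abs(control_ppm) < 50 || abs(control_ppm) < max(abs(offsets_ppm)))
    stop("control offset must lie far outside the sampled ppm range")
  structure(list(offsets_ppm = offsets_ppm, control_ppm = control_ppm),
            class = "offset_schedule")
}

#' Build the default dual-power acquisition schedule
#'
#' The union of a sparse outer grid (±10 to ±6.25 ppm, step 1.25 ppm) and a
#' dense inner grid (−5 to +5 ppm, step 0.125 ppm), 89 offsets in total, with
#' the control image at 500 ppm.
#'
#' @return An [offset_schedule()] of length 89.
#' @examples
#' sched <- build_offset_schedule()
#' length(sched$offsets_ppm)
#' @export
build_offset_schedule <- function() {
  sparse <- c(seq(-10, -6.25, by = 1.25), seq(6.25, 10, by = 1.25))
  dense <- seq(-5, 5, by = 0.125)
  offset_schedule(c(sparse, dense), control_ppm = 500)
}

#' @export
print.offset_schedule <- function(x, ...) {
  cat(sprintf("<offset_schedule> %d offsets, %.3g to %.3g ppm, control at %g ppm\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
              x$control_ppm))
  invisible(x)
}

#' @export
length.offset_schedule <- function(x) length(x$offsets_ppm)

#' @exportS3Method tibble::as_tibble
as_tibble.offset_schedule <- function(x, ...) {
  tibble(index = seq_along(x$offsets_ppm), offset_ppm = x$offsets_ppm)
}
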