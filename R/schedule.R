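#' Sequential BrdU addition schedule
#'
#' Describes the labelling regime in which BrdU is added to the culture
#' medium in equal concentration steps at fixed time intervals until a
#' maximum concentration is reached, which is then held. The resulting
#' medium concentration is a non-decreasing step function of time: zero
#' before `start_time`, rising by `step_increment` every `step_interval`
#' minutes, and constant at `max_concentration` from the end of the ramp
#' onwards. Defaults correspond to 0.5 uM added every 2.5 min up to 12 uM,
#' followed by a 60 min hold.
#'
#' @param step_interval Minutes between successive additions.
#' @param step_increment Concentration added at each step (uM). Must divide
#'   `max_concentration` exactly.
#' @param max_concentration Final medium concentration (uM).
#' @param hold_duration Minutes the maximum concentration is held before
#'   harvest.
#' @param start_time Simulation time (minutes) of the first addition.
#' @return An object of class `label_schedule`.
#' @seealso [schedule_concentration()], [incorporation_model()]
#' @export
label_schedule <- function(step_interval = 2.5, step_increment = 0.5,
                           max_concentration = 12, hold_duration = 60,
                           start_time = 0) {
  stopifnot(step_interval > 0, step_increment > 0, max_concentration > 0,
            hold_duration >= 0)
  n_steps <- max_concentration / step_increment
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("`max_concentration` must be an integer multiple of `step_increment`")
  }
  structure(
    list(step_interval = step_interval,
         step_increment = step_increment,
         max_concentration = max_concentration,
         hold_duration = hold_duration,
         start_time = start_time),
    class = "label_schedule"
  )
}

#' Medium BrdU concentration at given times
#'
#' @param schedule A [label_schedule()].
#' @param time Numeric vector of simulation times (minutes).
#' @return Concentrations (uM), same length as `time`. The function is a
#'   non-decreasing step function: the first addition takes effect at
#'   `start_time` and the maximum concentration persists indefinitely
#'   (positions replicated after the nominal hold are treated as replicated
#'   at the plateau concentration).
#' @export
schedule_concentration <- function(schedule, time) {
  stopifnot(inherits(schedule, "label_schedule"))
  rel <- time - schedule$start_time
  steps <- 1 + floor(rel / schedule$step_interval)
  conc <- pmin(schedule$max_concentration, steps * schedule$step_increment)
  conc[rel < 0] <- 0
  conc
}

#' Duration of the concentration ramp
#'
#' Time from the first addition until the maximum concentration is reached.
#' @param schedule A [label_schedule()].
#' @return Minutes.
#' @export
schedule_ramp_duration <- function(schedule) {
  n_steps <- round(schedule$max_concentration / schedule$step_increment)
  (n_steps - 1) * schedule$step_interval
}

#' End of the labelling period
#'
#' @param schedule A [label_schedule()].
#' @return Simulation time (minutes) at which the hold finishes (harvest).
#' @export
schedule_label_end <- function(schedule) {
  schedule$start_time + schedule_ramp_duration(schedule) +
    schedule$hold_duration
}

#' @export
print.label_schedule <- function(x, ...) {
  cat(sprintf(
    "<label_schedule> +%g uM every %g min to %g uM (start t=%g), hold %g min\n",
    x$step_increment, x$step_interval, x$max_concentration, x$start_time,
    x$hold_duration))
  invisible(x)
}

#' Concentration-dependent BrdU incorporation model
#'
#' Saturating (hyperbolic) relationship between the medium BrdU
#' concentration and the fraction of thymidine positions substituted with
#' BrdU in DNA synthesized at that concentration:
#' `f(c) = max_fraction * c / (c + saturation_constant)`.
#'
#' The defaults are calibrated so that `f(1.5) = 0.35` and `f(10) = 0.65`,
#' the modal incorporation levels observed on nascent DNA at 1.5 uM and
#' 10 uM treatments.
#'
#' @param saturation_constant Half-saturation concentration (uM).
#' @param max_fraction Asymptotic incorporated fraction in `[0, 1]`.
#' @return An object of class `incorporation_model`.
#' @export
incorporation_model <- function(saturation_constant = 1.7822,
                                max_fraction = 0.7659) {
  stopifnot(saturation_constant > 0,
            max_fraction > 0, max_fraction <= 1)
  structure(
    list(saturation_constant = saturation_constant,
         max_fraction = max_fraction),
    class = "incorporation_model"
  )
}

#' Incorporated BrdU fraction at given concentrations
#'
#' @param model An [incorporation_model()].
#' @param concentration Concentrations (uM), non-negative.
#' @return Fractions in `[0, max_fraction)`; `f(0) = 0`, monotone increasing.
#' @export
incorporation_fraction <- function(model, concentration) {
  stopifnot(inherits(model, "incorporation_model"),
            all(concentration >= 0))
  model$max_fraction * concentration /
    (concentration + model$saturation_constant)
}

#' Per-thymidine probability emission model
#'
#' Describes how a base caller emits a BrdU probability for each thymidine
#' position. Probabilities are drawn from a two-component mixture on the
#' unit interval: with weight equal to the local incorporated fraction the
#' BrdU component is used, otherwise the background (thymidine) component.
#' Component shapes are Beta distributions chosen in closed form so that at
#' the call threshold 0.5:
#' * the background emits a probability `>= 0.5` with rate `fpr`
#'   (`Beta(1, log2(1/fpr))`), and
#' * the BrdU component emits `< 0.5` with rate `fnr_at_full`
#'   (`Beta(log2(1/fnr_at_full), 1)`).
#'
#' Hence the expected call rate on a region with incorporated fraction `f`
#' is exactly `f * (1 - fnr_at_full) + (1 - f) * fpr`.
#'
#' @param fpr False positive rate: probability that an unsubstituted
#'   thymidine is emitted with probability `>= 0.5`. Default 0.001.
#' @param fnr_at_full False negative rate on fully substituted DNA.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(fpr = 0.001, fnr_at_full = 0.02) {
  stopifnot(fpr >= 0, fpr < 0.5, fnr_at_full >= 0, fnr_at_full < 0.5)
  structure(
    list(fpr = fpr,
         fnr_at_full = fnr_at_full,
         # Beta shape parameters; NA marks the degenerate (noise-free) case
         background_shape2 = if (fpr > 0) log2(1 / fpr) else NA_real_,
         brdu_shape1 = if (fnr_at_full > 0) log2(1 / fnr_at_full) else NA_real_),
    class = "emission_model"
  )
}

# Draw n probabilities from the background (thymidine) component.
remit_background <- function(emission, n) {
  if (is.na(emission$background_shape2)) {
    0.5 * stats::runif(n)
  } else {
    stats::rbeta(n, 1, emission$background_shape2)
  }
}

# Draw n probabilities from the BrdU component.
remit_brdu <- function(emission, n) {
  if (is.na(emission$brdu_shape1)) {
    0.5 + 0.5 * stats::runif(n)
  } else {
    stats::rbeta(n, emission$brdu_shape1, 1)
  }
}
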