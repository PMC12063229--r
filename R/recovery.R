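#' Initiation events the labelling design can resolve
#'
#' Not every true initiation is visible to the fork caller: a fork only
#' produces a calling-strength gradient while the incorporated-fraction
#' curve is steep, i.e. while the medium concentration at replication is
#' low. Because incorporation saturates with concentration, temporal (and
#' hence gradient) resolution falls through the ramp and vanishes during
#' the hold. This function marks, from ground truth alone, the initiation
#' events whose two flanking forks each sustain at least `min_windows`
#' consecutive windows of expected gradient magnitude at or above the
#' fork-calling threshold within their true extent — the events a correct
#' caller can be expected to recover. Two refinements make this
#' predictive for the actual estimator: the gradient run must start at the
#' origin itself (initiations that fired long before labelling produce
#' wide, unlocalizable minima whose gradients sit far from the origin),
#' and the required mean gradient is raised by the total-variation
#' shrinkage bias, about `2 * alpha / min_windows`, which the regularized
#' derivative subtracts from a segment's true slope.
#'
#' @param truths List of `molecule_truth` objects.
#' @param schedule A [label_schedule()].
#' @param incorporation An [incorporation_model()].
#' @param cfg A [fork_caller_config()] (threshold and percent scale).
#' @param min_windows Required run length per fork (default 10).
#' @param window_bp Approximate genomic width of one window (bp); default
#'   1000, matching 290 thymidines at density 0.29.
#' @return A `data.frame` with one row per true initiation event on a
#'   nascent strand: `read_id`, `position`, `time`, `eligible`.
#' @export
eligible_initiations <- function(truths, schedule, incorporation,
                                 cfg = fork_caller_config(),
                                 min_windows = 10, window_bp = 1000) {
  rows <- lapply(truths, function(tr) {
    ev <- tr$initiation_events
    if (!tr$is_nascent_strand || nrow(ev) == 0) return(NULL)
    fs <- tr$fork_segments
    elig <- vapply(seq_len(nrow(ev)), function(i) {
      x0 <- ev$position[i]; tau <- ev$time[i]
      left_ext <- {
        j <- which(fs$direction == "left" & abs(fs$end - x0) < 1e-6)
        if (length(j) == 0) 0 else x0 - fs$start[j[1]]
      }
      right_ext <- {
        j <- which(fs$direction == "right" & abs(fs$start - x0) < 1e-6)
        if (length(j) == 0) 0 else fs$end[j[1]] - x0
      }
      # the total-variation penalty shrinks a length-l segment's estimated
      # slope by about 2 * alpha / l, so a fork is reliably callable only
      # when its true mean gradient clears the threshold plus that bias
      eff_threshold <- cfg$pos_threshold + 2 * cfg$alpha / min_windows
      side_ok <- function(extent) {
        if (extent < min_windows * window_bp) return(FALSE)
        w_min <- window_bp / tr$fork_speed   # minutes per window
        f0 <- incorporation_fraction(
          incorporation, schedule_concentration(schedule, tau))
        f1 <- incorporation_fraction(
          incorporation,
          schedule_concentration(schedule, tau + min_windows * w_min))
        slope <- cfg$percent_scale * (f1 - f0) / min_windows
        slope >= eff_threshold
      }
      side_ok(left_ext) && side_ok(right_ext)
    }, TRUE)
    data.frame(read_id = tr$read_id, position = ev$position,
               time = ev$time, eligible = elig)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(read_id = character(0), position = numeric(0),
                      time = numeric(0), eligible = logical(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Match called initiation sites to planted events
#'
#' A true initiation is recovered when a called initiation site on the
#' same read contains it or lies within `max_dist` of it (midpoint
#' distance). The localization error of a recovered event is the distance
#' from the matched site's midpoint to the true origin position.
#'
#' @param sites Called initiation sites (`read_id`, `start`, `end`).
#' @param events True events (`read_id`, `position`), e.g. from
#'   [eligible_initiations()].
#' @param max_dist Maximum midpoint distance for a match (default 25 kb).
#' @return The `events` table with `recovered` and `error_bp` columns.
#' @export
match_initiations <- function(sites, events, max_dist = 25000) {
  if (nrow(events) == 0) {
    events$recovered <- logical(0)
    events$error_bp <- numeric(0)
    return(events)
  }
  events$recovered <- FALSE
  events$error_bp <- NA_real_
  for (i in seq_len(nrow(events))) {
    s <- sites[sites$read_id == events$read_id[i], , drop = FALSE]
    if (nrow(s) == 0) next
    x0 <- events$position[i]
    mid <- (s$start + s$end) / 2
    contains <- s$start <= x0 & x0 < s$end
    dist <- abs(mid - x0)
    hit <- which(contains | dist <= max_dist)
    if (length(hit) > 0) {
      best <- hit[which.min(dist[hit])]
      events$recovered[i] <- TRUE
      events$error_bp[i] <- dist[best]
    }
  }
  events
}

#' Direction agreement between called forks and ground truth
#'
#' Each called fork is matched to the true fork segment containing its
#' midpoint on the same molecule; agreement is the fraction of matched
#' forks whose called direction equals the true direction.
#'
#' @param forks Called forks (`read_id`, `start`, `end`, `direction`).
#' @param truths List of `molecule_truth` objects.
#' @return A list with `n_matched`, `n_agree`, `agreement`.
#' @export
fork_direction_agreement <- function(forks, truths) {
  truth_by_id <- stats::setNames(truths,
                                 vapply(truths, `[[`, "", "read_id"))
  n_matched <- 0L
  n_agree <- 0L
  for (i in seq_len(nrow(forks))) {
    tr <- truth_by_id[[forks$read_id[i]]]
    if (is.null(tr)) next
    mid <- (forks$start[i] + forks$end[i]) / 2
    fs <- tr$fork_segments
    j <- which(fs$start <= mid & mid < fs$end)
    if (length(j) == 0) next
    n_matched <- n_matched + 1L
    if (fs$direction[j[1]] == forks$direction[i]) n_agree <- n_agree + 1L
  }
  list(n_matched = n_matched, n_agree = n_agree,
       agreement = if (n_matched > 0) n_agree / n_matched else NA_real_)
}

#' Summarize recovery of planted initiations
#'
#' Runs the matching and direction-agreement comparisons for a simulated
#' dataset and its calls.
#'
#' @param calls Result of [call_reads()].
#' @param truths List of `molecule_truth` objects.
#' @param schedule,incorporation,cfg Simulation and calling configuration.
#' @param min_windows,window_bp,max_dist See [eligible_initiations()] and
#'   [match_initiations()].
#' @return A list with the annotated `events` table, `recovery_rate`
#'   (among eligible events), `median_error_bp` (recovered eligible
#'   events), and `direction` (see [fork_direction_agreement()]).
#' @export
compare_to_truth <- function(calls, truths, schedule,
                             incorporation = incorporation_model(),
                             cfg = fork_caller_config(),
                             min_windows = 10, window_bp = 1000,
                             max_dist = 25000) {
  ev <- eligible_initiations(truths, schedule, incorporation, cfg,
                             min_windows, window_bp)
  ev <- match_initiations(calls$initiations, ev, max_dist)
  el <- ev[ev$eligible, , drop = FALSE]
  list(events = ev,
       n_eligible = nrow(el),
       recovery_rate = if (nrow(el) > 0) mean(el$recovered) else NA_real_,
       median_error_bp = if (any(el$recovered)) {
         stats::median(el$error_bp[el$recovered])
       } else NA_real_,
       direction = fork_direction_agreement(calls$forks, truths))
}
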