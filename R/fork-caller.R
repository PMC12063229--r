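#' Segment a denoised derivative into directional fork calls
#'
#' Maximal runs of consecutive windows whose derivative exceeds
#' `pos_threshold` become rightward forks; runs below `neg_threshold`
#' become leftward forks. Runs shorter than `min_segment_windows` are
#' discarded. Under the rising-concentration labelling regime a rightward
#' fork replicates later (higher-BrdU) sequence to the right, so the sign
#' of the windowed-BrdU gradient is the fork direction.
#'
#' @param u Derivative per window (percent per window), as returned by
#'   [tv_derivative()].
#' @param track A `windowed_track` aligned with `u` (same windows).
#' @param cfg A [fork_caller_config()].
#' @return A `data.frame` of fork calls: `read_id`, `chrom`, `start`,
#'   `end`, `direction` (`"left"`/`"right"`), `mean_derivative`,
#'   `n_windows`, `first_window`, `last_window`; ordered by coordinate,
#'   non-overlapping.
#' @export
segment_forks <- function(u, track, cfg = fork_caller_config()) {
  stopifnot(inherits(track, "windowed_track"),
            length(u) == nrow(track$windows))
  state <- ifelse(u > cfg$pos_threshold, 1L,
                  ifelse(u < cfg$neg_threshold, -1L, 0L))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- runs$values != 0L & runs$lengths >= cfg$min_segment_windows
  w <- track$windows
  out <- data.frame(
    read_id = rep(track$read_id, sum(sel)),
    chrom = rep(track$chrom, sum(sel)),
    start = w$start[starts[sel]],
    end = w$end[ends[sel]],
    direction = ifelse(runs$values[sel] > 0, "right", "left"),
    mean_derivative = vapply(which(sel), function(i) {
      mean(u[starts[i]:ends[i]])
    }, 0),
    n_windows = runs$lengths[sel],
    first_window = starts[sel],
    last_window = ends[sel])
  out[order(out$start), , drop = FALSE]
}

#' Pair adjacent divergent/convergent forks into initiation and
#' termination sites
#'
#' On one read, every adjacent pair of fork calls in coordinate order that
#' is divergent (leftward fork then rightward fork) defines an initiation
#' site over the inter-fork gap, and every convergent pair (rightward then
#' leftward) a termination site. The gap width is the site's resolution.
#' Unpaired edge forks produce no event. Abutting forks (zero-width gap)
#' are widened by 1 bp on each side of the shared boundary so that
#' resolution is at least 1 bp.
#'
#' @param forks Fork calls for a single read, as from [segment_forks()].
#' @return `list(initiations = <data.frame>, terminations = <data.frame>)`,
#'   each with columns `read_id`, `chrom`, `start`, `end`, `resolution`,
#'   `flank_left`, `flank_right` (row indices into `forks`).
#' @export
pair_events <- function(forks) {
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      resolution = numeric(0), flank_left = integer(0),
                      flank_right = integer(0))
  if (nrow(forks) < 2) return(list(initiations = empty, terminations = empty))
  if (length(unique(forks$read_id)) != 1) {
    stop("pair_events expects forks from a single read")
  }
  if (any(forks$start[-1] < forks$end[-nrow(forks)])) {
    stop("internal error: overlapping fork calls")
  }
  i <- seq_len(nrow(forks) - 1)
  gap_start <- forks$end[i]
  gap_end <- forks$start[i + 1]
  zero <- gap_start >= gap_end
  gap_start[zero] <- gap_start[zero] - 1
  gap_end[zero] <- gap_end[zero] + 1
  make <- function(sel) {
    data.frame(read_id = forks$read_id[sel], chrom = forks$chrom[sel],
               start = gap_start[sel], end = gap_end[sel],
               resolution = gap_end[sel] - gap_start[sel],
               flank_left = sel, flank_right = sel + 1L)
  }
  div <- which(forks$direction[i] == "left" &
                 forks$direction[i + 1] == "right")
  con <- which(forks$direction[i] == "right" &
                 forks$direction[i + 1] == "left")
  list(initiations = make(div), terminations = make(con))
}

#' Keep only high-resolution sites
#'
#' Sites whose resolution (inter-fork gap width) is strictly below
#' `max_resolution` are most likely to stem from a single event.
#'
#' @param sites Initiation or termination sites from [pair_events()].
#' @param max_resolution Bp; default 5000 (`< 5 kb`, strict).
#' @return The filtered `data.frame`.
#' @export
filter_high_resolution <- function(sites, max_resolution = 5000) {
  sites[sites$resolution < max_resolution, , drop = FALSE]
}

#' Call replication dynamics on one read
#'
#' Composition of the full single-read pipeline: windowed BrdU fractions,
#' total-variation regularized differentiation on the percent scale, fork
#' segmentation, and divergent/convergent pairing into initiation and
#' termination sites. Deterministic.
#'
#' @param read A [brdu_read()].
#' @param window_size_t Thymidines per window.
#' @param threshold Per-position call threshold.
#' @param cfg A [fork_caller_config()].
#' @return An object of class `read_calls`: list with `track`
#'   (`windowed_track`), `derivative`, `forks`, `initiations`,
#'   `terminations`. Reads with fewer than 4 windows yield empty calls.
#' @export
call_read <- function(read, window_size_t = 290, threshold = 0.5,
                      cfg = fork_caller_config()) {
  track <- suppressWarnings(window_fractions(read, window_size_t, threshold))
  if (nrow(track$windows) < 4) {
    track0 <- track
    track0$windows <- track0$windows[0, , drop = FALSE]
    empty_forks <- segment_forks(numeric(0), track0, cfg)
    ev <- pair_events(empty_forks)
    res <- list(track = track, derivative = numeric(0), forks = empty_forks,
                initiations = ev$initiations, terminations = ev$terminations)
    return(structure(res, class = "read_calls"))
  }
  y <- track$windows$fraction_brdu * cfg$percent_scale
  u <- tv_derivative(y, cfg)
  forks <- segment_forks(u, track, cfg)
  ev <- pair_events(forks)
  structure(
    list(track = track, derivative = u, forks = forks,
         initiations = ev$initiations, terminations = ev$terminations),
    class = "read_calls")
}

#' @export
print.read_calls <- function(x, ...) {
  cat(sprintf("<read_calls> %s: %d forks, %d initiations, %d terminations\n",
              x$track$read_id, nrow(x$forks), nrow(x$initiations),
              nrow(x$terminations)))
  invisible(x)
}

#' Call replication dynamics on a set of reads
#'
#' Applies [call_read()] to every nascent read (overall BrdU fraction at
#' least `cfg$nascent_threshold`; parental reads carry no labelling
#' gradient and are skipped). Returns pooled call tables.
#'
#' @param reads List of [brdu_read()] objects.
#' @param window_size_t,threshold,cfg As in [call_read()].
#' @param nascent_only If `FALSE`, parental reads are processed too.
#' @return A list with pooled `data.frame`s `forks`, `initiations`,
#'   `terminations`, the per-read `calls` (named by read_id, nascent reads
#'   only), and `n_nascent` / `n_reads` counts.
#' @export
call_reads <- function(reads, window_size_t = 290, threshold = 0.5,
                       cfg = fork_caller_config(), nascent_only = TRUE) {
  nascent <- vapply(reads, function(r) {
    if (length(r$positions) == 0) return(FALSE)
    classify_nascent(r, cfg$nascent_threshold, threshold)$is_nascent
  }, TRUE)
  use <- if (nascent_only) reads[nascent] else reads
  calls <- lapply(use, call_read, window_size_t = window_size_t,
                  threshold = threshold, cfg = cfg)
  names(calls) <- vapply(use, `[[`, "", "read_id")
  empty_forks <- data.frame(read_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            direction = character(0),
                            mean_derivative = numeric(0),
                            n_windows = integer(0),
                            first_window = integer(0),
                            last_window = integer(0))
  empty_sites <- data.frame(read_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            resolution = numeric(0), flank_left = integer(0),
                            flank_right = integer(0))
  pool <- function(field, empty) {
    parts <- lapply(calls, `[[`, field)
    if (length(parts) == 0) return(empty)
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  list(forks = pool("forks", empty_forks),
       initiations = pool("initiations", empty_sites),
       terminations = pool("terminations", empty_sites), calls = calls,
       n_nascent = sum(nascent), n_reads = length(reads))
}
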