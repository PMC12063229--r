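#' Binary BrdU calls from per-thymidine probabilities
#'
#' A thymidine position is called BrdU when its probability reaches the
#' threshold (`>=`, default 0.5).
#'
#' @param read A [brdu_read()].
#' @param threshold Call threshold in (0, 1).
#' @return Integer vector of 0/1 calls, one per thymidine position.
#' @export
call_brdu <- function(read, threshold = 0.5) {
  stopifnot(inherits(read, "brdu_read"), threshold > 0, threshold < 1)
  as.integer(read$probabilities >= threshold)
}

#' Windowed BrdU incorporation fractions
#'
#' Partitions a read's thymidine positions into consecutive, independent
#' (non-overlapping) windows of exactly `window_size_t` thymidines and
#' computes the fraction of BrdU calls in each. Remainder thymidines at the
#' 3' end that do not fill a window are dropped. The genomic interval of a
#' window spans its first to one past its last member thymidine.
#'
#' @param read A [brdu_read()].
#' @param window_size_t Thymidines per window (default 290, about 1 kb of
#'   human sequence).
#' @param threshold Call threshold passed to [call_brdu()].
#' @return An object of class `windowed_track`: a list with `read_id`,
#'   `chrom`, `window_size_t`, `call_threshold` and `windows`, a
#'   `data.frame` with columns `start`, `end`, `n_thymidines`,
#'   `fraction_brdu`. Zero windows (with a warning) if the read has fewer
#'   than `window_size_t` thymidines.
#' @export
window_fractions <- function(read, window_size_t = 290, threshold = 0.5) {
  stopifnot(inherits(read, "brdu_read"), window_size_t >= 1)
  calls <- call_brdu(read, threshold)
  n <- length(calls)
  k <- n %/% window_size_t
  if (k == 0) {
    warning("read ", read$read_id, " has fewer than ", window_size_t,
            " thymidines; no windows")
    windows <- data.frame(start = numeric(0), end = numeric(0),
                          n_thymidines = integer(0),
                          fraction_brdu = numeric(0))
  } else {
    used <- k * window_size_t
    grp <- rep(seq_len(k), each = window_size_t)
    frac <- as.vector(tapply(calls[seq_len(used)], grp, sum)) / window_size_t
    first <- read$positions[(seq_len(k) - 1) * window_size_t + 1]
    last <- read$positions[seq_len(k) * window_size_t]
    windows <- data.frame(start = first, end = last + 1,
                          n_thymidines = rep(as.integer(window_size_t), k),
                          fraction_brdu = frac)
  }
  structure(
    list(read_id = read$read_id, chrom = read$chrom,
         window_size_t = as.integer(window_size_t),
         call_threshold = threshold, windows = windows),
    class = "windowed_track")
}

#' @export
print.windowed_track <- function(x, ...) {
  cat(sprintf("<windowed_track> %s: %d windows of %d T (threshold %.2f)\n",
              x$read_id, nrow(x$windows), x$window_size_t,
              x$call_threshold))
  invisible(x)
}

#' Classify a read as nascent or parental
#'
#' A read whose overall fraction of BrdU-called thymidines reaches the
#' threshold (default 5\%, `>=`) is classified as a nascent strand,
#' i.e. synthesized during the labelling period.
#'
#' @param read A [brdu_read()].
#' @param threshold Nascent classification threshold (fraction of called
#'   thymidines).
#' @param call_threshold Per-position call threshold.
#' @return A list with `read_id`, `read_fraction_brdu`, `is_nascent` and
#'   `threshold`.
#' @export
classify_nascent <- function(read, threshold = 0.05, call_threshold = 0.5) {
  stopifnot(inherits(read, "brdu_read"))
  if (length(read$positions) == 0) {
    stop("cannot classify a read with zero thymidines")
  }
  frac <- mean(call_brdu(read, call_threshold))
  list(read_id = read$read_id, read_fraction_brdu = frac,
       is_nascent = frac >= threshold, threshold = threshold)
}

#' Frequency distributions of BrdU signal
#'
#' Binned counts of the BrdU signal at one of three granularities: raw
#' per-thymidine probabilities, per-window incorporation fractions, or
#' per-read fractions.
#'
#' @param reads List of [brdu_read()] objects.
#' @param per One of `"position"`, `"window"`, `"read"`.
#' @param breaks Histogram break points on `[0, 1]`.
#' @param window_size_t,threshold Windowing parameters (used for
#'   `per = "window"`; `threshold` also for `per = "read"`).
#' @return A `data.frame` with columns `bin_low`, `bin_high`, `bin_mid`,
#'   `count`.
#' @export
fraction_histograms <- function(reads,
                                per = c("position", "window", "read"),
                                breaks = seq(0, 1, by = 0.025),
                                window_size_t = 290, threshold = 0.5) {
  per <- match.arg(per)
  values <- switch(per,
    position = unlist(lapply(reads, `[[`, "probabilities")),
    window = unlist(lapply(reads, function(r) {
      suppressWarnings(
        window_fractions(r, window_size_t, threshold)$windows$fraction_brdu)
    })),
    read = vapply(reads, function(r) {
      classify_nascent(r, call_threshold = threshold)$read_fraction_brdu
    }, 0)
  )
  if (is.null(values)) values <- numeric(0)
  counts <- if (length(values) == 0) {
    integer(length(breaks) - 1)
  } else {
    # right-open bins except the last, so a fraction of exactly 1 is counted
    tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  }
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = counts)
}
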