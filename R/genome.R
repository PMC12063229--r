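#' Genome and initiation landscape for the replication simulator
#'
#' Encodes a reference genome together with the initiation model used by
#' [sample_molecules()]: focused initiation zones that fire with a given
#' per-molecule probability, and a uniform background of dispersed
#' initiation at a constant rate per basepair per molecule. Both classes of
#' origin launch a pair of replication forks moving apart at constant speed.
#'
#' @param chromosomes `data.frame` with columns `name` and `length` (bp).
#' @param focused_zones Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `firing_prob` (per-molecule probability
#'   that the zone fires on a molecule overlapping it).
#' @param dispersed_rate Initiations per bp per molecule outside zones.
#'   The default corresponds to a mean inter-origin distance of 100 kb.
#' @param fork_speed Fork speed in bp per minute.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes,
                         focused_zones = NULL,
                         dispersed_rate = 1e-5,
                         fork_speed = 1500) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) {
    stop("zero-length chromosome in genome model")
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("duplicated chromosome names")
  }
  if (!is.null(focused_zones)) {
    stopifnot(is.data.frame(focused_zones),
              all(c("chrom", "start", "end", "firing_prob") %in%
                    names(focused_zones)))
    if (any(focused_zones$start >= focused_zones$end)) {
      stop("focused zone with start >= end")
    }
    if (any(focused_zones$firing_prob < 0 | focused_zones$firing_prob > 1)) {
      stop("zone firing probabilities must lie in [0, 1]")
    }
    len <- chromosomes$length[match(focused_zones$chrom, chromosomes$name)]
    if (anyNA(len) || any(focused_zones$start < 0) ||
        any(focused_zones$end > len)) {
      stop("focused zones must lie within chromosome bounds")
    }
  }
  stopifnot(dispersed_rate >= 0, fork_speed > 0)
  structure(
    list(chromosomes = chromosomes,
         focused_zones = focused_zones,
         dispersed_rate = dispersed_rate,
         fork_speed = fork_speed),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosome(s), %s bp; %d zone(s); dispersed %g /bp; fork %g bp/min\n",
    nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ","),
    if (is.null(x$focused_zones)) 0L else nrow(x$focused_zones),
    x$dispersed_rate, x$fork_speed))
  invisible(x)
}
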