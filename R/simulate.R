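#' Simulate S-phase molecules with known replication dynamics
#'
#' Draws sequenced molecules from an asynchronously cycling cell population.
#' Each molecule receives a footprint on the genome, an S-phase entry time
#' (its phase relative to the labelling schedule), a set of fired origins
#' (focused zones plus dispersed background), and the resulting fork
#' trajectories. Origins that would be passively replicated by a
#' neighbouring fork before their own firing time are removed, so the
#' remaining initiation events satisfy the fork-trajectory invariants:
#' every position's replication time is the minimum over origins of
#' `firing_time + distance / fork_speed`.
#'
#' Two strand-level thinnings reflect what is actually sequenced: a
#' `quiescent_fraction` of molecules comes from non-cycling cells and is
#' never replicated during the simulation, and each replicated duplex
#' contributes its BrdU-free template strand with probability
#' `parental_strand_prob` (sequencing samples either strand of a duplex).
#'
#' @param genome A [genome_model()].
#' @param n_reads Number of molecules to draw.
#' @param read_length Read length spec: a scalar, a vector of length
#'   `n_reads`, or a `function(n)` returning lengths (bp).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param schedule A [label_schedule()]; only its `start_time` is used here,
#'   to anchor molecule phases.
#' @param cycle_length Cell-cycle length in minutes (default 20 h).
#' @param s_phase_duration Length of S phase in minutes; origin firing times
#'   are i.i.d. uniform over the molecule's S phase.
#' @param phase `"asynchronous"` (default): S-phase entry offsets uniform
#'   across the cell cycle, centred on the label start so the label meets
#'   molecules at every replication stage. `"labelling"`: entries
#'   concentrated so that replication overlaps the labelling period, for
#'   recovery experiments.
#' @param quiescent_fraction Fraction of molecules from non-cycling cells.
#' @param parental_strand_prob Probability the sequenced strand is the
#'   unlabelled template of a replicated duplex.
#' @param pad Basepairs of flanking genome simulated beyond each read end,
#'   so that forks from off-read origins replicate the read edges.
#' @return A list of `molecule_truth` objects. Each records the read span,
#'   the fired initiation events on the read (`initiation_events`:
#'   `position`, `time`), termination positions, directional
#'   `fork_segments`, all governing origins including off-read ones
#'   (`origins_all`), the number of candidate dispersed+zone origins placed
#'   within the read span before passive-replication pruning
#'   (`n_candidate_origins_read`), the phase `t0`, and the strand flags
#'   `quiescent` and `is_nascent_strand`.
#' @export
sample_molecules <- function(genome, n_reads,
                             read_length = 150000,
                             seed = NULL,
                             schedule = label_schedule(),
                             cycle_length = 1200,
                             s_phase_duration = 480,
                             phase = c("asynchronous", "labelling"),
                             quiescent_fraction = 0.1,
                             parental_strand_prob = 0.5,
                             pad = 300000) {
  stopifnot(inherits(genome, "genome_model"), n_reads >= 1,
            cycle_length > s_phase_duration, s_phase_duration > 0)
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)

  lengths <- if (is.function(read_length)) {
    read_length(n_reads)
  } else if (length(read_length) == 1L) {
    rep(as.numeric(read_length), n_reads)
  } else {
    stopifnot(length(read_length) == n_reads)
    as.numeric(read_length)
  }
  if (any(lengths < 1)) stop("read lengths must be >= 1 bp")
  if (any(lengths > max(genome$chromosomes$length))) {
    stop("read longer than every chromosome")
  }

  s0 <- schedule$start_time
  lapply(seq_len(n_reads), function(i) {
    L <- floor(lengths[i])
    chroms <- genome$chromosomes[genome$chromosomes$length >= L, , drop = FALSE]
    w <- chroms$length - L + 1
    ci <- sample.int(nrow(chroms), 1L, prob = w)
    chrom <- chroms$name[ci]
    clen <- chroms$length[ci]
    start <- floor(stats::runif(1, 0, clen - L + 1))
    end <- start + L

    t0 <- switch(phase,
      asynchronous = {
        half <- (cycle_length - s_phase_duration) / 2
        stats::runif(1, s0 - half, s0 + half)
      },
      labelling = stats::runif(1, s0 - s_phase_duration,
                               s0 + schedule_ramp_duration(schedule))
    )
    quiescent <- stats::runif(1) < quiescent_fraction
    nascent_strand <- !quiescent &&
      stats::runif(1) >= parental_strand_prob

    win_start <- max(0, start - pad)
    win_end <- min(clen, end + pad)

    pos <- numeric(0)
    if (!quiescent) {
      if (!is.null(genome$focused_zones)) {
        fz <- genome$focused_zones
        fz <- fz[fz$chrom == chrom & fz$end > win_start & fz$start < win_end, ,
                 drop = FALSE]
        if (nrow(fz) > 0) {
          fires <- stats::runif(nrow(fz)) < fz$firing_prob
          if (any(fires)) {
            zs <- pmax(fz$start[fires], win_start)
            ze <- pmin(fz$end[fires], win_end)
            pos <- c(pos, stats::runif(sum(fires), zs, ze))
          }
        }
      }
      if (genome$dispersed_rate > 0) {
        k <- stats::rpois(1, genome$dispersed_rate * (win_end - win_start))
        if (k > 0) {
          dp <- stats::runif(k, win_start, win_end)
          # dispersed initiation is the background outside focused zones
          if (!is.null(genome$focused_zones)) {
            fz <- genome$focused_zones
            fz <- fz[fz$chrom == chrom, , drop = FALSE]
            if (nrow(fz) > 0) {
              in_zone <- vapply(dp, function(x) {
                any(x >= fz$start & x < fz$end)
              }, TRUE)
              dp <- dp[!in_zone]
            }
          }
          pos <- c(pos, dp)
        }
      }
    }
    n_candidate_read <- sum(pos >= start & pos < end)
    times <- t0 + stats::runif(length(pos), 0, s_phase_duration)

    keep <- prune_passive_origins(pos, times, genome$fork_speed)
    pos <- pos[keep]
    times <- times[keep]
    ord <- order(pos)
    pos <- pos[ord]
    times <- times[ord]

    geometry <- molecule_geometry(pos, times, genome$fork_speed, start, end)

    on_read <- pos >= start & pos < end
    structure(
      list(read_id = sprintf("sim_read_%04d", i),
           chrom = chrom,
           start = start,
           end = end,
           strand = "+",
           initiation_events = data.frame(position = pos[on_read],
                                          time = times[on_read]),
           termination_positions = geometry$terminations,
           fork_segments = geometry$fork_segments,
           origins_all = data.frame(position = pos, time = times),
           n_candidate_origins_read = n_candidate_read,
           t0 = t0,
           fork_speed = genome$fork_speed,
           quiescent = quiescent,
           is_nascent_strand = nascent_strand),
      class = "molecule_truth")
  })
}

# Origins passively replicated by a neighbour's fork before their own firing
# time never fire. Domination is transitive along the line, so one pass over
# all pairs suffices.
prune_passive_origins <- function(pos, times, fork_speed) {
  n <- length(pos)
  if (n <= 1) return(rep(TRUE, n))
  keep <- logical(n)
  for (i in seq_len(n)) {
    arrival <- times[-i] + abs(pos[-i] - pos[i]) / fork_speed
    keep[i] <- all(arrival > times[i])
  }
  keep
}

# Fork segments and termination positions on [start, end) given fired
# origins (sorted by position) governing the region.
molecule_geometry <- function(pos, times, fork_speed, start, end) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0))
  if (length(pos) == 0) {
    return(list(fork_segments = empty, terminations = numeric(0)))
  }
  # meeting point of the rightward fork of origin k and the leftward fork
  # of origin k+1
  meets <- if (length(pos) > 1) {
    (pos[-length(pos)] + pos[-1]) / 2 + fork_speed * diff(times) / 2
  } else {
    numeric(0)
  }
  # breakpoints partition the line into alternating leftward/rightward
  # segments: ... | left | origin | right | meet | left | origin | ...
  bounds <- c(-Inf, as.vector(rbind(pos, c(meets, Inf))))
  dirs <- rep(c("left", "right"), length.out = length(bounds) - 1)
  seg_start <- pmax(bounds[-length(bounds)], start)
  seg_end <- pmin(bounds[-1], end)
  ok <- seg_start < seg_end
  fork_segments <- data.frame(start = seg_start[ok], end = seg_end[ok],
                              direction = dirs[ok])
  terminations <- meets[meets >= start & meets < end]
  list(fork_segments = fork_segments, terminations = terminations)
}

#' Replication time of positions on a simulated molecule
#'
#' @param truth A `molecule_truth`.
#' @param positions Basepair coordinates within the molecule's span.
#' @return Replication times in minutes: `-Inf` for quiescent molecules
#'   (replicated before the simulation window), the molecule phase `t0` if
#'   no origin governs the molecule, otherwise the piecewise-linear
#'   first-passage time `min_k(time_k + |pos - x_k| / fork_speed)`.
#' @export
replication_time <- function(truth, positions) {
  stopifnot(inherits(truth, "molecule_truth"))
  if (truth$quiescent) return(rep(-Inf, length(positions)))
  org <- truth$origins_all
  if (nrow(org) == 0) return(rep(truth$t0, length(positions)))
  rt <- rep(Inf, length(positions))
  for (k in seq_len(nrow(org))) {
    rt <- pmin(rt, org$time[k] + abs(positions - org$position[k]) /
                 truth$fork_speed)
  }
  rt
}

#' Expected BrdU incorporation along a simulated molecule
#'
#' Combines the molecule's replication-time profile with the labelling
#' schedule and the concentration-incorporation model: a position replicated
#' at time `t` carries incorporated fraction
#' `f(concentration(t))`. Template (non-nascent) strands carry none.
#'
#' @param truth A `molecule_truth`.
#' @param schedule A [label_schedule()].
#' @param model An [incorporation_model()].
#' @param positions Coordinates at which to evaluate; default every bp of
#'   the molecule span.
#' @return Numeric vector of incorporated fractions in `[0, 1)`.
#' @export
incorporation_track <- function(truth, schedule, model, positions = NULL) {
  stopifnot(inherits(truth, "molecule_truth"))
  if (is.null(positions)) positions <- seq(truth$start, truth$end - 1)
  if (!truth$is_nascent_strand) return(rep(0, length(positions)))
  rt <- replication_time(truth, positions)
  incorporation_fraction(model, schedule_concentration(schedule, rt))
}

#' Emit a per-thymidine BrdU probability read from a simulated molecule
#'
#' Thymidine positions are placed by i.i.d. Bernoulli draws at density
#' `t_density`; each position's probability is drawn from the BrdU
#' component of the emission mixture with probability equal to the local
#' incorporated fraction, otherwise from the background component.
#'
#' @param truth A `molecule_truth`.
#' @param schedule A [label_schedule()].
#' @param incorporation An [incorporation_model()].
#' @param emission An [emission_model()].
#' @param t_density Per-bp probability a position is a thymidine.
#' @param seed Optional integer seed.
#' @return A [brdu_read()].
#' @export
emit_probabilities <- function(truth, schedule, incorporation, emission,
                               t_density = 0.29, seed = NULL) {
  stopifnot(inherits(truth, "molecule_truth"),
            inherits(emission, "emission_model"),
            t_density > 0, t_density < 1)
  span <- truth$end - truth$start
  if (span < 1) stop("empty molecule")
  if (!is.null(seed)) set.seed(seed)
  offsets <- which(stats::runif(span) < t_density) - 1L
  positions <- truth$start + offsets
  frac <- incorporation_track(truth, schedule, incorporation, positions)
  labelled <- stats::runif(length(positions)) < frac
  probs <- numeric(length(positions))
  probs[labelled] <- remit_brdu(emission, sum(labelled))
  probs[!labelled] <- remit_background(emission, sum(!labelled))
  brdu_read(truth$read_id, truth$chrom, truth$start, truth$end,
            truth$strand, positions, probs)
}

#' Simulate a full detect-style dataset with ground truth
#'
#' Convenience wrapper: draws molecules with [sample_molecules()] and emits
#' a probability read for each with [emit_probabilities()]. All randomness
#' is governed by a single seed.
#'
#' @inheritParams sample_molecules
#' @inheritParams emit_probabilities
#' @param ... Further arguments passed to [sample_molecules()].
#' @return `list(reads = <list of brdu_read>, truths = <list of
#'   molecule_truth>)`.
#' @export
simulate_reads <- function(genome, n_reads,
                           schedule = label_schedule(),
                           incorporation = incorporation_model(),
                           emission = emission_model(),
                           read_length = 150000,
                           t_density = 0.29,
                           seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  truths <- sample_molecules(genome, n_reads, read_length = read_length,
                             seed = NULL, schedule = schedule, ...)
  reads <- lapply(truths, emit_probabilities, schedule = schedule,
                  incorporation = incorporation, emission = emission,
                  t_density = t_density, seed = NULL)
  list(reads = reads, truths = truths)
}

#' Write simulator ground truth as BED files
#'
#' Emits `initiations.bed` (score = firing time, minutes),
#' `terminations.bed`, and `forks.bed` (strand `+` for rightward, `-` for
#' leftward forks); all BED6, 0-based half-open, names carrying the read id.
#'
#' @param truths List of `molecule_truth` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_truth <- function(truths, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- function(f) do.call(rbind, lapply(truths, f))
  ini <- rows(function(tr) {
    ev <- tr$initiation_events
    if (nrow(ev) == 0) return(NULL)
    data.frame(chrom = tr$chrom, start = floor(ev$position),
               end = floor(ev$position) + 1, name = tr$read_id,
               score = ev$time, strand = ".")
  })
  ter <- rows(function(tr) {
    tp <- tr$termination_positions
    if (length(tp) == 0) return(NULL)
    data.frame(chrom = tr$chrom, start = floor(tp), end = floor(tp) + 1,
               name = tr$read_id, score = 0, strand = ".")
  })
  frk <- rows(function(tr) {
    fs <- tr$fork_segments
    if (nrow(fs) == 0) return(NULL)
    data.frame(chrom = tr$chrom, start = floor(fs$start),
               end = ceiling(fs$end), name = tr$read_id, score = 0,
               strand = ifelse(fs$direction == "right", "+", "-"))
  })
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0))
  paths <- file.path(dir, c("initiations.bed", "terminations.bed",
                            "forks.bed"))
  write_bed(if (is.null(ini)) empty else ini, paths[1])
  write_bed(if (is.null(ter)) empty else ter, paths[2])
  write_bed(if (is.null(frk)) empty else frk, paths[3])
  invisible(paths)
}
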