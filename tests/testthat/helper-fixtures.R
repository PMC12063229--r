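# Shared fixture builders. Everything is generated in code; no data files.

# A molecule_truth with hand-chosen origins, for targeted emission and
# calling tests without the sampling layer.
make_truth <- function(origins = data.frame(position = 75000, time = 5),
                       start = 0, end = 150000, chrom = "chr1",
                       fork_speed = 1500, t0 = 0,
                       nascent = TRUE, quiescent = FALSE,
                       read_id = "fixture_read") {
  origins <- origins[order(origins$position), , drop = FALSE]
  geom <- replifork:::molecule_geometry(origins$position, origins$time,
                                        fork_speed, start, end)
  on_read <- origins$position >= start & origins$position < end
  structure(
    list(read_id = read_id, chrom = chrom, start = start, end = end,
         strand = "+",
         initiation_events = data.frame(position = origins$position[on_read],
                                        time = origins$time[on_read]),
         termination_positions = geom$terminations,
         fork_segments = geom$fork_segments,
         origins_all = origins,
         n_candidate_origins_read = sum(on_read),
         t0 = t0, fork_speed = fork_speed,
         quiescent = quiescent, is_nascent_strand = nascent),
    class = "molecule_truth")
}

# A brdu_read with explicit probabilities at evenly spaced thymidines.
make_read <- function(probs, read_id = "toy", chrom = "chr1", start = 0,
                      spacing = 3) {
  n <- length(probs)
  positions <- start + spacing * (seq_len(n) - 1)
  brdu_read(read_id, chrom, start, positions[n] + spacing, "+",
            positions, probs)
}

# Random footprints on one chromosome.
make_footprints <- function(n, chrom_len = 1e7, min_len = 5e4,
                            max_len = 1.5e5, prefix = "r") {
  len <- floor(stats::runif(n, min_len, max_len))
  start <- floor(stats::runif(n, 0, chrom_len - len))
  data.frame(read_id = paste0(prefix, seq_len(n)), chrom = "chr1",
             start = start, end = start + len)
}

# Brute-force overlap of one interval with an unmerged region set.
brute_overlap_bp <- function(chrom, start, end, regions) {
  bases <- seq(start, end - 1)
  covered <- rep(FALSE, length(bases))
  rr <- regions[regions$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(rr))) {
    covered <- covered | (bases >= rr$start[k] & bases < rr$end[k])
  }
  sum(covered)
}

# Independent dense solver for the epsilon-smoothed TV objective:
# quasi-Newton restarts until the gradient is negligible.
tv_oracle <- function(y, alpha, eps) {
  n <- length(y)
  A <- replifork:::tv_antiderivative_matrix(n)
  D <- replifork:::tv_difference_matrix(n)
  b <- y - y[1]
  fn <- function(u) {
    alpha * sum(sqrt((D %*% u)^2 + eps)) + 0.5 * sum((A %*% u - b)^2)
  }
  gr <- function(u) {
    du <- as.vector(D %*% u)
    as.vector(alpha * crossprod(D, du / sqrt(du^2 + eps)) +
                crossprod(A, A %*% u - b))
  }
  u <- c(diff(y), y[n] - y[n - 1])
  for (r in 1:50) {
    u <- stats::optim(u, fn, gr, method = "BFGS",
                      control = list(maxit = 5e4, reltol = 1e-15))$par
    if (sqrt(sum(gr(u)^2)) < 1e-7) break
  }
  u
}

# Random two-slope noisy signal for oracle-equivalence checks.
random_tv_instance <- function() {
  n <- sample(8:32, 1)
  k <- sample(3:(n - 3), 1)
  y <- cumsum(c(0, c(rep(stats::runif(1, -3, 3), k),
                     rep(stats::runif(1, -3, 3), n - 1 - k)))) +
    stats::rnorm(n)
  list(y = y, alpha = stats::runif(1, 0.5, 8))
}
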