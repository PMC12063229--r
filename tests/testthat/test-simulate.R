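test_that("degenerate initiation landscapes behave as configured", {
  # a single always-firing zone, no dispersed background
  gen <- genome_model(
    data.frame(name = "chr1", length = 2e5),
    focused_zones = data.frame(chrom = "chr1", start = 9e4, end = 1e5,
                               firing_prob = 1),
    dispersed_rate = 0)
  tr <- sample_molecules(gen, 30, read_length = 1.8e5, seed = 61,
                         quiescent_fraction = 0, parental_strand_prob = 0,
                         pad = 0)
  for (t in tr) {
    ev <- t$initiation_events
    expect_equal(nrow(ev), 1)
    expect_true(ev$position >= 9e4 && ev$position < 1e5)
  }
  # no origins at all: replication time is the constant phase offset
  gen0 <- genome_model(data.frame(name = "chr1", length = 2e5),
                       dispersed_rate = 0)
  tr0 <- sample_molecules(gen0, 3, read_length = 1e5, seed = 62,
                          quiescent_fraction = 0)[[1]]
  expect_equal(nrow(tr0$fork_segments), 0)
  rt <- replication_time(tr0, c(tr0$start, tr0$start + 5e4))
  expect_equal(rt[1], rt[2])
  # pre-replicated molecule carries no incorporation under a later label
  late <- label_schedule(start_time = tr0$t0 + 10)
  expect_equal(incorporation_track(tr0, late, incorporation_model(),
                                   tr0$start + c(0, 100, 1e4)),
               rep(0, 3))
})

test_that("candidate origin counts follow the Poisson expectation", {
  gen <- genome_model(data.frame(name = "chr1", length = 2e7),
                      dispersed_rate = 1e-5)
  tr <- sample_molecules(gen, 200, read_length = 1e5, seed = 63,
                         quiescent_fraction = 0, parental_strand_prob = 0)
  cand <- vapply(tr, `[[`, 0L, "n_candidate_origins_read")
  # expectation rate * length = 1.0; allow 3 SE of the Monte-Carlo mean
  expect_lt(abs(mean(cand) - 1), 3 * sqrt(1 / 200))
  fired <- vapply(tr, function(t) nrow(t$initiation_events), 0L)
  expect_true(all(fired <= cand))
})

test_that("fork geometry is conserved on every molecule", {
  gen <- genome_model(data.frame(name = "chr1", length = 1e7),
                      dispersed_rate = 3e-5)
  tr <- sample_molecules(gen, 50, read_length = 2e5, seed = 64,
                         quiescent_fraction = 0)
  for (t in tr) {
    fs <- t$fork_segments
    if (nrow(fs) == 0) next
    # segments tile the read without gaps and alternate direction
    expect_equal(fs$start[1], t$start)
    expect_equal(fs$end[nrow(fs)], t$end)
    if (nrow(fs) > 1) {
      expect_equal(fs$start[-1], fs$end[-nrow(fs)])
      expect_true(all(fs$direction[-1] != fs$direction[-nrow(fs)]))
    }
    # each (left,right) boundary is an on-read initiation, each
    # (right,left) boundary a termination
    dirs <- fs$direction
    n_div <- sum(dirs[-nrow(fs)] == "left" & dirs[-1] == "right")
    n_con <- sum(dirs[-nrow(fs)] == "right" & dirs[-1] == "left")
    expect_equal(n_div, nrow(t$initiation_events))
    expect_equal(n_con, length(t$termination_positions))
    # replication time at an initiation equals its firing time (no other
    # fork arrives earlier: passively replicated candidates were pruned)
    for (i in seq_len(nrow(t$initiation_events))) {
      expect_equal(replication_time(t, t$initiation_events$position[i]),
                   t$initiation_events$time[i])
    }
  }
})

test_that("identical seeds give byte-identical detect output", {
  gen <- genome_model(data.frame(name = "chr1", length = 1e6),
                      dispersed_rate = 2e-5)
  p1 <- tempfile(); p2 <- tempfile()
  s1 <- simulate_reads(gen, 5, read_length = 1e5, seed = 99)
  s2 <- simulate_reads(gen, 5, read_length = 1e5, seed = 99)
  write_detect(s1$reads, p1)
  write_detect(s2$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- simulate_reads(gen, 5, read_length = 1e5, seed = 100)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("ground-truth BED export conserves per-read event counts", {
  gen <- genome_model(data.frame(name = "chr1", length = 5e6),
                      dispersed_rate = 2e-5)
  tr <- sample_molecules(gen, 20, read_length = 2e5, seed = 101,
                         quiescent_fraction = 0)
  dir <- tempfile(); paths <- write_truth(tr, dir)
  ini <- read_bed(paths[1])
  ter <- read_bed(paths[2])
  frk <- read_bed(paths[3], expect_strand = TRUE)
  expect_equal(nrow(ini),
               sum(vapply(tr, function(t) nrow(t$initiation_events), 0L)))
  expect_equal(nrow(ter),
               sum(vapply(tr, function(t) length(t$termination_positions),
                          0L)))
  expect_equal(nrow(frk),
               sum(vapply(tr, function(t) nrow(t$fork_segments), 0L)))
  expect_setequal(unique(frk$strand), c("+", "-"))
  # empty truth set still writes a valid (empty) BED
  paths0 <- write_truth(list(), tempfile())
  expect_equal(nrow(read_bed(paths0[1])), 0)
})

test_that("configuration errors are caught", {
  expect_error(genome_model(data.frame(name = "c", length = 0)),
               "zero-length chromosome")
  gen <- genome_model(data.frame(name = "c", length = 1e4))
  expect_error(sample_molecules(gen, 2, read_length = 2e4, seed = 1),
               "longer than every chromosome")
  expect_error(genome_model(
    data.frame(name = "c", length = 1e4),
    focused_zones = data.frame(chrom = "c", start = 5e3, end = 2e4,
                               firing_prob = 0.5)),
    "within chromosome bounds")
  tr <- make_truth()
  tr$end <- tr$start
  expect_error(emit_probabilities(tr, label_schedule(),
                                  incorporation_model(), emission_model()),
               "empty molecule")
})

test_that("a fork crossing the ramp steps up every step_interval of travel", {
  # rightward fork at 1500 bp/min with 2.5-min steps: new concentration
  # every 3750 bp of travel
  sched <- label_schedule()
  inc <- incorporation_model()
  tr <- make_truth(data.frame(position = 0, time = 0), start = 0, end = 9e4)
  pos <- seq(0, 89999)
  frac <- incorporation_track(tr, sched, inc, pos)
  expect_true(all(diff(frac) >= 0))
  jumps <- which(diff(frac) > 1e-9)
  expect_equal(diff(jumps), rep(3750, length(jumps) - 1))
  # plateau value: f at the maximum concentration
  expect_equal(frac[9e4], incorporation_fraction(inc, 12), tolerance = 1e-9)
  # position replicated before the label start carries nothing
  early <- make_truth(data.frame(position = 0, time = -100), end = 1e4)
  expect_equal(incorporation_track(early, sched, inc, c(0, 5000)), c(0, 0))
})
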