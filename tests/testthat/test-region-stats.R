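test_that("site counting requires strictly more than half the site inside", {
  regions <- data.frame(chrom = "chr1", start = 150, end = 300)
  sites <- data.frame(chrom = "chr1",
                      start = c(100, 160, 99),
                      end = c(200, 180, 199))
  # overlaps: 50/100 (not counted), fully inside, 49/100 (not counted)
  res <- intersect_sites(sites, regions)
  expect_equal(res$in_region, c(FALSE, TRUE, FALSE))
  expect_equal(res$count, 1L)
})

test_that("overlap and coverage agree with a per-bp brute force scan", {
  set.seed(71)
  for (r in 1:5) {
    rs <- floor(runif(8, 0, 5e3))
    regions <- data.frame(chrom = sample(c("chr1", "chr2"), 8, TRUE),
                          start = rs, end = rs + floor(runif(8, 50, 900)))
    ss <- floor(runif(12, 0, 5e3))
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                        start = ss, end = ss + floor(runif(12, 20, 400)))
    lookup <- replifork:::region_lookup(merge_regions(regions))
    got <- replifork:::overlap_bp(lookup, sites$chrom, sites$start,
                                  sites$end)
    want <- vapply(seq_len(12), function(i) {
      brute_overlap_bp(sites$chrom[i], sites$start[i], sites$end[i],
                       regions)
    }, 0)
    expect_equal(got, want)
  }
})

test_that("coverage is summed per-base over reads in gigabases", {
  fp <- data.frame(read_id = paste0("r", 1:10), chrom = "chr1",
                   start = (0:9) * 2e5, end = (0:9) * 2e5 + 1e5)
  expect_equal(coverage_gb(fp), 0.001)
  # region covering exactly half of every read
  half <- data.frame(chrom = "chr1", start = (0:9) * 2e5,
                     end = (0:9) * 2e5 + 5e4)
  expect_equal(coverage_gb(fp, half), 0.0005)
})

test_that("observed density is sites per gigabase", {
  fp <- data.frame(read_id = paste0("r", 1:1000), chrom = "chr1",
                   start = (0:999) * 2e5, end = (0:999) * 2e5 + 1e5)
  ss <- (0:9) * 2e5 + 100
  sites <- data.frame(chrom = "chr1", start = ss, end = ss + 1000)
  res <- rigr(sites, fp, NULL, n_randomizations = 5, seed = 1)
  expect_equal(res$rigr, 10 / 0.1)   # 10 sites in 0.1 Gb
  expect_equal(res$n_sites, 10L)
})

test_that("density is invariant to read order and region splitting", {
  set.seed(73)
  fp <- make_footprints(40)
  sites <- replifork:::place_sites_in_footprints(rep(800, 20), fp)
  rs <- floor(runif(10, 0, 9.9e6))
  regions <- data.frame(chrom = "chr1", start = rs, end = rs + 5e4)
  r1 <- rigr(sites, fp, regions, n_randomizations = 1, seed = 5)
  r2 <- rigr(sites, fp[sample(40), ], regions, n_randomizations = 1,
             seed = 5)
  expect_equal(r1$rigr, r2$rigr)
  # split every region into two adjacent halves
  halves <- rbind(
    data.frame(chrom = regions$chrom, start = regions$start,
               end = regions$start + 2.5e4),
    data.frame(chrom = regions$chrom, start = regions$start + 2.5e4,
               end = regions$end))
  r3 <- rigr(sites, fp, halves, n_randomizations = 1, seed = 5)
  expect_equal(r1$rigr, r3$rigr)
  expect_equal(r1$n_sites, r3$n_sites)
})

test_that("randomized sites preserve count and lengths inside footprints", {
  set.seed(74)
  fp <- make_footprints(25)
  lens <- c(500, 1000, 2000, 4999, 120)
  placed <- replifork:::place_sites_in_footprints(lens, fp)
  expect_equal(nrow(placed), 5)
  expect_equal(placed$end - placed$start, lens)
  for (i in 1:5) {
    inside <- any(fp$start <= placed$start[i] & placed$end[i] <= fp$end)
    expect_true(inside)
  }
  giant <- rep(1e7, 1)
  expect_error(replifork:::place_sites_in_footprints(giant, fp),
               "longer than every")
})

test_that("the subsampled null inflates density by 1/fraction and p is never 0", {
  set.seed(75)
  fp <- make_footprints(80, min_len = 1e5, max_len = 1e5 + 1)
  sites <- replifork:::place_sites_in_footprints(rep(1000, 100), fp)
  res <- rigr(sites, fp, NULL, n_randomizations = 400,
              read_subsample_fraction = 0.8)
  expect_equal(res$null_mean / res$rigr, 1.25, tolerance = 0.01)
  expect_gt(res$p_enrichment, 0)
  expect_gt(res$p_depletion, 0)
  expect_lte(res$p_value, 1)
})

test_that("relative distance follows the midpoint convention", {
  regions <- data.frame(chrom = "chr1",
                        start = c(1000, 9000), end = c(3000, 11000))
  # midpoints at 2000 and 10000
  midway <- data.frame(chrom = "chr1", start = 5999, end = 6001)
  at_mid <- data.frame(chrom = "chr1", start = 1999, end = 2001)
  quarter <- data.frame(chrom = "chr1", start = 3999, end = 4001)
  rd <- relative_distance(rbind(midway, at_mid, quarter), regions)
  expect_equal(rd$d, c(0.5, 0, 0.25))
  # chromosomes with < 2 regions are skipped with a warning
  one <- data.frame(chrom = "chr2", start = 0, end = 10)
  expect_warning(
    rd2 <- relative_distance(midway, rbind(regions, one)),
    "skipped")
  expect_equal(rd2$d, 0.5)
})

test_that("uniformly placed sites give a flat relative-distance histogram", {
  set.seed(76)
  rs <- sort(floor(runif(150, 0, 4e7)))
  regions <- data.frame(chrom = "chr1", start = rs, end = rs + 2e4)
  ss <- floor(runif(4000, 0, 4e7))
  sites <- data.frame(chrom = "chr1", start = ss, end = ss + 1)
  rd <- relative_distance(sites, regions)
  chi <- suppressWarnings(chisq.test(rd$histogram$count))
  expect_gt(chi$p.value, 0.01)
})

test_that("track stratification yields equal-length strata and assigns sites", {
  # linear track on one chromosome: strata are 4 equal blocks
  track <- data.frame(chrom = "chr1", start = (0:99) * 1e4,
                      end = (1:100) * 1e4, value = 1:100)
  sites <- data.frame(chrom = "chr1",
                      start = c(5e4, 3e5, 6e5, 9.9e5), end = c(5e4, 3e5, 6e5, 9.9e5) + 10)
  st <- stratify_by_track(sites, track)
  lens <- vapply(st$strata, function(s) sum(s$end - s$start), 0)
  expect_equal(lens, rep(2.5e5, 4))
  expect_equal(st$assignment, c(1L, 2L, 3L, 4L))
  # constant track: everything in stratum 1 with a warning
  track$value <- 7
  expect_warning(st2 <- stratify_by_track(sites, track), "constant track")
  expect_equal(st2$assignment, rep(1L, 4))
  # uncovered site is unassigned
  off <- data.frame(chrom = "chr2", start = 10, end = 20)
  track$value <- 1:100
  expect_true(is.na(stratify_by_track(off, track)$assignment))
})
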