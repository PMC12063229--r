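make_forks <- function(n_right, n_left, start = 0, end = 1000,
                       chrom = "chr1") {
  data.frame(read_id = paste0("r", seq_len(n_right + n_left)),
             chrom = chrom, start = start, end = end,
             direction = c(rep("right", n_right), rep("left", n_left)))
}

test_that("ensemble RFD equals (right - left) / total per bin", {
  prof <- rfd_ensemble(make_forks(18, 31), bin_size = 1000)
  expect_equal(round(prof$rfd, 2), -0.27)
  prof2 <- rfd_ensemble(make_forks(6, 5), bin_size = 1000)
  expect_equal(round(prof2$rfd, 2), 0.09)
  # all rightward: +1 in every covered bin
  prof3 <- rfd_ensemble(make_forks(4, 0, 0, 10000), bin_size = 1000)
  expect_true(all(prof3$rfd == 1))
  expect_equal(nrow(prof3), 10)
  expect_true(all(prof3$rfd >= -1 & prof3$rfd <= 1))
})

test_that("swapping every fork direction negates RFD exactly", {
  set.seed(81)
  fs <- floor(runif(60, 0, 2e5))
  forks <- data.frame(read_id = paste0("r", 1:60), chrom = "chr1",
                      start = fs, end = fs + floor(runif(60, 5e3, 4e4)),
                      direction = sample(c("left", "right"), 60, TRUE))
  a <- rfd_ensemble(forks, bin_size = 5000)
  flipped <- forks
  flipped$direction <- ifelse(forks$direction == "left", "right", "left")
  b <- rfd_ensemble(flipped, bin_size = 5000)
  expect_equal(b$rfd, -a$rfd)
  expect_equal(b$n_right, a$n_left)
})

test_that("expression split halves the gene table with a stable tiebreak", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = "chr1", tss = 1:4, tes = 11:14,
                      strand = "+", expression = c(1, 2, 3, 4))
  sp <- split_genes_by_expression(genes)
  expect_setequal(sp$low$gene_id, c("g1", "g2"))
  expect_setequal(sp$high$gene_id, c("g3", "g4"))
  # tie at the median: stable rank order by gene_id
  genes$expression <- c(1, 2, 2, 4)
  sp2 <- split_genes_by_expression(genes)
  expect_setequal(sp2$low$gene_id, c("g1", "g2"))
  # odd count: extra gene to the low half
  sp3 <- split_genes_by_expression(genes[1:3, ])
  expect_equal(nrow(sp3$low), 2)
  expect_error(split_genes_by_expression(genes[0, ]), "empty gene table")
  genes$expression[1] <- 0
  expect_error(split_genes_by_expression(genes), "without expression")
})

test_that("fork co-directionality flips with anchor strand", {
  forks <- data.frame(read_id = "r1", chrom = "chr1", start = 4000,
                      end = 6000, direction = "right")
  plus <- data.frame(chrom = "chr1", pos = 5000, strand = "+")
  minus <- data.frame(chrom = "chr1", pos = 5000, strand = "-")
  a <- fork_directionality_at_anchors(forks, plus, half_window = 2000,
                                      bin_size = 100,
                                      n_randomizations = 0)
  expect_gt(sum(a$co), 0)
  expect_equal(sum(a$counter), 0)
  b <- fork_directionality_at_anchors(forks, minus, half_window = 2000,
                                      bin_size = 100,
                                      n_randomizations = 0)
  expect_equal(sum(b$co), 0)
  expect_gt(sum(b$counter), 0)
  # simultaneous strand + direction flip leaves counts unchanged
  lforks <- forks; lforks$direction <- "left"
  c2 <- fork_directionality_at_anchors(lforks, minus, half_window = 2000,
                                       bin_size = 100,
                                       n_randomizations = 0)
  expect_equal(c2$co, a$co)
  expect_equal(c2$counter, a$counter)
  expect_error(fork_directionality_at_anchors(
    forks, data.frame(chrom = "chr1", pos = 1, strand = "."),
    n_randomizations = 0), "stranded")
})

test_that("direction-randomized forks stay inside the 99% null band", {
  set.seed(83)
  fs <- floor(runif(80, 0, 1e5))
  forks <- data.frame(read_id = paste0("r", 1:80), chrom = "chr1",
                      start = fs, end = fs + 8000,
                      direction = sample(c("left", "right"), 80, TRUE))
  anchors <- data.frame(chrom = "chr1",
                        pos = floor(runif(12, 2e4, 8e4)),
                        strand = sample(c("+", "-"), 12, TRUE))
  prof <- fork_directionality_at_anchors(forks, anchors,
                                         half_window = 10000,
                                         bin_size = 500,
                                         n_randomizations = 500,
                                         conf = 0.99, seed = 84)
  covered <- prof$total > 0
  inside <- prof$co[covered] >= prof$null_lo[covered] &
    prof$co[covered] <= prof$null_hi[covered]
  expect_gte(mean(inside), 0.97)
})

test_that("meta-profiles reproduce constant and indicator tracks", {
  signal <- data.frame(chrom = "chr1", start = 0, end = 1e6, value = 4.2)
  anchors <- data.frame(chrom = "chr1", pos = c(3e5, 5e5))
  mp <- meta_profile(anchors, signal, half_window = 1e5, bin_size = 1e4)
  expect_equal(dim(mp$matrix), c(2, 20))
  expect_true(all(mp$matrix == 4.2))
  expect_equal(mp$summary, rep(4.2, 20))
  # indicator of a region exactly at the anchor
  ind <- data.frame(chrom = "chr1",
                    start = c(0, 295000, 305000),
                    end = c(295000, 305000, 1e6),
                    value = c(0, 1, 0))
  mp2 <- meta_profile(anchors[1, , drop = FALSE], ind, half_window = 1e5,
                      bin_size = 1e4)
  central <- mp2$matrix[1, 10:11]
  expect_true(all(central > 0))
  expect_equal(sum(mp2$matrix[1, c(1:8, 13:20)]), 0)
  # anchor near the signal edge: out-of-track bins are NA
  mp3 <- meta_profile(data.frame(chrom = "chr1", pos = 5e4), signal,
                      half_window = 1e5, bin_size = 1e4)
  expect_true(anyNA(mp3$matrix))
  expect_equal(mp3$matrix[1, 20], 4.2)
  # geometric mean uses the +1 pseudocount
  mp4 <- meta_profile(anchors, signal, half_window = 1e5, bin_size = 1e4,
                      stat = "geometric_mean")
  expect_equal(mp4$summary, rep(4.2, 20), tolerance = 1e-12)
})

test_that("gene-zone densities localize planted depletion", {
  set.seed(85)
  # reads tile the genome; sites only outside gene bodies
  fp <- data.frame(read_id = paste0("r", 1:50), chrom = "chr1",
                   start = (0:49) * 2e5, end = (0:49) * 2e5 + 2e5)
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      tss = (0:9) * 1e6 + 4e5, tes = (0:9) * 1e6 + 5e5,
                      strand = "+", expression = 10)
  ss <- runif(200, 0, 1e7)
  keep <- !vapply(ss, function(x) {
    any(x >= genes$tss & x < genes$tes)
  }, TRUE)
  sites <- data.frame(chrom = "chr1", start = floor(ss[keep]),
                      end = floor(ss[keep]) + 1)
  gz <- gene_body_rigr(sites, fp, genes, n_randomizations = 200, seed = 86)
  expect_equal(gz$gene_body$rigr, 0)
  expect_lt(gz$gene_body$p_depletion, 0.01)
  expect_gt(gz$upstream$rigr, 0)
})
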