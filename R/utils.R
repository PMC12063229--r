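# Internal interval machinery shared by the enrichment statistics.
#
# Region sets are plain data.frames (chrom, start, end), 0-based half-open.
# Merging goes through GenomicRanges; overlap queries against a merged set
# use a per-chromosome prefix-sum lookup so that the permutation loops stay
# cheap.

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
}

granges_to_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

#' Merge a region set into disjoint intervals
#'
#' @param regions `data.frame` with `chrom`, `start`, `end`.
#' @return A `data.frame` of disjoint, sorted intervals covering the same
#'   basepairs.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions[, c("chrom", "start", "end")])
  granges_to_regions(GenomicRanges::reduce(regions_to_granges(regions)))
}

# Prefix-sum lookup over a merged (disjoint, sorted) region set.
region_lookup <- function(merged) {
  by_chrom <- split(merged[, c("start", "end")], merged$chrom)
  lapply(by_chrom, function(d) {
    ord <- order(d$start)
    s <- d$start[ord]; e <- d$end[ord]
    list(start = s, end = e, cum = cumsum(e - s))
  })
}

# Covered bp in (-Inf, x) for each x, within one chromosome's lookup.
lookup_cum <- function(lk, x) {
  i <- findInterval(x, lk$start)
  out <- numeric(length(x))
  pos <- i > 0
  out[pos] <- lk$cum[i[pos]] - pmax(0, lk$end[i[pos]] - x[pos])
  out
}

# Overlap bp of query intervals with a merged region set.
overlap_bp <- function(lookup, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    lk <- lookup[[ch]]
    if (is.null(lk)) next
    out[sel] <- lookup_cum(lk, end[sel]) - lookup_cum(lk, start[sel])
  }
  out
}

# Place intervals of the given lengths uniformly at random, wholly inside
# the supplied footprints (each site lands in a footprint chosen with
# probability proportional to the number of valid start positions).
place_sites_in_footprints <- function(lengths, fp) {
  n <- length(lengths)
  fl <- fp$end - fp$start
  W <- pmax(outer(fl, lengths, "-") + 1, 0)   # footprints x sites
  tot <- colSums(W)
  if (any(tot <= 0)) {
    stop("site longer than every available footprint")
  }
  cs <- apply(W, 2, cumsum)
  if (n == 1) cs <- matrix(cs, ncol = 1)
  u <- stats::runif(n) * tot
  ridx <- colSums(cs < rep(u, each = nrow(fp))) + 1L
  room <- fl[ridx] - lengths + 1
  start <- fp$start[ridx] + floor(stats::runif(n) * room)
  data.frame(chrom = fp$chrom[ridx], start = start, end = start + lengths)
}
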