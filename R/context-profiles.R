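#' Ensemble replication fork directionality profile
#'
#' Bins the genome and computes, per bin, the replication fork
#' directionality `RFD = (n_right - n_left) / (n_right + n_left)` over all
#' single-molecule fork calls whose interval overlaps the bin. RFD ranges
#' from -1 (all leftward forks) to +1 (all rightward); 0 is an equal mix.
#' An optional null band is derived by flipping each fork's direction
#' independently with probability 0.5.
#'
#' @param forks Fork calls `data.frame` (`chrom`, `start`, `end`,
#'   `direction`).
#' @param bin_size Bin width in bp.
#' @param n_randomizations Direction randomizations for the null band
#'   (0 to skip).
#' @param conf Confidence level of the null band (e.g. 0.95 or 0.99).
#' @param seed Optional integer seed.
#' @return An object of class `rfd_profile`: `data.frame` with `chrom`,
#'   `start`, `end`, `n_right`, `n_left`, `rfd` and, when randomized,
#'   `null_lo` / `null_hi`. Bins with no overlapping fork carry `NA` RFD.
#' @export
rfd_ensemble <- function(forks, bin_size = 1000, n_randomizations = 0,
                         conf = 0.95, seed = NULL) {
  stopifnot(bin_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(forks) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_right = integer(0),
                      n_left = integer(0), rfd = numeric(0))
    class(out) <- c("rfd_profile", "data.frame")
    return(out)
  }
  is_right <- forks$direction == "right"
  res <- lapply(split(seq_len(nrow(forks)), forks$chrom), function(idx) {
    f <- forks[idx, , drop = FALSE]
    a <- floor(f$start / bin_size)
    b <- ceiling(f$end / bin_size) - 1
    off <- min(a)
    nb <- max(b) - off + 1
    acc <- function(sel) {
      d <- numeric(nb + 1)
      if (any(sel)) {
        ia <- a[sel] - off + 1
        ib <- b[sel] - off + 2
        for (k in seq_along(ia)) {
          d[ia[k]] <- d[ia[k]] + 1
          d[ib[k]] <- d[ib[k]] - 1
        }
      }
      cumsum(d[-(nb + 1)])
    }
    right_f <- is_right[idx]
    nr <- acc(right_f)
    nl <- acc(!right_f)
    tot <- nr + nl
    out <- data.frame(chrom = f$chrom[1],
                      start = (off + seq_len(nb) - 1) * bin_size,
                      end = (off + seq_len(nb)) * bin_size,
                      n_right = nr, n_left = nl,
                      rfd = ifelse(tot > 0, (nr - nl) / tot, NA_real_))
    if (n_randomizations > 0) {
      reps <- vapply(seq_len(n_randomizations), function(r) {
        flip <- stats::runif(length(idx)) < 0.5
        rr <- acc(xor(right_f, flip))
        ifelse(tot > 0, (2 * rr - tot) / tot, NA_real_)
      }, numeric(nb))
      if (nb == 1) reps <- matrix(reps, nrow = 1)
      qs <- apply(reps, 1, stats::quantile,
                  probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  na.rm = TRUE, names = FALSE)
      out$null_lo <- qs[1, ]
      out$null_hi <- qs[2, ]
    }
    out
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("rfd_profile", "data.frame")
  out
}

#' Split genes into low- and high-expression halves
#'
#' Genes are ranked by expression and divided at the median into two
#' equally sized categories; with an odd count the extra gene goes to the
#' low half. Ties at the median are broken by stable rank order on
#' `gene_id`. Genes with no expression must be excluded beforehand (an
#' error otherwise).
#'
#' @param genes Gene table `data.frame` with `gene_id`, `chrom`, `tss`,
#'   `tes`, `strand`, `expression`.
#' @return `list(low = <data.frame>, high = <data.frame>)`.
#' @export
split_genes_by_expression <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "strand", "expression") %in% names(genes)))
  if (nrow(genes) == 0) stop("empty gene table")
  if (any(genes$expression <= 0)) {
    stop("genes without expression must be excluded before splitting")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  ord <- order(genes$expression, genes$gene_id)
  n_low <- ceiling(nrow(genes) / 2)
  list(low = genes[ord[seq_len(n_low)], , drop = FALSE],
       high = genes[ord[-seq_len(n_low)], , drop = FALSE])
}

#' Fork co-directionality around stranded anchors
#'
#' Counts, in small bins across a window centred on stranded anchors
#' (typically transcription start or end sites), replication forks moving
#' co-directionally versus counter-directionally with transcription.
#' Coordinates are flipped for minus-strand anchors so transcription always
#' reads left to right; a fork is then co-directional iff it moves
#' rightward. The null band comes from flipping each fork's direction
#' independently with probability 0.5.
#'
#' @param forks Fork calls `data.frame` (`chrom`, `start`, `end`,
#'   `direction`).
#' @param anchors `data.frame` with `chrom`, `pos`, `strand`.
#' @param half_window Window half-width around each anchor (bp).
#' @param bin_size Bin width (bp, default 10).
#' @param n_randomizations Direction randomizations (default 1000).
#' @param conf Confidence level of the null band (default 0.99).
#' @param seed Optional integer seed.
#' @return An object of class `directionality_profile`: `data.frame` with
#'   `offset_start`, `offset_end` (bp relative to the anchor, transcription
#'   rightward), `co`, `counter`, `total`, `null_mean`, `null_lo`,
#'   `null_hi` (band on a single direction's count).
#' @export
fork_directionality_at_anchors <- function(forks, anchors,
                                           half_window = 10000,
                                           bin_size = 10,
                                           n_randomizations = 1000,
                                           conf = 0.99, seed = NULL) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(anchors)))
  if (!all(anchors$strand %in% c("+", "-"))) {
    stop("anchors must be stranded (+/-)")
  }
  if (!is.null(seed)) set.seed(seed)
  nb <- as.integer(2 * half_window / bin_size)
  # collect (fork, anchor) pairs as bin ranges in flipped coordinates
  fork_idx <- integer(0); bin_a <- integer(0); bin_b <- integer(0)
  co <- logical(0)
  for (j in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[j]; p <- anchors$pos[j]; st <- anchors$strand[j]
    sel <- which(forks$chrom == ch & forks$end > p - half_window &
                   forks$start < p + half_window)
    if (length(sel) == 0) next
    rs <- forks$start[sel] - p
    re <- forks$end[sel] - p
    if (st == "-") {
      tmp <- rs; rs <- -re; re <- -tmp
    }
    rs <- pmax(rs, -half_window)
    re <- pmin(re, half_window)
    a <- floor(rs / bin_size) + nb / 2 + 1
    b <- ceiling(re / bin_size) + nb / 2
    keep <- a <= b
    fork_idx <- c(fork_idx, sel[keep])
    bin_a <- c(bin_a, as.integer(a[keep]))
    bin_b <- c(bin_b, as.integer(b[keep]))
    co <- c(co, ((forks$direction[sel] == "right") == (st == "+"))[keep])
  }
  accumulate <- function(weights) {
    d <- numeric(nb + 1)
    for (k in seq_along(weights)) {
      d[bin_a[k]] <- d[bin_a[k]] + weights[k]
      d[bin_b[k] + 1] <- d[bin_b[k] + 1] - weights[k]
    }
    cumsum(d[-(nb + 1)])
  }
  co_obs <- accumulate(as.numeric(co))
  total <- accumulate(rep(1, length(co)))
  out <- data.frame(
    offset_start = (seq_len(nb) - 1 - nb / 2) * bin_size,
    offset_end = (seq_len(nb) - nb / 2) * bin_size,
    co = co_obs, counter = total - co_obs, total = total)
  if (n_randomizations > 0 && length(co) > 0) {
    nf <- max(fork_idx)
    reps <- vapply(seq_len(n_randomizations), function(r) {
      flip <- stats::runif(nf) < 0.5
      accumulate(as.numeric(xor(co, flip[fork_idx])))
    }, numeric(nb))
    if (nb == 1) reps <- matrix(reps, nrow = 1)
    out$null_mean <- rowMeans(reps)
    qs <- apply(reps, 1, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                names = FALSE)
    out$null_lo <- qs[1, ]
    out$null_hi <- qs[2, ]
  }
  class(out) <- c("directionality_profile", "data.frame")
  out
}

#' Initiation density within, upstream of, and flanking genes
#'
#' Computes the read-normalized initiation density ([rigr()]) for three
#' strand-aware zones derived from a gene table: transcribed gene bodies,
#' windows immediately upstream of the transcription start sites, and
#' distal flanks on both sides.
#'
#' @param sites Initiation sites `data.frame`.
#' @param fp Read footprints ([footprints()]).
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `tes`, `strand`).
#' @param upstream_window Bp upstream of the TSS (default 25 kb).
#' @param flank Bp of distal flank on each side (default 100 kb).
#' @param ... Passed to [rigr()] (randomizations, subsampling, seed).
#' @return `list(gene_body = , upstream = , flank = )` of `rigr_result`s.
#' @export
gene_body_rigr <- function(sites, fp, genes, upstream_window = 25000,
                           flank = 100000, ...) {
  stopifnot(all(c("chrom", "tss", "tes", "strand") %in% names(genes)))
  lo <- pmin(genes$tss, genes$tes)
  hi <- pmax(genes$tss, genes$tes)
  body <- data.frame(chrom = genes$chrom, start = lo, end = hi)
  plus <- genes$strand == "+"
  up <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, pmax(0, genes$tss - upstream_window), genes$tss),
    end = ifelse(plus, genes$tss, genes$tss + upstream_window))
  fl <- rbind(
    data.frame(chrom = genes$chrom, start = pmax(0, lo - flank), end = lo),
    data.frame(chrom = genes$chrom, start = hi, end = hi + flank))
  attr(body, "region_set_name") <- "gene_body"
  attr(up, "region_set_name") <- "upstream"
  attr(fl, "region_set_name") <- "flank"
  list(gene_body = rigr(sites, fp, body, ...),
       upstream = rigr(sites, fp, up, ...),
       flank = rigr(sites, fp, fl, ...))
}

# Per-chromosome integrator over a bedGraph track: integral of value and
# of coverage over [s, e), vectorized.
signal_integrator <- function(signal) {
  by_chrom <- split(signal, signal$chrom)
  lapply(by_chrom, function(d) {
    ord <- order(d$start)
    s <- d$start[ord]; e <- d$end[ord]; v <- d$value[ord]
    if (any(s[-1] < e[-length(e)])) {
      stop("overlapping bedGraph intervals")
    }
    list(s = s, e = e,
         cumv = cumsum(v * (e - s)), cumc = cumsum(e - s), v = v)
  })
}

integrate_signal <- function(itg, x, what = c("value", "coverage")) {
  what <- match.arg(what)
  i <- findInterval(x, itg$s)
  out <- numeric(length(x))
  pos <- i > 0
  ip <- i[pos]
  tail_len <- pmax(0, itg$e[ip] - x[pos])
  if (what == "value") {
    out[pos] <- itg$cumv[ip] - itg$v[ip] * tail_len
  } else {
    out[pos] <- itg$cumc[ip] - tail_len
  }
  out
}

#' Signal meta-profile around anchor points
#'
#' Extracts a matrix of binned signal values centred on each anchor
#' midpoint (one row per anchor, one column per bin across
#' `+/- half_window`) from a bedGraph track, and summarizes each bin across
#' anchors. Bins with no signal coverage are `NA` and excluded from the
#' summary. The geometric mean is computed on `value + 1` (pseudocount) and
#' reported with the offset removed.
#'
#' @param anchors `data.frame` with `chrom` and either `pos` or
#'   `start`/`end` (midpoint used).
#' @param signal bedGraph `data.frame` (`chrom`, `start`, `end`, `value`),
#'   non-overlapping intervals.
#' @param half_window Half-width of the window (default 100 kb).
#' @param bin_size Bin width (default 1 kb).
#' @param stat Summary across anchors: `"mean"`, `"sum"` or
#'   `"geometric_mean"`.
#' @param fp Optional footprints; when supplied together with
#'   `n_randomizations > 0`, anchors are re-placed uniformly within the
#'   footprints to build a null band around the summary curve.
#' @param n_randomizations Anchor randomizations (0 to skip).
#' @param conf Confidence level of the null band (default 0.99).
#' @param seed Optional integer seed.
#' @return An object of class `meta_profile`: list with `matrix`
#'   (anchors x bins), `bins` (`offset_start`, `offset_end`), `summary`,
#'   `stat`, and optional `null_mean` / `null_lo` / `null_hi`.
#' @export
meta_profile <- function(anchors, signal, half_window = 100000,
                         bin_size = 1000,
                         stat = c("mean", "sum", "geometric_mean"),
                         fp = NULL, n_randomizations = 0, conf = 0.99,
                         seed = NULL) {
  stat <- match.arg(stat)
  if (!is.null(seed)) set.seed(seed)
  itg <- signal_integrator(signal)
  nb <- as.integer(2 * half_window / bin_size)
  offs <- (seq_len(nb) - 1 - nb / 2) * bin_size

  profile_matrix <- function(anch) {
    mid <- if ("pos" %in% names(anch)) anch$pos else
      (anch$start + anch$end) / 2
    M <- matrix(NA_real_, nrow(anch), nb)
    for (i in seq_len(nrow(anch))) {
      it <- itg[[anch$chrom[i]]]
      if (is.null(it)) next
      edges <- mid[i] + c(offs, half_window)
      iv <- diff(integrate_signal(it, edges, "value"))
      ic <- diff(integrate_signal(it, edges, "coverage"))
      M[i, ] <- ifelse(ic > 0, iv / ic, NA_real_)
    }
    M
  }
  summarize <- function(M) {
    apply(M, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0) return(NA_real_)
      switch(stat,
             mean = mean(col),
             sum = sum(col),
             geometric_mean = exp(mean(log(col + 1))) - 1)
    })
  }
  M <- profile_matrix(anchors)
  out <- list(matrix = M,
              bins = data.frame(offset_start = offs,
                                offset_end = offs + bin_size),
              summary = summarize(M), stat = stat)
  if (!is.null(fp) && n_randomizations > 0) {
    mid <- if ("pos" %in% names(anchors)) anchors$pos else
      (anchors$start + anchors$end) / 2
    widths <- rep(1, length(mid))
    reps <- vapply(seq_len(n_randomizations), function(r) {
      ra <- place_sites_in_footprints(widths, fp)
      summarize(profile_matrix(ra))
    }, numeric(nb))
    if (nb == 1) reps <- matrix(reps, nrow = 1)
    out$null_mean <- rowMeans(reps, na.rm = TRUE)
    qs <- apply(reps, 1, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                na.rm = TRUE, names = FALSE)
    out$null_lo <- qs[1, ]
    out$null_hi <- qs[2, ]
  }
  class(out) <- "meta_profile"
  out
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d anchors x %d bins (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$stat))
  invisible(x)
}
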