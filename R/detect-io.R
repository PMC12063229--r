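#' Per-thymidine BrdU probability track for one aligned molecule
#'
#' The central single-read container: the reference span of the molecule
#' and, at every thymidine position within it (forward-reference frame),
#' the probability that the position carries BrdU rather than thymidine.
#'
#' @param read_id Read identifier.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open reference span (bp).
#' @param strand `"+"` or `"-"`. Probabilities are always reported on
#'   forward-reference coordinates; strand is retained only for
#'   transcription-aware analyses.
#' @param positions Strictly increasing thymidine coordinates in
#'   `[start, end)`.
#' @param probabilities BrdU probabilities in `[0, 1]`, one per position.
#' @return An object of class `brdu_read`.
#' @export
brdu_read <- function(read_id, chrom, start, end, strand = "+",
                      positions = integer(0), probabilities = numeric(0)) {
  if (length(positions) != length(probabilities)) {
    stop("positions and probabilities must have equal length")
  }
  if (length(positions) > 0) {
    if (is.unsorted(positions, strictly = TRUE)) {
      stop("positions must be strictly increasing")
    }
    if (positions[1] < start || positions[length(positions)] >= end) {
      stop("positions must lie within [start, end)")
    }
    if (any(probabilities < 0 | probabilities > 1)) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(read_id = as.character(read_id), chrom = as.character(chrom),
         start = as.numeric(start), end = as.numeric(end), strand = strand,
         positions = as.numeric(positions),
         probabilities = as.numeric(probabilities)),
    class = "brdu_read")
}

#' @export
print.brdu_read <- function(x, ...) {
  cat(sprintf("<brdu_read> %s %s:%.0f-%.0f(%s) %d thymidines\n",
              x$read_id, x$chrom, x$start, x$end, x$strand,
              length(x$positions)))
  invisible(x)
}

#' Read a detect-format file of per-thymidine BrdU probabilities
#'
#' Parses the text format emitted by nanopore BrdU base callers: records
#' start with a header line `>read_id chrom start end strand`, followed by
#' tab-separated `position probability` lines (extra columns, such as the
#' reference 6-mer, are ignored). Lines starting with `#` are comments.
#' Files ending in `.gz` are decompressed transparently.
#'
#' @param path Path to the detect file.
#' @param min_length Reads whose reference span is shorter than this are
#'   dropped (with a message reporting the count). Default 1000 bp.
#' @return A list of [brdu_read()] objects.
#' @export
read_detect <- function(path, min_length = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  is_header <- startsWith(lines, ">")
  if (length(lines) > 0 && !is_header[1]) {
    stop("malformed detect file: data before first header at line ",
         lineno[1])
  }
  if (length(lines) == 0) return(list())

  hdr_idx <- which(is_header)
  hdr_fields <- strsplit(sub("^>", "", lines[hdr_idx]), "[ \t]+")
  bad <- which(lengths(hdr_fields) < 5)
  if (length(bad) > 0) {
    stop("malformed header at line ", lineno[hdr_idx[bad[1]]])
  }
  ids <- vapply(hdr_fields, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate read_id in detect file: ",
         ids[duplicated(ids)][1])
  }

  block <- findInterval(seq_along(lines), hdr_idx)
  data_idx <- which(!is_header)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    bad <- data_idx[which(lengths(fields) < 2)[1]]
    stop("malformed data line at line ", lineno[bad])
  }
  pos <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  prob <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(pos) || anyNA(prob)) {
    bad <- data_idx[which(is.na(pos) | is.na(prob))[1]]
    stop("non-numeric position/probability at line ", lineno[bad])
  }
  if (any(prob < 0 | prob > 1)) {
    bad <- data_idx[which(prob < 0 | prob > 1)[1]]
    stop("probability outside [0, 1] at line ", lineno[bad])
  }

  reads <- lapply(seq_along(hdr_idx), function(b) {
    h <- hdr_fields[[b]]
    sel <- data_idx[block[data_idx] == b]
    p <- pos[match(sel, data_idx)]
    q <- prob[match(sel, data_idx)]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("non-monotone positions in read ", h[1])
    }
    tryCatch(
      brdu_read(h[1], h[2], as.numeric(h[3]), as.numeric(h[4]), h[5], p, q),
      error = function(e) stop("record '", h[1], "': ", conditionMessage(e),
                               call. = FALSE))
  })
  spans <- vapply(reads, function(r) r$end - r$start, 0)
  short <- spans < min_length
  if (any(short)) {
    message(sum(short), " read(s) shorter than ", min_length, " bp dropped")
  }
  reads[!short]
}

#' Write reads in detect format
#'
#' Probabilities are written with six decimal places, so
#' `read_detect(write_detect(x))` round-trips exactly at that precision.
#'
#' @param reads List of [brdu_read()] objects.
#' @param path Output path (`.gz` for compressed output).
#' @return Invisibly, `path`.
#' @export
write_detect <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("#detect format: >read_id chrom start end strand", con)
  for (r in reads) {
    writeLines(sprintf(">%s %s %.0f %.0f %s", r$read_id, r$chrom,
                       r$start, r$end, r$strand), con)
    if (length(r$positions) > 0) {
      writeLines(sprintf("%.0f\t%.6f", r$positions, r$probabilities), con)
    }
  }
  invisible(path)
}

#' Read a BED file as a region set
#'
#' BED3/BED6, 0-based half-open. Track/browser/comment lines are skipped.
#'
#' @param path Path to the BED file (`.gz` supported).
#' @param expect_strand If `TRUE`, require a strand column.
#' @param name Optional name for the region set (default: file base name).
#' @param genome Optional `data.frame(name, length)`; if given, regions on
#'   unknown chromosomes or beyond chromosome ends are an error.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`; carries the set name as the
#'   attribute `"region_set_name"`.
#' @export
read_bed <- function(path, expect_strand = FALSE, name = NULL,
                     genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(lines) == 0) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  } else {
    fields <- strsplit(lines, "[ \t]+")
    nf <- min(lengths(fields))
    if (nf < 3) stop("BED line with fewer than 3 fields")
    df <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(nf))),
                        stringsAsFactors = FALSE)
    names(df) <- cols[seq_len(nf)]
    df$start <- as.numeric(df$start)
    df$end <- as.numeric(df$end)
    if (anyNA(df$start) || anyNA(df$end)) stop("non-numeric BED coordinate")
    if (any(df$start >= df$end)) stop("BED interval with start >= end")
    if (!is.null(df$score)) {
      df$score <- suppressWarnings(as.numeric(df$score))
    }
  }
  if (expect_strand && is.null(df$strand) && nrow(df) > 0) {
    stop("strand column required but absent")
  }
  if (!is.null(genome)) {
    len <- genome$length[match(df$chrom, genome$name)]
    if (anyNA(len)) {
      stop("unknown chromosome: ", df$chrom[which(is.na(len))[1]])
    }
    if (any(df$end > len)) stop("BED interval beyond chromosome end")
  }
  attr(df, "region_set_name") <-
    if (is.null(name)) sub("\\.(bed|bed\\.gz)$", "", basename(path)) else name
  df
}

#' Write a region set as BED
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(regions))
  df <- regions[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to the bedGraph file (`.gz` supported).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `value`;
#'   intervals carry a constant value, coordinates 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path)
  if (is.null(df$name) && nrow(df) > 0) {
    stop("bedGraph requires 4 columns (chrom start end value)")
  }
  value <- if (nrow(df) == 0) numeric(0) else suppressWarnings(
    as.numeric(df$name))
  if (anyNA(value)) stop("non-numeric bedGraph value")
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    value = value)
  attr(out, "region_set_name") <- attr(df, "region_set_name")
  out
}

#' Aligned footprints of a set of reads
#'
#' One interval per read, equal to the read's reference span. Footprints
#' are the shuffle domain and the coverage denominator for all
#' read-normalized enrichment statistics.
#'
#' @param reads List of [brdu_read()] objects, or a list of
#'   `molecule_truth` objects from the simulator.
#' @return A `data.frame` with columns `read_id`, `chrom`, `start`, `end`.
#' @export
footprints <- function(reads) {
  ids <- vapply(reads, `[[`, "", "read_id")
  if (anyDuplicated(ids)) stop("duplicate read_ids in footprints")
  data.frame(read_id = ids,
             chrom = vapply(reads, `[[`, "", "chrom"),
             start = vapply(reads, `[[`, 0, "start"),
             end = vapply(reads, `[[`, 0, "end"))
}
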