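#' Construct a per-base depth track
#'
#' A `DepthTrack` holds the read depth of one sample on one platform as a set
#' of per-chromosome integer vectors (index i = 0-based position i-1).
#' Positions beyond the stored span, and chromosomes absent from the track,
#' have depth 0 by convention: completeness must penalize missing bases, not
#' skip them.
#'
#' @param depth named list of non-negative integer vectors, one per chromosome.
#' @param sample_id,platform labels carried through to summaries.
#' @return an object of class `DepthTrack`.
#' @export
depth_track <- function(depth, sample_id = "sample", platform = "platform") {
  stopifnot(is.list(depth), !is.null(names(depth)) || length(depth) == 0L)
  for (chrom in names(depth)) {
    d <- depth[[chrom]]
    if (anyNA(d) || any(d < 0)) {
      stop("negative or missing depth on chromosome ", chrom)
    }
    depth[[chrom]] <- as.integer(d)
  }
  structure(
    list(sample_id = sample_id, platform = platform, depth = depth),
    class = "DepthTrack"
  )
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat(sprintf(
    "DepthTrack '%s' (%s): %d chromosome(s), %d bases stored\n",
    x$sample_id, x$platform, length(x$depth),
    sum(vapply(x$depth, length, integer(1)))
  ))
  invisible(x)
}

#' Query depth over a genomic interval
#'
#' Coordinates are 0-based half-open, as everywhere inside the package.
#' Bases outside the stored span (or on an unknown chromosome) return 0.
#'
#' @param track a `DepthTrack`.
#' @param chrom chromosome label.
#' @param start,end 0-based half-open interval.
#' @return integer vector of length `end - start`.
#' @export
track_depth <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "DepthTrack"), start >= 0, end > start)
  n <- end - start
  out <- integer(n)
  d <- track$depth[[chrom]]
  if (is.null(d)) return(out)
  # stored indices are 1-based: base b (0-based) lives at d[b + 1]
  hi <- min(end, length(d))
  if (hi > start) out[seq_len(hi - start)] <- d[(start + 1L):hi]
  out
}

#' Write a depth track to disk
#'
#' Two dialects: `bedgraph` (4 columns, 0-based half-open, zero-depth runs
#' omitted) and `per_base_tsv` (3 columns chrom / 1-based position / depth,
#' zero-depth bases omitted).
#'
#' @param track a `DepthTrack`.
#' @param path output file.
#' @param dialect `"bedgraph"` or `"per_base_tsv"`.
#' @export
write_depth_track <- function(track, path, dialect = c("bedgraph", "per_base_tsv")) {
  dialect <- match.arg(dialect)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$depth)) {
    d <- track$depth[[chrom]]
    if (length(d) == 0L) next
    if (dialect == "bedgraph") {
      r <- rle(d)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0L
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%d",
                           chrom, starts[keep], ends[keep], r$values[keep]), con)
      }
    } else {
      keep <- which(d > 0L)
      if (length(keep)) {
        writeLines(sprintf("%s\t%d\t%d", chrom, keep, d[keep]), con)
      }
    }
  }
  invisible(path)
}

#' Read a depth track from disk
#'
#' @param path input file.
#' @param dialect `"bedgraph"` (0-based half-open) or `"per_base_tsv"`
#'   (1-based positions).
#' @param sample_id,platform labels to attach.
#' @param strict if `TRUE`, unsorted input is an error; otherwise it is sorted
#'   internally. Overlapping bedGraph records are always an error.
#' @return a `DepthTrack`.
#' @export
read_depth_track <- function(path, dialect = c("bedgraph", "per_base_tsv"),
                             sample_id = "sample", platform = "platform",
                             strict = FALSE) {
  dialect <- match.arg(dialect)
  n_cols <- if (dialect == "bedgraph") 4L else 3L
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", rep("integer", n_cols - 1L)),
                           col.names = if (dialect == "bedgraph")
                             c("chrom", "start", "end", "depth")
                           else c("chrom", "pos", "depth"),
                           blank.lines.skip = TRUE)
  if (nrow(tab) == 0L) return(depth_track(list(), sample_id, platform))
  if (any(tab$depth < 0)) stop("negative depth in ", path)
  rows_by_chrom <- split(seq_len(nrow(tab)), factor(tab$chrom, unique(tab$chrom)))
  depth <- lapply(rows_by_chrom, function(idx) {
    sub <- tab[idx, , drop = FALSE]
    chrom <- sub$chrom[1L]
    if (dialect == "bedgraph") {
      if (any(sub$end <= sub$start)) stop("empty or inverted bedGraph record on ", chrom)
      o <- order(sub$start)
      if (strict && !identical(o, seq_len(nrow(sub)))) {
        stop("unsorted bedGraph records on ", chrom, " (strict mode)")
      }
      sub <- sub[o, , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
        stop("overlapping bedGraph records on ", chrom)
      }
      d <- integer(max(sub$end))
      lens <- sub$end - sub$start
      d[sequence(lens) + rep(sub$start, lens)] <- rep(sub$depth, lens)
    } else {
      if (any(sub$pos < 1L)) stop("per-base TSV positions are 1-based; got pos < 1 on ", chrom)
      o <- order(sub$pos)
      if (strict && !identical(o, seq_len(nrow(sub)))) {
        stop("unsorted per-base records on ", chrom, " (strict mode)")
      }
      sub <- sub[o, , drop = FALSE]
      if (anyDuplicated(sub$pos)) stop("duplicate positions on ", chrom)
      d <- integer(max(sub$pos))
      d[sub$pos] <- sub$depth
    }
    d
  })
  names(depth) <- names(rows_by_chrom)
  depth_track(depth, sample_id, platform)
}

#' Depth statistics over one interval
#'
#' Computes the minimum, mean, and fraction of bases at or above each
#' threshold over every base of `[start, end)`; bases missing from the track
#' count as depth 0.
#'
#' @param track a `DepthTrack`.
#' @param chrom,start,end the interval (0-based half-open).
#' @param thresholds integer vector of depth cutoffs.
#' @return list with `min_depth`, `mean_depth`, `n_bases`, and `frac_at_least`
#'   (named numeric vector, one entry per threshold).
#' @export
interval_depth_stats <- function(track, chrom, start, end, thresholds = 13L) {
  if (end <= start) stop("empty interval: [", start, ", ", end, ")")
  d <- track_depth(track, chrom, start, end)
  frac <- vapply(thresholds, function(t) mean(d >= t), numeric(1))
  names(frac) <- as.character(thresholds)
  list(
    min_depth = min(d),
    mean_depth = mean(d),
    n_bases = length(d),
    frac_at_least = frac
  )
}
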