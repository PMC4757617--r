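#' GC fraction of a sequence
#'
#' (G + C) / (A + C + G + T); N bases are excluded from the denominator, and a
#' sequence of only Ns yields `NA`. Soft-masked lowercase counts as ordinary
#' sequence.
#'
#' @param sequence a character string (or anything coercible) over A,C,G,T,N.
#' @return GC fraction in `[0, 1]`, or `NA` for all-N input.
#' @export
exon_gc <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L || nchar(s) == 0L) stop("need one non-empty sequence")
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("unexpected characters in sequence: ", paste(bad, collapse = ""))
  denom <- sum(bases != "N")
  if (denom == 0L) return(NA_real_)
  sum(bases %in% c("G", "C")) / denom
}

#' Annotate exons with GC fractions from a reference
#'
#' @param exons exon data.frame.
#' @param reference named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @return `exons` with a `gc_fraction` column computed from the exact exon
#'   spans of the reference.
#' @export
annotate_gc <- function(exons, reference) {
  ref <- stats::setNames(as.character(reference), names(reference))
  exons$gc_fraction <- vapply(seq_len(nrow(exons)), function(i) {
    exon_gc(substr(ref[[exons$chrom[i]]], exons$start[i] + 1L, exons$end[i]))
  }, numeric(1))
  exons
}

mean_exon_depths <- function(tracks, exons) {
  # per-exon mean depth averaged over samples
  m <- exon_mean_depth_matrix(tracks, exons)
  rowMeans(m)
}

#' GC-stratified mean-depth profile
#'
#' Bins eligible exons by GC fraction (left-closed, right-open; last bin
#' closed) and reports, per bin, the unweighted mean over exons of each exon's
#' across-sample mean depth — the "mean read depth per GC content" view that
#' exposes capture GC bias. Empty bins carry `NA`, never 0.
#'
#' @param tracks list of `DepthTrack`s for one platform.
#' @param exons exon data.frame with `gc_fraction` (see [annotate_gc()]).
#' @param bin_width GC bin width; must divide 1 evenly (default 0.01).
#' @param platform label attached to the output.
#' @param weight `"exon"` (unweighted mean over exons, default) or `"length"`
#'   (exon-length weighted).
#' @return data.frame: platform, bin_low, bin_high, n_exons, mean_depth.
#' @export
gc_depth_profile <- function(tracks, exons, bin_width = 0.01,
                             platform = tracks[[1]]$platform,
                             weight = c("exon", "length")) {
  weight <- match.arg(weight)
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9) stop("bin_width must divide 1 evenly")
  if (is.null(exons$gc_fraction) || anyNA(exons$gc_fraction)) {
    stop("exons need a gc_fraction column without NAs (see annotate_gc)")
  }
  d <- mean_exon_depths(tracks, exons)
  bin <- pmin(floor(exons$gc_fraction / bin_width), n_bins - 1L) + 1L
  w <- if (weight == "length") exons$end - exons$start else rep(1, nrow(exons))
  mean_depth <- rep(NA_real_, n_bins)
  n_exons <- integer(n_bins)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    n_exons[b] <- length(idx)
    mean_depth[b] <- sum(w[idx] * d[idx]) / sum(w[idx])
  }
  data.frame(platform = platform,
             bin_low = (seq_len(n_bins) - 1L) * bin_width,
             bin_high = seq_len(n_bins) * bin_width,
             n_exons = n_exons, mean_depth = mean_depth,
             stringsAsFactors = FALSE)
}

#' Mean GC percentage of an exon subset
#'
#' Unweighted mean of exon GC fractions, as a percentage (e.g. first exons
#' versus all exons). Display rounding to integer percent is left to the
#' caller; the exact value is returned.
#'
#' @param exons exon data.frame with `gc_fraction`.
#' @param subset logical vector or exon_id character vector selecting the
#'   subset; default all exons.
#' @return mean GC as a percentage.
#' @export
subset_mean_gc <- function(exons, subset = NULL) {
  sel <- if (is.null(subset)) rep(TRUE, nrow(exons))
         else if (is.logical(subset)) subset
         else exons$exon_id %in% subset
  if (!any(sel)) stop("empty exon subset")
  100 * mean(exons$gc_fraction[sel])
}
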