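#' Is an interval completely covered at a depth cutoff?
#'
#' TRUE iff every base of `[start, end)` has depth >= t (inclusive comparison,
#' matching the ">= 13 reads at each nucleotide position" convention).
#'
#' @param track a `DepthTrack`.
#' @param chrom,start,end the interval (0-based half-open).
#' @param t depth cutoff in reads.
#' @return logical flag.
#' @export
interval_complete <- function(track, chrom, start, end, t = 13L) {
  if (end <= start) stop("empty interval: [", start, ", ", end, ")")
  all(track_depth(track, chrom, start, end) >= t)
}

# per-sample completeness flags for a set of intervals
intervals_complete <- function(track, intervals, t) {
  vapply(seq_len(nrow(intervals)), function(i) {
    interval_complete(track, intervals$chrom[i], intervals$start[i],
                      intervals$end[i], t)
  }, logical(1))
}

# mean and t-based 95% CI across per-sample percentages
percent_ci <- function(per_sample, conf = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  n <- length(per_sample)
  m <- mean(per_sample)
  if (n < 2L) {
    message("single sample: confidence interval omitted")
    return(list(mean = m, lo = NA_real_, hi = NA_real_))
  }
  se <- stats::sd(per_sample) / sqrt(n)
  q <- if (method == "t") stats::qt(1 - (1 - conf) / 2, df = n - 1L)
       else stats::qnorm(1 - (1 - conf) / 2)
  list(mean = m, lo = m - q * se, hi = m + q * se)
}

summary_row <- function(gene_set, stratum, t, n_complete, n_items, ci_method) {
  per_sample <- 100 * n_complete / n_items
  ci <- percent_ci(per_sample, method = ci_method)
  data.frame(
    gene_set = gene_set, stratum = stratum, threshold = t,
    n_items = n_items, n_samples = length(per_sample),
    mean_percent = ci$mean, ci_lo = ci$lo, ci_hi = ci$hi,
    per_sample_percent = I(list(per_sample)),
    n_complete = I(list(n_complete)),
    stringsAsFactors = FALSE
  )
}

# deduplicate exons sharing coordinates across transcripts
dedup_exons <- function(exons) {
  exons[!duplicated(paste(exons$chrom, exons$start, exons$end)), , drop = FALSE]
}

#' Complete-coverage summaries per stratum
#'
#' For each sample, the percentage of exons, first exons, and genes whose
#' every base reaches the depth cutoff, with the across-sample mean and a 95%
#' confidence interval. Exons shared by several transcripts are counted once
#' (deduplicated on coordinates); the first-exon set is the union of
#' start-codon-containing exons over transcripts, deduplicated the same way.
#' A gene is complete iff all its assessable (eligible) exons are complete.
#'
#' @param tracks list of `DepthTrack`s (one per sample).
#' @param exons eligible exon data.frame (already filtered).
#' @param gene_exons named list gene_id -> exon_ids from
#'   [derive_gene_eligibility()]; computed from `exons` when `NULL`.
#' @param t depth cutoff (reads).
#' @param gene_set label attached to the output rows.
#' @param ci_method `"t"` (default, suits n = 5 samples) or `"normal"`.
#' @return data.frame with one row per stratum (all_exons, first_exons, genes):
#'   mean percent, CI bounds, denominators, and per-sample percentages as a
#'   list column (exact fractions retained via `n_complete`).
#' @export
completeness_summary <- function(tracks, exons, gene_exons = NULL, t = 13L,
                                 gene_set = "RefSeq", ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(tracks) >= 1L, nrow(exons) >= 1L)
  if (is.null(exons$exon_id)) exons$exon_id <- exon_id_of(exons)
  if (is.null(gene_exons)) gene_exons <- split(exons$exon_id, exons$gene_id)

  uniq <- dedup_exons(exons)
  first <- dedup_exons(exons[exons$is_first_exon, , drop = FALSE])

  # completeness per unique exon coordinate, per sample
  flags <- vapply(tracks, intervals_complete, logical(nrow(uniq)),
                  intervals = uniq, t = t)
  flags <- matrix(flags, nrow = nrow(uniq))
  rownames(flags) <- paste(uniq$chrom, uniq$start, uniq$end)

  coord_of <- function(df) paste(df$chrom, df$start, df$end)
  first_flags <- flags[coord_of(first), , drop = FALSE]

  # gene complete iff all assessable exons complete
  coord_by_id <- stats::setNames(coord_of(exons), exons$exon_id)
  gene_flags <- vapply(gene_exons, function(ids) {
    apply(flags[unique(coord_by_id[ids]), , drop = FALSE], 2L, all)
  }, logical(length(tracks)))
  gene_flags <- t(matrix(gene_flags, nrow = length(tracks)))

  rbind(
    summary_row(gene_set, "all_exons", t, colSums(flags), nrow(uniq), ci_method),
    if (nrow(first))
      summary_row(gene_set, "first_exons", t, colSums(first_flags), nrow(first), ci_method),
    summary_row(gene_set, "genes", t, colSums(gene_flags), length(gene_exons), ci_method)
  )
}

variant_bases <- function(variant) {
  # 1-based positions whose depth determines coverage of the variant:
  # a span >= 1 variant needs all its reference bases; a pure insertion
  # (span 0, pos = base left of the insertion point) needs both flanks.
  pos <- variant$pos; len <- variant$ref_span_len
  if (len >= 1L) pos:(pos + len - 1L) else c(pos, pos + 1L)
}

variant_covered <- function(track, variants, t, mode = c("span", "start_only")) {
  mode <- match.arg(mode)
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    bases <- if (mode == "start_only") v$pos else variant_bases(v)
    all(track_depth(track, v$chrom, min(bases) - 1L, max(bases)) >= t)
  }, logical(1))
}

#' Variant and variant-exon coverage summaries
#'
#' A variant with reference span >= 1 bp counts covered iff all its reference
#' bases reach the cutoff; a pure insertion (span 0) iff both bases flanking
#' the insertion point do. The `variant_exons` stratum asks whether the host
#' exon of each coding variant is completely covered.
#'
#' @param tracks list of `DepthTrack`s.
#' @param variants data.frame: chrom, pos (1-based first reference base),
#'   ref_span_len (0..20), is_coding, optional exon_id.
#' @param exons exon data.frame (needed for the variant_exons stratum; omit to
#'   skip it).
#' @param t depth cutoff.
#' @param gene_set label for the output rows.
#' @param mode `"span"` (default) assesses the full reference span;
#'   `"start_only"` only the first position.
#' @param on_unknown_chrom `"error"` or `"skip"` (skipped variants counted and
#'   reported via attribute `n_skipped`).
#' @param ci_method passed to the CI computation.
#' @return completeness data.frame with strata `variants` and (if exons given)
#'   `variant_exons`.
#' @export
variant_coverage <- function(tracks, variants, exons = NULL, t = 13L,
                             gene_set = "HGMD", mode = c("span", "start_only"),
                             on_unknown_chrom = c("error", "skip"),
                             ci_method = c("t", "normal")) {
  mode <- match.arg(mode)
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  ci_method <- match.arg(ci_method)
  stopifnot(nrow(variants) >= 1L)
  if (any(variants$ref_span_len > 20L)) stop("reference span exceeds 20 bp")
  known_chroms <- unique(unlist(lapply(tracks, function(tr) names(tr$depth))))
  unknown <- !(variants$chrom %in% known_chroms)
  n_skipped <- 0L
  if (any(unknown)) {
    if (on_unknown_chrom == "error") {
      stop("variant on chromosome absent from all tracks: ",
           variants$chrom[which(unknown)[1L]])
    }
    n_skipped <- sum(unknown)
    variants <- variants[!unknown, , drop = FALSE]
    if (nrow(variants) == 0L) stop("no variants left after skipping unknown chromosomes")
  }

  cov <- vapply(tracks, variant_covered, logical(nrow(variants)),
                variants = variants, t = t, mode = mode)
  cov <- matrix(cov, nrow = nrow(variants))
  out <- summary_row(gene_set, "variants", t, colSums(cov), nrow(variants), ci_method)

  if (!is.null(exons)) {
    if (is.null(exons$exon_id)) exons$exon_id <- exon_id_of(exons)
    host_ids <- unique(variants$exon_id[variants$is_coding & !is.na(variants$exon_id)])
    host <- dedup_exons(exons[exons$exon_id %in% host_ids, , drop = FALSE])
    if (nrow(host)) {
      ef <- vapply(tracks, intervals_complete, logical(nrow(host)),
                   intervals = host, t = t)
      ef <- matrix(ef, nrow = nrow(host))
      out <- rbind(out, summary_row(gene_set, "variant_exons", t,
                                    colSums(ef), nrow(host), ci_method))
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Largest cutoff at which coverage is everywhere complete
#'
#' Returns the largest integer t such that every base of every interval in
#' every track has depth >= t — i.e. the global minimum depth over all
#' assessed bases. This is how a "minimum number of reads at which coverage
#' is 100.00% complete" cutoff is derived from data.
#'
#' @param tracks list of `DepthTrack`s.
#' @param intervals data.frame chrom/start/end.
#' @return integer global minimum depth.
#' @export
max_complete_threshold <- function(tracks, intervals) {
  stopifnot(nrow(intervals) >= 1L)
  min(vapply(tracks, function(tr) {
    min(vapply(seq_len(nrow(intervals)), function(i) {
      min(track_depth(tr, intervals$chrom[i], intervals$start[i], intervals$end[i]))
    }, numeric(1)))
  }, numeric(1)))
}

#' Mean depth required to guarantee a per-base cutoff
#'
#' Linear scaling: if mean depth `mean_depth` guarantees every base at
#' `achieved_t`, guaranteeing `desired_t` requires
#' `mean_depth * desired_t / achieved_t` (e.g. 65x guaranteeing 13x scales to
#' 100x for a 20x guarantee).
#'
#' @param mean_depth achieved mean depth (reads).
#' @param achieved_t per-base cutoff guaranteed at that mean depth.
#' @param desired_t per-base cutoff to guarantee.
#' @return required mean depth (reads).
#' @export
required_mean_depth <- function(mean_depth, achieved_t, desired_t) {
  if (achieved_t < 1) stop("achieved_t must be >= 1")
  mean_depth * desired_t / achieved_t
}

#' Near-miss report: intervals just below the completeness cutoff
#'
#' Lists every assessed interval whose minimum depth lies in `[floor, t - 1]`,
#' per sample, sorted by minimum depth ascending — the "partially covered
#' with 7-12 reads" footnote material of a clinical coverage report.
#'
#' @param tracks list of `DepthTrack`s.
#' @param intervals data.frame chrom/start/end with optional exon_id.
#' @param t completeness cutoff.
#' @param floor lowest minimum depth reported (must be < t).
#' @return data.frame: sample_id, exon_id, chrom, start, end, min_depth.
#' @export
near_miss_report <- function(tracks, intervals, t = 13L, floor = 7L) {
  if (floor >= t) stop("floor must be below the cutoff t")
  ids <- if (!is.null(intervals$exon_id)) intervals$exon_id
         else sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  rows <- lapply(tracks, function(tr) {
    mins <- vapply(seq_len(nrow(intervals)), function(i) {
      min(track_depth(tr, intervals$chrom[i], intervals$start[i], intervals$end[i]))
    }, numeric(1))
    hit <- which(mins >= floor & mins <= t - 1L)
    if (!length(hit)) return(NULL)
    data.frame(sample_id = tr$sample_id, exon_id = ids[hit],
               chrom = intervals$chrom[hit], start = intervals$start[hit],
               end = intervals$end[hit], min_depth = mins[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), exon_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      min_depth = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$min_depth, out$sample_id, out$exon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Missed fraction from printed counts
#'
#' The fraction of catalogued variants a platform may fail to detect, given a
#' missed count and a total, with its complement (the covered percentage).
#' Display formatting is two decimals; exact values are returned.
#'
#' @param n_missed,n_total counts with `0 <= n_missed <= n_total`, `n_total > 0`.
#' @return list: `missed_percent`, `covered_percent` (exact), and `display`
#'   (two-decimal strings).
#' @export
missed_fraction <- function(n_missed, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_missed < 0 || n_missed > n_total) stop("need 0 <= n_missed <= n_total")
  missed <- 100 * n_missed / n_total
  covered <- 100 * (n_total - n_missed) / n_total
  list(missed_percent = missed, covered_percent = covered,
       display = c(missed = sprintf("%.2f", missed),
                   covered = sprintf("%.2f", covered)))
}

#' Shift depth tracks so the global assessed minimum equals a target
#'
#' Used to emulate deriving the completeness cutoff from the data: the cutoff
#' of interest is the observed global minimum depth over all assessed bases,
#' i.e. the largest t at which completeness is exactly 100%. Adds a constant
#' to every stored base so that minimum equals `target`.
#'
#' @param tracks list of `DepthTrack`s.
#' @param intervals assessed intervals (chrom/start/end).
#' @param target desired global minimum depth.
#' @return the shifted list of tracks.
#' @export
calibrate_min_depth <- function(tracks, intervals, target = 13L) {
  shift <- target - max_complete_threshold(tracks, intervals)
  lapply(tracks, function(tr) {
    tr$depth <- lapply(tr$depth, function(d) pmax(as.integer(d + shift), 0L))
    tr
  })
}
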