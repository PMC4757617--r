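#' Exon-by-sample mean-depth matrix
#'
#' Entry (e, s) is the mean depth of exon e in sample s, with bases missing
#' from the track counted as depth 0. Input to both coefficient-of-variation
#' directions.
#'
#' @param tracks list of `DepthTrack`s.
#' @param exons exon data.frame.
#' @return numeric matrix, rownames exon_id, colnames sample_id.
#' @export
exon_mean_depth_matrix <- function(tracks, exons) {
  stopifnot(length(tracks) >= 1L)
  if (nrow(exons) == 0L) stop("no exons to assess")
  if (is.null(exons$exon_id)) exons$exon_id <- exon_id_of(exons)
  m <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(exons)), function(i) {
      mean(track_depth(tr, exons$chrom[i], exons$start[i], exons$end[i]))
    }, numeric(1))
  }, numeric(nrow(exons)))
  m <- matrix(m, nrow = nrow(exons),
              dimnames = list(exons$exon_id,
                              vapply(tracks, `[[`, character(1), "sample_id")))
  m
}

cv_of <- function(x, sd_denom) {
  s <- if (sd_denom == "n-1") stats::sd(x)
       else sqrt(mean((x - mean(x))^2))
  s / mean(x)
}

#' Intra-individual coverage variability
#'
#' For each sample, the coefficient of variation (SD/mean) of exon mean depths
#' across exons — how uneven one individual's coverage is across the exome.
#' Capture platforms typically show several-fold higher values than PCR-free
#' genome sequencing.
#'
#' @param mat exon-by-sample matrix from [exon_mean_depth_matrix()].
#' @param sd_denom `"n-1"` (sample SD, default) or `"n"`.
#' @return list: `per_sample` (named cv vector), `mean`, `n_exons`,
#'   `n_samples`, `sd_convention`.
#' @export
intra_individual_cv <- function(mat, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  if (nrow(mat) < 2L) stop("need at least 2 exons")
  means <- colMeans(mat)
  if (any(means == 0)) stop("degenerate track: sample with mean depth 0")
  per_sample <- apply(mat, 2L, cv_of, sd_denom = sd_denom)
  list(per_sample = per_sample, mean = mean(per_sample),
       n_exons = nrow(mat), n_samples = ncol(mat), sd_convention = sd_denom)
}

#' Inter-individual coverage variability
#'
#' For each exon, the coefficient of variation of its mean depth across
#' samples; the summary is the unweighted mean over exons. Exons with mean
#' depth 0 across all samples cannot carry a cv and are excluded (their count
#' is reported). Comparable values across platforms indicate that coverage
#' differences are reproducible rather than noise.
#'
#' @param mat exon-by-sample matrix.
#' @param sd_denom `"n-1"` (default) or `"n"`.
#' @return list: `per_exon` (named cv vector over assessable exons), `mean`,
#'   `n_exons_used`, `n_zero_mean_excluded`, `n_samples`, `sd_convention`.
#' @export
inter_individual_cv <- function(mat, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  means <- rowMeans(mat)
  usable <- means > 0
  if (!any(usable)) stop("all exons have mean depth 0")
  per_exon <- apply(mat[usable, , drop = FALSE], 1L, cv_of, sd_denom = sd_denom)
  list(per_exon = per_exon, mean = mean(per_exon),
       n_exons_used = sum(usable), n_zero_mean_excluded = sum(!usable),
       n_samples = ncol(mat), sd_convention = sd_denom)
}

#' Ratio of two coefficients of variation
#'
#' @param cv_a,cv_b non-negative cv values; `cv_b` must be positive.
#' @return `cv_a / cv_b`.
#' @export
cv_ratio <- function(cv_a, cv_b) {
  if (cv_b <= 0) stop("cv_b must be positive")
  cv_a / cv_b
}

#' Full cv decomposition for one platform
#'
#' @param tracks list of `DepthTrack`s (one platform).
#' @param exons eligible exon data.frame.
#' @param sd_denom SD convention passed through.
#' @return list of class `CVSummary` combining both directions.
#' @export
cv_summary <- function(tracks, exons, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  mat <- exon_mean_depth_matrix(tracks, exons)
  intra <- intra_individual_cv(mat, sd_denom)
  inter <- if (ncol(mat) >= 2L) inter_individual_cv(mat, sd_denom) else NULL
  structure(list(
    platform = tracks[[1]]$platform,
    intra_cv_per_sample = intra$per_sample,
    intra_cv_mean = intra$mean,
    inter_cv_per_exon_mean = if (is.null(inter)) NA_real_ else inter$mean,
    n_exons = nrow(mat), n_samples = ncol(mat),
    sd_convention = sd_denom
  ), class = "CVSummary")
}

#' @export
print.CVSummary <- function(x, ...) {
  cat(sprintf(
    "CVSummary [%s]: intra-individual cv %.3f (mean of %d samples), inter-individual cv %.3f (mean over %d exons), SD denom %s\n",
    x$platform, x$intra_cv_mean, x$n_samples, x$inter_cv_per_exon_mean,
    x$n_exons, x$sd_convention))
  invisible(x)
}
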