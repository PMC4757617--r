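#' Platform depth profile
#'
#' Describes how a sequencing platform distributes read depth: the target mean
#' depth, a GC-dependent efficiency curve, a reproducible per-exon capture
#' efficiency (lognormal, shared across samples), a per-sample global factor
#' (library yield), a per-base noise model, and whether depth is restricted to
#' capture targets.
#'
#' The GC efficiency curve is log-quadratic, peaked at `gc_opt`:
#' `g(x) = max(gc_floor, exp(-gc_strength * (x - gc_opt)^2))`, so
#' `gc_strength = 0` gives a flat curve (no GC bias) and larger values
#' penalize GC-rich and GC-poor sequence more steeply.
#'
#' @param name platform label.
#' @param mean_depth target mean on-target depth in reads (> 0).
#' @param gc_strength curvature of the GC efficiency curve (0 = flat).
#' @param gc_opt GC fraction of peak efficiency.
#' @param gc_floor lower clamp on efficiency, in (0, 1].
#' @param exon_bias_sd lognormal sigma of the per-exon capture efficiency
#'   (shared across samples — the reproducible component of capture bias).
#' @param sample_effect_sd lognormal sigma of the per-sample global factor.
#' @param noise per-base count model: `"poisson"`, `"nb"` (negative binomial
#'   with dispersion `nb_size`), or `"none"` (rounded expectation).
#' @param nb_size negative-binomial size parameter (only for `noise = "nb"`).
#' @param restricted_to_targets if `TRUE` (capture platforms), depth outside
#'   target exons decays to 0 beyond a `capture_pad` flank.
#' @param capture_pad flank width (bp) with decaying off-target efficiency.
#' @param mean_convention `"on_target"` (default: expected mean depth over
#'   exon bases equals `mean_depth` after GC/exon bias) or `"per_base"`
#'   (`mean_depth` is the pre-bias per-base expectation, so realized on-target
#'   means fall below it under capture bias).
#' @return a `PlatformProfile` list.
#' @export
platform_profile <- function(name, mean_depth,
                             gc_strength = 0, gc_opt = 0.45, gc_floor = 0.01,
                             exon_bias_sd = 0, sample_effect_sd = 0,
                             noise = c("poisson", "nb", "none"), nb_size = 10,
                             restricted_to_targets = FALSE, capture_pad = 50L,
                             mean_convention = c("on_target", "per_base")) {
  noise <- match.arg(noise)
  mean_convention <- match.arg(mean_convention)
  stopifnot(mean_depth > 0, gc_strength >= 0, gc_floor > 0, gc_floor <= 1,
            exon_bias_sd >= 0, sample_effect_sd >= 0, capture_pad >= 0)
  structure(list(
    name = name, mean_depth = mean_depth,
    gc_strength = gc_strength, gc_opt = gc_opt, gc_floor = gc_floor,
    exon_bias_sd = exon_bias_sd, sample_effect_sd = sample_effect_sd,
    noise = noise, nb_size = nb_size,
    restricted_to_targets = restricted_to_targets, capture_pad = as.integer(capture_pad),
    mean_convention = mean_convention
  ), class = "PlatformProfile")
}

#' Evaluate a profile's GC efficiency curve
#' @param profile a `PlatformProfile`.
#' @param gc GC fraction(s) in `[0, 1]`.
#' @return efficiency in `(0, 1]`.
#' @export
gc_bias_curve <- function(profile, gc) {
  pmax(profile$gc_floor, exp(-profile$gc_strength * (gc - profile$gc_opt)^2))
}

#' Bundled platform profiles
#'
#' Three study conditions: hybridization-capture exome sequencing at 154x
#' mean on-target depth with strong GC bias and reproducible per-exon capture
#' efficiency; genome sequencing with PCR during library preparation at 65x
#' with mild GC bias; and PCR-free genome sequencing at 65x with a flat GC
#' curve and near-zero exon-level bias.
#'
#' @return a `PlatformProfile`.
#' @name bundled_profiles
NULL

#' @rdname bundled_profiles
#' @export
wes_profile <- function() {
  platform_profile("WES", mean_depth = 154, gc_strength = 24, gc_opt = 0.45,
                   exon_bias_sd = 0.5, sample_effect_sd = 0.1,
                   restricted_to_targets = TRUE)
}

#' @rdname bundled_profiles
#' @export
wgs_wpcr_profile <- function() {
  platform_profile("WGS_wPCR", mean_depth = 65, gc_strength = 2, gc_opt = 0.45,
                   exon_bias_sd = 0.1, sample_effect_sd = 0.1)
}

#' @rdname bundled_profiles
#' @export
wgs_pcrfree_profile <- function() {
  platform_profile("WGS", mean_depth = 65, gc_strength = 0,
                   exon_bias_sd = 0.1, sample_effect_sd = 0.1)
}

#' Simulation configuration
#'
#' @param n_genes number of genes (one synthetic chromosome each).
#' @param exons_per_gene length-2 range of exon counts per gene.
#' @param exon_length length-2 range of exon lengths (bp).
#' @param gc_target_range GC-fraction target range for ordinary exons.
#' @param first_exon_gc_shift additive GC shift for first exons (they are
#'   GC-rich in real annotation; default +0.08, i.e. ~59% vs ~51%).
#' @param intron_length length-2 range of intron lengths (bp).
#' @param flank length of chromosome flanks around the gene body (bp).
#' @param n_samples samples per platform (default 5).
#' @param variant_density catalogued variants per kb of exon sequence.
#' @param noncoding_variant_fraction fraction of variants placed outside exons.
#' @param seed integer seed fixing all downstream randomness.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 100L, exons_per_gene = c(2L, 10L),
                       exon_length = c(100L, 300L),
                       gc_target_range = c(0.35, 0.65),
                       first_exon_gc_shift = 0.08,
                       intron_length = c(50L, 200L), flank = 200L,
                       n_samples = 5L, variant_density = 0.5,
                       noncoding_variant_fraction = 0.11,
                       seed = 1L) {
  stopifnot(n_genes >= 0, n_samples >= 0, variant_density >= 0,
            noncoding_variant_fraction >= 0, noncoding_variant_fraction <= 1,
            length(exons_per_gene) == 2L, exons_per_gene[1] >= 1,
            diff(exons_per_gene) >= 0,
            length(exon_length) == 2L, exon_length[1] >= 10,
            diff(exon_length) >= 0,
            gc_target_range[1] >= 0, gc_target_range[2] <= 1,
            diff(gc_target_range) >= 0)
  structure(list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length), gc_target_range = gc_target_range,
    first_exon_gc_shift = first_exon_gc_shift,
    intron_length = as.integer(intron_length), flank = as.integer(flank),
    n_samples = as.integer(n_samples), variant_density = variant_density,
    noncoding_variant_fraction = noncoding_variant_fraction,
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

# uniform draw from lo..hi that is immune to R's sample(n) scalar expansion
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

# sequence of length len with exactly round(gc * len) G/C bases, shuffled
random_seq_with_gc <- function(len, gc) {
  n_gc <- round(gc * len)
  strong <- sample(c("G", "C"), n_gc, replace = TRUE)
  weak <- sample(c("A", "T"), len - n_gc, replace = TRUE)
  paste(sample(c(strong, weak)), collapse = "")
}

#' Simulate a coding-exon annotation and matching reference
#'
#' Lays out `n_genes` genes on one synthetic chromosome each: non-overlapping
#' exons separated by introns, each exon's sequence constructed with a GC
#' fraction within +/- 0.05 of a target drawn from `gc_target_range` (first
#' exons are shifted GC-rich). Exactly one first exon per transcript: the
#' 5'-most exon on the transcript's strand.
#'
#' @param config a `SimulationConfig`.
#' @return list: `exons` (data.frame with gc_target and exon_id) and
#'   `reference` (named character vector of chromosome sequences).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  if (config$n_genes == 0L) {
    ex <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     strand = character(0), gene_id = character(0),
                     transcript_id = character(0), exon_index = integer(0),
                     is_first_exon = logical(0), gc_target = numeric(0),
                     exon_id = character(0), stringsAsFactors = FALSE)
    return(list(exons = ex, reference = character(0)))
  }
  rows <- vector("list", config$n_genes)
  reference <- character(config$n_genes)
  chroms <- sprintf("chrS%04d", seq_len(config$n_genes))
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2])
    lens <- sample_range(config$exon_length[1], config$exon_length[2], n_ex)
    introns <- if (n_ex > 1L)
      sample_range(config$intron_length[1], config$intron_length[2], n_ex - 1L)
    else integer(0)
    strand <- sample(c("+", "-"), 1L)
    starts <- config$flank + cumsum(c(0L, lens[-n_ex] + introns))
    ends <- starts + lens
    chrom_len <- ends[n_ex] + config$flank
    # exon_index follows transcription order; first exon is the 5'-most
    idx <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    gc <- stats::runif(n_ex, config$gc_target_range[1], config$gc_target_range[2])
    gc[idx == 1L] <- pmin(0.95, gc[idx == 1L] + config$first_exon_gc_shift)
    exon_seqs <- vapply(seq_len(n_ex), function(i)
      random_seq_with_gc(lens[i], gc[i]), character(1))
    # background: uniform random bases between and around exons
    seq_parts <- character(2L * n_ex + 1L)
    gaps <- c(starts, chrom_len) - c(0L, ends)
    for (i in seq_len(n_ex + 1L)) {
      seq_parts[2L * i - 1L] <- paste(sample(c("A", "C", "G", "T"), gaps[i],
                                             replace = TRUE), collapse = "")
    }
    seq_parts[2L * seq_len(n_ex)] <- exon_seqs
    reference[g] <- paste(seq_parts, collapse = "")
    gene_id <- sprintf("GENE%04d", g)
    rows[[g]] <- data.frame(
      chrom = chroms[g], start = starts, end = ends, strand = strand,
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
      exon_index = idx, is_first_exon = idx == 1L, gc_target = gc,
      stringsAsFactors = FALSE
    )
  }
  names(reference) <- chroms
  exons <- do.call(rbind, rows)
  exons$exon_id <- exon_id_of(exons)
  validate_exons(exons)
  list(exons = exons, reference = reference)
}

#' Simulate confounder resources with ground truth
#'
#' Emits the three resources the eligibility filter consumes — a
#' unique-mappability interval set, a common-CNV interval set, and an
#' assembly-identity table — after knocking a configurable fraction of exons
#' out through each mechanism: a 1+ bp gap punched into the mappability
#' track inside the exon, a small CNV overlapping the exon by at least 1 bp,
#' or an identity-table mismatch. A ground-truth eligibility table is emitted
#' alongside so tests never re-derive labels from generator internals.
#'
#' @param exons exon data.frame from [simulate_annotation()].
#' @param config a `SimulationConfig` (its seed, offset, governs selection).
#' @param mappability_gap_fraction,cnv_fraction,identity_mismatch_fraction
#'   fraction of exons hit by each mechanism (sampled independently).
#' @return list: `mappability`, `cnvs` (chrom/start/end data.frames),
#'   `identity` (exon_id/identical), `truth` (exon_id, eligible, per-mechanism
#'   flags).
#' @export
simulate_confounders <- function(exons, config,
                                 mappability_gap_fraction = 0.03,
                                 cnv_fraction = 0.03,
                                 identity_mismatch_fraction = 0.02) {
  if (nrow(exons) == 0L) stop("exon set is empty")
  set.seed(config$seed + 1L)
  n <- nrow(exons)
  pick <- function(frac) {
    k <- round(frac * n)
    seq_len(n) %in% sample.int(n, k)
  }
  gap_hit <- pick(mappability_gap_fraction)
  cnv_hit <- pick(cnv_fraction)
  id_hit <- pick(identity_mismatch_fraction)

  # mappability: every chromosome fully covered, minus a 1-5 bp gap inside
  # each selected exon
  chrom_spans <- do.call(rbind, lapply(split(exons, exons$chrom), function(e) {
    data.frame(chrom = e$chrom[1], start = 0L,
               end = max(e$end) + 1000L, stringsAsFactors = FALSE)
  }))
  rownames(chrom_spans) <- NULL
  mapp <- chrom_spans
  for (i in which(gap_hit)) {
    w <- sample(1:5, 1L)
    gs <- sample_range(exons$start[i], exons$end[i] - w)
    row <- which(mapp$chrom == exons$chrom[i] & mapp$start <= gs & mapp$end >= gs + w)
    hit <- mapp[row[1L], ]
    mapp <- rbind(mapp[-row[1L], ],
                  data.frame(chrom = hit$chrom, start = hit$start, end = gs),
                  data.frame(chrom = hit$chrom, start = gs + w, end = hit$end))
  }
  mapp <- mapp[mapp$end > mapp$start, , drop = FALSE]
  mapp <- mapp[order(mapp$chrom, mapp$start), , drop = FALSE]
  rownames(mapp) <- NULL

  cnvs <- if (any(cnv_hit)) {
    do.call(rbind, lapply(which(cnv_hit), function(i) {
      pos <- sample_range(exons$start[i], exons$end[i] - 1L)
      data.frame(chrom = exons$chrom[i], start = pos,
                 end = pos + sample(1:50, 1L), stringsAsFactors = FALSE)
    }))
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))

  identity <- data.frame(exon_id = exons$exon_id,
                         identical = as.integer(!id_hit),
                         stringsAsFactors = FALSE)
  truth <- data.frame(exon_id = exons$exon_id,
                      mappability_gap = gap_hit, cnv_overlap = cnv_hit,
                      assembly_mismatch = id_hit,
                      eligible = !(gap_hit | cnv_hit | id_hit),
                      stringsAsFactors = FALSE)
  list(mappability = mapp, cnvs = cnvs, identity = identity, truth = truth)
}

#' Simulate per-base depth tracks for one platform
#'
#' The expected depth at a base of exon e in sample s is
#' `mu * g(GC_e) * b_e * a_s`: the platform mean, the GC efficiency at the
#' exon's GC fraction, a per-exon lognormal capture efficiency `b_e` (shared
#' across samples — reproducible capture bias), and a per-sample lognormal
#' factor `a_s`. Lognormals are mean-1 parameterized, so their coefficients of
#' variation are `sqrt(exp(sigma^2) - 1)`. Per-base counts follow the
#' profile's noise model. Capture platforms keep a +/- `capture_pad` bp flank
#' at linearly decaying efficiency and zero depth beyond it; genome-wide
#' platforms cover whole chromosomes, with non-exonic bases at background GC
#' efficiency.
#'
#' @param exons exon data.frame with `gc_target` or `gc_fraction`.
#' @param reference named character vector of chromosome sequences (gives
#'   chromosome lengths; GC is taken from the exon table).
#' @param profile a `PlatformProfile`.
#' @param config a `SimulationConfig` (`n_samples`, seed).
#' @return list of `DepthTrack`s, one per sample.
#' @export
simulate_depth <- function(exons, reference, profile, config) {
  set.seed((config$seed + 2L + sum(utf8ToInt(profile$name))) %% .Machine$integer.max)
  stopifnot(inherits(profile, "PlatformProfile"))
  gc <- if (!is.null(exons$gc_fraction)) exons$gc_fraction else exons$gc_target
  if (is.null(gc)) stop("exons need gc_fraction or gc_target")
  n_ex <- nrow(exons)
  chrom_len <- nchar(reference)

  b_e <- if (profile$exon_bias_sd > 0)
    stats::rlnorm(n_ex, -profile$exon_bias_sd^2 / 2, profile$exon_bias_sd)
  else rep(1, n_ex)
  a_s <- if (profile$sample_effect_sd > 0)
    stats::rlnorm(config$n_samples, -profile$sample_effect_sd^2 / 2,
                  profile$sample_effect_sd)
  else rep(1, config$n_samples)

  g_e <- gc_bias_curve(profile, gc)
  # on-target convention: rescale so the expected mean over exon bases is mu
  scale <- if (profile$mean_convention == "on_target") {
    w <- exons$end - exons$start
    1 / (sum(w * g_e * b_e) / sum(w))
  } else 1

  draw <- function(lambda) {
    switch(profile$noise,
           poisson = stats::rpois(length(lambda), lambda),
           nb = stats::rnbinom(length(lambda), mu = lambda, size = profile$nb_size),
           none = as.integer(round(lambda)))
  }

  lapply(seq_len(config$n_samples), function(s) {
    depth <- lapply(names(reference), function(chrom) {
      len <- chrom_len[[chrom]]
      lam <- if (profile$restricted_to_targets) numeric(len)
             else rep(profile$mean_depth * scale *
                      gc_bias_curve(profile, 0.5) * a_s[s], len)
      idx <- which(exons$chrom == chrom)
      for (i in idx) {
        span <- (exons$start[i] + 1L):exons$end[i]
        lam_exon <- profile$mean_depth * scale * g_e[i] * b_e[i] * a_s[s]
        lam[span] <- lam_exon
        if (profile$restricted_to_targets && profile$capture_pad > 0L) {
          pad <- profile$capture_pad
          ramp <- lam_exon * 0.5 * (1 - (seq_len(pad) - 1L) / pad)
          left <- exons$start[i] - seq_len(pad) + 1L
          ok <- left >= 1L
          lam[left[ok]] <- pmax(lam[left[ok]], ramp[ok])
          right <- exons$end[i] + seq_len(pad)
          ok <- right <= len
          lam[right[ok]] <- pmax(lam[right[ok]], ramp[ok])
        }
      }
      draw(lam)
    })
    names(depth) <- names(reference)
    depth_track(depth, sample_id = sprintf("%s_s%d", profile$name, s),
                platform = profile$name)
  })
}

#' Simulate a variant catalog
#'
#' Places catalogued small variants (reference span 0-20 bp; span 1 = SNV,
#' 0 = pure insertion) in the simulated genome: coding variants inside exons
#' (span fully contained), a configured fraction non-coding outside exons.
#'
#' @param exons exon data.frame.
#' @param config a `SimulationConfig` (`variant_density` per exon kb,
#'   `noncoding_variant_fraction`, seed).
#' @return data.frame: chrom, pos (1-based), ref_span_len, is_coding, exon_id
#'   (NA for non-coding).
#' @export
simulate_variant_catalog <- function(exons, config) {
  if (nrow(exons) == 0L) stop("exon set is empty")
  set.seed(config$seed + 3L)
  uniq <- dedup_exons(exons)
  total_kb <- sum(uniq$end - uniq$start) / 1000
  n_coding <- round(config$variant_density * total_kb *
                    (1 - config$noncoding_variant_fraction))
  n_noncoding <- round(config$variant_density * total_kb *
                       config$noncoding_variant_fraction)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref_span_len = integer(0), is_coding = logical(0),
                      exon_id = character(0), stringsAsFactors = FALSE)
  if (n_coding + n_noncoding == 0L) return(empty)
  # mostly SNVs, some indels up to 20 bp, a few pure insertions
  draw_span <- function(n) sample(0:20, n, replace = TRUE,
                                  prob = c(0.05, 0.70, rep(0.25 / 19, 19)))
  coding <- if (n_coding > 0L) {
    ei <- sample.int(nrow(uniq), n_coding, replace = TRUE,
                     prob = uniq$end - uniq$start)
    span <- draw_span(n_coding)
    pos <- vapply(seq_len(n_coding), function(i) {
      lo <- uniq$start[ei[i]] + 1L
      hi <- uniq$end[ei[i]] - max(span[i] - 1L, 1L)
      sample_range(lo, max(lo, hi))
    }, integer(1))
    data.frame(chrom = uniq$chrom[ei], pos = pos, ref_span_len = span,
               is_coding = TRUE, exon_id = uniq$exon_id[ei],
               stringsAsFactors = FALSE)
  } else empty
  noncoding <- if (n_noncoding > 0L) {
    ci <- sample(unique(exons$chrom), n_noncoding, replace = TRUE)
    pos <- vapply(ci, function(chrom) {
      ex <- exons[exons$chrom == chrom, ]
      repeat {
        p <- sample.int(min(ex$start), 1L)  # upstream flank: never exonic
        if (!any(p > ex$start & p <= ex$end)) return(p)
      }
    }, integer(1))
    data.frame(chrom = ci, pos = pos, ref_span_len = draw_span(n_noncoding),
               is_coding = FALSE, exon_id = NA_character_,
               stringsAsFactors = FALSE)
  } else empty
  out <- rbind(coding, noncoding)
  rownames(out) <- NULL
  out
}

#' Write the reference as FASTA
#' @param reference named character vector of sequences.
#' @param path output FASTA.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a variant catalog TSV
#' @param variants variant data.frame.
#' @param path output TSV.
#' @export
write_variants <- function(variants, path) {
  out <- variants
  out$is_coding <- as.integer(out$is_coding)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant catalog TSV
#' @param path TSV with chrom, pos, ref_span_len, is_coding, exon_id.
#' @export
read_variants <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(exon_id = "character"))
  v$is_coding <- as.logical(v$is_coding)
  v
}

#' Write an identity table TSV
#' @param identity data.frame exon_id/identical.
#' @param path output TSV.
#' @export
write_identity <- function(identity, path) {
  utils::write.table(identity, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identity table TSV
#' @param path TSV with exon_id, identical.
#' @export
read_identity <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
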