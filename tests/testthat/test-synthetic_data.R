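test_that("annotation simulation honors its geometry and GC contracts", {
  # empty case
  empty <- simulate_annotation(sim_config(n_genes = 0))
  expect_equal(nrow(empty$exons), 0L)
  expect_length(empty$reference, 0L)

  # determinism: identical config + seed => identical output
  a <- simulate_annotation(sim_config(n_genes = 20, seed = 5))
  b <- simulate_annotation(sim_config(n_genes = 20, seed = 5))
  expect_identical(a, b)

  ex <- a$exons
  # exons non-overlapping and sorted within each gene
  for (g in split(ex, ex$gene_id)) {
    o <- order(g$start)
    expect_true(all(g$start[o][-1] >= g$end[o][-nrow(g)]))
  }
  # exactly one first exon per transcript, at the 5' end of the strand
  per_tx <- tapply(ex$is_first_exon, ex$transcript_id, sum)
  expect_true(all(per_tx == 1L))
  for (g in split(ex, ex$transcript_id)) {
    first <- g[g$is_first_exon, ]
    expect_equal(first$exon_index, 1L)
    if (g$strand[1] == "+") expect_equal(first$start, min(g$start))
    else expect_equal(first$end, max(g$end))
  }
})

test_that("realized GC, recounted independently from the FASTA, is within 0.05 of target", {
  sim <- simulate_annotation(sim_config(n_genes = 50, seed = 31,
                                        gc_target_range = c(0.3, 0.8),
                                        first_exon_gc_shift = 0))
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(sim$reference, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  for (i in seq_len(nrow(sim$exons))) {
    e <- sim$exons[i, ]
    sub <- Biostrings::subseq(seqs[[e$chrom]], e$start + 1L, e$end)
    gc <- sum(Biostrings::letterFrequency(sub, c("G", "C"))) / length(sub)
    expect_lt(abs(gc - e$gc_target), 0.05)
  }
})

test_that("confounder simulation emits resources matching its ground truth", {
  cfg <- sim_config(n_genes = 40, seed = 13)
  sim <- simulate_annotation(cfg)

  # no confounders: everything eligible, resources trivial
  none <- simulate_confounders(sim$exons, cfg, 0, 0, 0)
  expect_true(all(none$truth$eligible))
  expect_equal(nrow(none$cnvs), 0L)
  expect_true(all(none$identity$identical == 1L))
  m <- apply_eligibility(sim$exons, none$mappability, none$cnvs, none$identity,
                         allowed_chroms = unique(sim$exons$chrom))
  expect_true(all(m$eligible))

  # requested fractions appear in the emitted truth table
  conf <- simulate_confounders(sim$exons, cfg, 0.05, 0.1, 0.05)
  n <- nrow(sim$exons)
  expect_equal(sum(conf$truth$cnv_overlap), round(0.1 * n))
  expect_equal(sum(conf$truth$mappability_gap), round(0.05 * n))
  expect_equal(sum(conf$truth$assembly_mismatch), round(0.05 * n))

  # the filter reproduces the ground-truth labels exactly
  mask <- apply_eligibility(sim$exons, conf$mappability, conf$cnvs, conf$identity,
                            allowed_chroms = unique(sim$exons$chrom))
  mask <- mask[match(conf$truth$exon_id, mask$exon_id), ]
  expect_identical(mask$eligible, conf$truth$eligible)
  expect_identical(mask$not_uniquely_mappable, conf$truth$mappability_gap)
  expect_identical(mask$cnv_overlap, conf$truth$cnv_overlap)
  expect_identical(mask$assembly_mismatch, conf$truth$assembly_mismatch)
})

test_that("a 1 bp mappability gap makes an exon ineligible", {
  ex <- toy_exons()
  mapp <- rbind(
    data.frame(chrom = "chrA", start = 0L, end = 30L),
    data.frame(chrom = "chrA", start = 31L, end = 2000L),  # base 30 missing
    data.frame(chrom = "chrB", start = 0L, end = 2000L)
  )
  m <- apply_eligibility(ex, mapp, no_cnvs(), all_identical(ex),
                         allowed_chroms = c("chrA", "chrB"))
  expect_false(m$eligible[m$exon_id == ex$exon_id[1]])
})

test_that("noise-free flat-curve depth is exactly the configured mean", {
  cfg <- sim_config(n_genes = 5, n_samples = 2, seed = 3)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("flat", mean_depth = 65, gc_strength = 0,
                           exon_bias_sd = 0, sample_effect_sd = 0, noise = "none")
  tracks <- simulate_depth(sim$exons, sim$reference, prof, cfg)
  expect_length(tracks, 2L)
  for (tr in tracks) {
    for (i in seq_len(nrow(sim$exons))) {
      e <- sim$exons[i, ]
      expect_true(all(track_depth(tr, e$chrom, e$start, e$end) == 65L))
    }
  }
})

test_that("Poisson depth recovers the configured mean within 3 SE", {
  cfg <- sim_config(n_genes = 120, n_samples = 1, exons_per_gene = c(5, 5),
                    exon_length = c(300, 300), seed = 17)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("poisson", mean_depth = 65, gc_strength = 0,
                           exon_bias_sd = 0, sample_effect_sd = 0)
  tr <- simulate_depth(sim$exons, sim$reference, prof, cfg)[[1]]
  d <- unlist(lapply(seq_len(nrow(sim$exons)), function(i) {
    e <- sim$exons[i, ]
    track_depth(tr, e$chrom, e$start, e$end)
  }))
  expect_gte(length(d), 1.5e5)
  se <- sqrt(65 / length(d))
  expect_lt(abs(mean(d) - 65), 3 * se)
})

test_that("a GC-penalizing curve depresses depth in the penalized GC range", {
  cfg <- sim_config(n_genes = 150, n_samples = 1, gc_target_range = c(0.3, 0.8),
                    first_exon_gc_shift = 0, seed = 23)
  sim <- simulate_annotation(cfg)
  exons <- annotate_gc(sim$exons, sim$reference)
  prof <- platform_profile("wes-like", mean_depth = 154, gc_strength = 24,
                           gc_opt = 0.45, exon_bias_sd = 0, sample_effect_sd = 0,
                           restricted_to_targets = TRUE)
  tr <- simulate_depth(exons, sim$reference, prof, cfg)[[1]]
  mean_of <- function(lo, hi) {
    idx <- which(exons$gc_fraction >= lo & exons$gc_fraction < hi)
    mean(vapply(idx, function(i)
      mean(track_depth(tr, exons$chrom[i], exons$start[i], exons$end[i])),
      numeric(1)))
  }
  expect_lt(mean_of(0.7, 0.8), mean_of(0.4, 0.5))
})

test_that("capture tracks are silent outside the padded targets", {
  cfg <- sim_config(n_genes = 4, n_samples = 1, seed = 29)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("cap", mean_depth = 100, exon_bias_sd = 0,
                           sample_effect_sd = 0, noise = "none",
                           restricted_to_targets = TRUE, capture_pad = 50L)
  tr <- simulate_depth(sim$exons, sim$reference, prof, cfg)[[1]]
  for (chrom in unique(sim$exons$chrom)) {
    ex <- sim$exons[sim$exons$chrom == chrom, ]
    len <- nchar(sim$reference[[chrom]])
    d <- track_depth(tr, chrom, 0, len)
    outside <- rep(TRUE, len)
    for (i in seq_len(nrow(ex))) {
      lo <- max(1L, ex$start[i] - 50L + 1L)
      hi <- min(len, ex$end[i] + 50L)
      outside[lo:hi] <- FALSE
    }
    expect_true(all(d[outside] == 0L))
    # on-target bases are covered
    for (i in seq_len(nrow(ex))) {
      expect_true(all(d[(ex$start[i] + 1L):ex$end[i]] > 0L))
    }
  }
})

test_that("variant catalogs respect density, span, and placement contracts", {
  cfg <- sim_config(n_genes = 30, seed = 41, variant_density = 1,
                    noncoding_variant_fraction = 0.2)
  sim <- simulate_annotation(cfg)

  none <- simulate_variant_catalog(sim$exons,
                                   sim_config(n_genes = 30, seed = 41,
                                              variant_density = 0))
  expect_equal(nrow(none), 0L)

  v <- simulate_variant_catalog(sim$exons, cfg)
  v2 <- simulate_variant_catalog(sim$exons, cfg)
  expect_identical(v, v2)  # determinism

  expect_true(all(v$ref_span_len >= 0 & v$ref_span_len <= 20))
  ex <- sim$exons
  for (i in which(v$is_coding)) {
    host <- ex[ex$exon_id == v$exon_id[i], ]
    expect_equal(nrow(host), 1L)
    expect_gte(v$pos[i], host$start + 1L)
    expect_lte(v$pos[i] + max(v$ref_span_len[i], 1L) - 1L, host$end)
  }
  for (i in which(!v$is_coding)) {
    on_chrom <- ex[ex$chrom == v$chrom[i], ]
    inside <- any(v$pos[i] > on_chrom$start & v$pos[i] <= on_chrom$end)
    expect_false(inside)
  }
  frac_nc <- mean(!v$is_coding)
  expect_equal(frac_nc, 0.2, tolerance = 0.05)
})

test_that("profile constructors enforce the documented invariants", {
  expect_error(platform_profile("bad", mean_depth = 0), "mean_depth")
  p <- wgs_pcrfree_profile()
  gc <- seq(0, 1, by = 0.05)
  expect_true(all(gc_bias_curve(p, gc) == 1))  # flat curve
  w <- wes_profile()
  eff <- gc_bias_curve(w, gc)
  expect_true(all(eff > 0 & eff <= 1))
  expect_equal(which.max(gc_bias_curve(w, gc)), which(gc == 0.45))
})
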