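test_that("interval completeness follows the inclusive per-base rule", {
  tr <- uniform_track(13L, c(chrA = 200L))
  expect_true(interval_complete(tr, "chrA", 0, 200, 13))
  expect_false(interval_complete(tr, "chrA", 0, 200, 14))

  dl <- list(chrA = rep(13L, 200L))
  dl$chrA[57] <- 12L
  tr2 <- depth_track(dl)
  expect_false(interval_complete(tr2, "chrA", 0, 200, 13))
  expect_true(interval_complete(tr2, "chrA", 0, 200, 12))
  expect_error(interval_complete(tr, "chrA", 10, 10, 13), "empty")
})

test_that("interval completeness and the global threshold match brute force", {
  set.seed(201)
  for (rep in 1:15) {
    dl <- random_depth_list(2L, c(100L, 600L), max_depth = 30L)
    tr <- depth_track(dl)
    iv <- random_intervals(dl, 8L)
    for (t in sample(1:30, 5)) {
      for (i in seq_len(nrow(iv))) {
        expect_identical(
          interval_complete(tr, iv$chrom[i], iv$start[i], iv$end[i], t),
          oracle_interval_complete(dl, iv$chrom[i], iv$start[i], iv$end[i], t))
      }
    }
    want <- min(vapply(seq_len(nrow(iv)), function(i)
      oracle_min_depth(dl, iv$chrom[i], iv$start[i], iv$end[i]), numeric(1)))
    expect_equal(max_complete_threshold(list(tr), iv), want)
  }
})

test_that("stratum summaries count exons, first exons, and genes correctly", {
  ex <- toy_exons()
  # all bases deep enough everywhere: 100.00% with zero-width CI
  trs <- lapply(1:5, function(s)
    uniform_track(20L, c(chrA = 300L, chrB = 300L), sample_id = paste0("s", s)))
  s <- completeness_summary(trs, ex, t = 13)
  expect_equal(s$mean_percent, c(100, 100, 100))
  expect_equal(s$ci_lo, s$ci_hi)
  expect_equal(s$ci_lo, c(100, 100, 100))

  # 1 of 4 exons incomplete in every one of 5 identical samples
  dl <- list(chrA = rep(20L, 300L), chrB = rep(20L, 300L))
  dl$chrA[30] <- 5L  # inside exon 1 (chrA 10-60)
  trs2 <- lapply(1:5, function(s) depth_track(dl, sample_id = paste0("s", s)))
  s2 <- completeness_summary(trs2, ex, t = 13)
  expect_equal(s2$mean_percent[s2$stratum == "all_exons"], 75)
  expect_equal(s2$ci_lo[s2$stratum == "all_exons"],
               s2$ci_hi[s2$stratum == "all_exons"])
  # the broken exon is G1's first exon: first-exon stratum 50%, genes 50%
  expect_equal(s2$mean_percent[s2$stratum == "first_exons"], 50)
  expect_equal(s2$mean_percent[s2$stratum == "genes"], 50)

  # single sample: no CI, with a logged note
  expect_message(s1 <- completeness_summary(trs2[1], ex, t = 13), "single sample")
  expect_true(is.na(s1$ci_lo[1]))
})

test_that("summaries agree with an independent per-sample recomputation", {
  cfg <- sim_config(n_genes = 60, seed = 19)
  sim <- simulate_annotation(cfg)
  exons <- annotate_gc(sim$exons, sim$reference)
  prof <- platform_profile("p", mean_depth = 20, gc_strength = 3,
                           exon_bias_sd = 0.4, sample_effect_sd = 0.1)
  trs <- simulate_depth(exons, sim$reference, prof, cfg)
  s <- completeness_summary(trs, exons, t = 13)

  uniq <- exons[!duplicated(paste(exons$chrom, exons$start, exons$end)), ]
  # independent recomputation via the raw depth vectors
  per_sample <- vapply(trs, function(tr) {
    100 * mean(vapply(seq_len(nrow(uniq)), function(i)
      oracle_interval_complete(tr$depth, uniq$chrom[i], uniq$start[i],
                               uniq$end[i], 13), logical(1)))
  }, numeric(1))
  got <- s$per_sample_percent[[which(s$stratum == "all_exons")]]
  expect_equal(unname(got), unname(per_sample), tolerance = 1e-9)
  m <- mean(per_sample)
  ci <- qt(0.975, 4) * sd(per_sample) / sqrt(5)
  expect_equal(s$mean_percent[s$stratum == "all_exons"], m, tolerance = 1e-9)
  expect_equal(s$ci_lo[s$stratum == "all_exons"], m - ci, tolerance = 1e-9)
  expect_equal(s$ci_hi[s$stratum == "all_exons"], m + ci, tolerance = 1e-9)
})

test_that("percent complete is non-increasing in the cutoff", {
  set.seed(202)
  cfg <- sim_config(n_genes = 25, seed = 37)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("p", mean_depth = 18, exon_bias_sd = 0.3)
  trs <- simulate_depth(sim$exons, sim$reference, prof, cfg)
  prev <- rep(Inf, 3)
  for (t in c(1, 5, 10, 13, 16, 20, 30)) {
    s <- completeness_summary(trs, sim$exons, t = t)
    expect_true(all(s$mean_percent <= prev + 1e-12))
    prev <- s$mean_percent
  }
})

test_that("gene completeness implies completeness of all its exons", {
  set.seed(203)
  cfg <- sim_config(n_genes = 30, seed = 43)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("p", mean_depth = 16, exon_bias_sd = 0.3)
  tr <- simulate_depth(sim$exons, sim$reference, prof, cfg)[[1]]
  ex <- sim$exons
  gene_exons <- split(ex$exon_id, ex$gene_id)
  # brute-force exon flags straight off the raw depth vectors
  complete_e <- vapply(seq_len(nrow(ex)), function(i)
    oracle_interval_complete(tr$depth, ex$chrom[i], ex$start[i], ex$end[i], 13),
    logical(1))
  names(complete_e) <- ex$exon_id
  gene_ok <- vapply(gene_exons, function(ids) all(complete_e[ids]), logical(1))
  suppressMessages(s <- completeness_summary(list(tr), ex, t = 13))
  expect_equal(s$mean_percent[s$stratum == "genes"], 100 * mean(gene_ok),
               tolerance = 1e-12)
  expect_equal(s$mean_percent[s$stratum == "all_exons"],
               100 * mean(complete_e), tolerance = 1e-12)
  # a complete gene stratum forces a complete exon stratum and vice versa at 100%
  if (all(complete_e)) expect_equal(s$mean_percent[s$stratum == "genes"], 100)
  if (any(!gene_ok)) expect_true(any(!complete_e))
})

test_that("variant coverage applies the span and insertion-flank rules", {
  dl <- list(chrA = rep(13L, 100L))
  tr <- depth_track(dl)
  v_snv <- data.frame(chrom = "chrA", pos = 50L, ref_span_len = 1L,
                      is_coding = TRUE, exon_id = NA_character_)
  s <- variant_coverage(list(tr), v_snv, t = 13)
  expect_equal(s$mean_percent[s$stratum == "variants"], 100)

  # 5 bp deletion with one internal base below the cutoff
  dl2 <- dl; dl2$chrA[52] <- 12L
  tr2 <- depth_track(dl2)
  v_del <- data.frame(chrom = "chrA", pos = 50L, ref_span_len = 5L,
                      is_coding = TRUE, exon_id = NA_character_)
  s2 <- variant_coverage(list(tr2), v_del, t = 13)
  expect_equal(s2$mean_percent[s2$stratum == "variants"], 0)
  # but a start-only assessment calls it covered
  s3 <- variant_coverage(list(tr2), v_del, t = 13, mode = "start_only")
  expect_equal(s3$mean_percent[s3$stratum == "variants"], 100)

  # pure insertion: both flanks must reach the cutoff
  v_ins <- data.frame(chrom = "chrA", pos = 51L, ref_span_len = 0L,
                      is_coding = TRUE, exon_id = NA_character_)
  expect_equal(variant_coverage(list(tr), v_ins, t = 13)$mean_percent[1], 100)
  expect_equal(variant_coverage(list(tr2), v_ins, t = 13)$mean_percent[1], 0)

  # unknown chromosome: strict errors, lenient skips with a count
  v_mix <- rbind(v_snv, data.frame(chrom = "chrZ", pos = 5L, ref_span_len = 1L,
                                   is_coding = FALSE, exon_id = NA_character_))
  expect_error(variant_coverage(list(tr), v_mix, t = 13), "absent")
  s4 <- variant_coverage(list(tr), v_mix, t = 13, on_unknown_chrom = "skip")
  expect_equal(attr(s4, "n_skipped"), 1L)
  expect_equal(s4$n_items[1], 1L)
})

test_that("variant coverage matches brute force on random fixtures", {
  set.seed(204)
  for (rep in 1:10) {
    dl <- random_depth_list(2L, c(200L, 500L), max_depth = 25L)
    tr <- depth_track(dl)
    n <- 100L
    v <- data.frame(
      chrom = sample(names(dl), n, replace = TRUE),
      pos = sample(2:150, n, replace = TRUE),
      ref_span_len = sample(0:20, n, replace = TRUE),
      is_coding = sample(c(TRUE, FALSE), n, replace = TRUE),
      exon_id = NA_character_, stringsAsFactors = FALSE
    )
    t <- sample(5:20, 1)
    s <- variant_coverage(list(tr), v, t = t)
    want <- mean(vapply(seq_len(n), function(i)
      oracle_variant_covered(dl, v[i, ], t), logical(1)))
    expect_equal(s$mean_percent[s$stratum == "variants"], 100 * want,
                 tolerance = 1e-12)
  }
})

test_that("the maximum complete threshold sits exactly at the boundary", {
  set.seed(205)
  cfg <- sim_config(n_genes = 15, seed = 47)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("p", mean_depth = 40, exon_bias_sd = 0.2)
  trs <- simulate_depth(sim$exons, sim$reference, prof, cfg)
  iv <- sim$exons[, c("chrom", "start", "end")]
  t_star <- max_complete_threshold(trs, iv)
  s_at <- completeness_summary(trs, sim$exons, t = t_star)
  expect_true(all(s_at$mean_percent == 100))
  s_above <- completeness_summary(trs, sim$exons, t = t_star + 1L)
  expect_lt(s_above$mean_percent[s_above$stratum == "all_exons"], 100)
})

test_that("required mean depth scales linearly with the guaranteed cutoff", {
  expect_equal(required_mean_depth(65, 13, 20), 100)
  expect_equal(required_mean_depth(42, 13, 13), 42)    # identity
  expect_equal(required_mean_depth(154, 13, 26), 308)  # doubling
  expect_error(required_mean_depth(65, 0, 20), "achieved_t")
})

test_that("near-miss reports list intervals just under the cutoff", {
  trs <- lapply(1:2, function(s)
    uniform_track(20L, c(chrA = 300L, chrB = 300L), sample_id = paste0("s", s)))
  ex <- toy_exons()
  expect_equal(nrow(near_miss_report(trs, ex, t = 13, floor = 7)), 0L)

  dl <- list(chrA = rep(20L, 300L), chrB = rep(20L, 300L))
  dl$chrA[30] <- 12L
  tr <- depth_track(dl, sample_id = "s1")
  nm <- near_miss_report(list(tr), ex, t = 13, floor = 7)
  expect_equal(nrow(nm), 1L)
  expect_equal(nm$min_depth, 12)
  expect_equal(nm$exon_id, ex$exon_id[1])
  # a depth below the floor is not a near miss
  dl$chrA[30] <- 5L
  expect_equal(nrow(near_miss_report(list(depth_track(dl)), ex, 13, 7)), 0L)
  expect_error(near_miss_report(list(tr), ex, t = 13, floor = 13), "floor")

  # random fixture vs brute-force scan
  set.seed(206)
  dl <- random_depth_list(2L, c(200L, 400L), max_depth = 20L)
  tr <- depth_track(dl, sample_id = "r")
  iv <- random_intervals(dl, 12L)
  nm <- near_miss_report(list(tr), iv, t = 13, floor = 7)
  mins <- vapply(seq_len(nrow(iv)), function(i)
    oracle_min_depth(dl, iv$chrom[i], iv$start[i], iv$end[i]), numeric(1))
  want_ids <- iv$exon_id[mins >= 7 & mins <= 12]
  expect_setequal(nm$exon_id, want_ids)
  expect_false(is.unsorted(nm$min_depth))
})

test_that("missed-fraction arithmetic returns exact values and displays", {
  r <- missed_fraction(0, 1000)
  expect_equal(r$missed_percent, 0)
  expect_equal(r$covered_percent, 100)
  expect_identical(unname(r$display["missed"]), "0.00")
  expect_error(missed_fraction(5, 0), "positive")
  expect_error(missed_fraction(-1, 10), "n_missed")
  expect_error(missed_fraction(11, 10), "n_missed")
})

test_that("depth calibration pins the global minimum to the target", {
  set.seed(207)
  cfg <- sim_config(n_genes = 20, seed = 53)
  sim <- simulate_annotation(cfg)
  prof <- platform_profile("p", mean_depth = 65, exon_bias_sd = 0.1,
                           sample_effect_sd = 0.1)
  trs <- simulate_depth(sim$exons, sim$reference, prof, cfg)
  iv <- sim$exons[, c("chrom", "start", "end")]
  cal <- calibrate_min_depth(trs, iv, target = 13L)
  expect_equal(max_complete_threshold(cal, iv), 13)
})
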