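#!/usr/bin/env Rscript
# Step 3 — complete-coverage statistics at the 13x cutoff.
#
# For every platform: the percentage of eligible exons, first exons, and
# genes whose every base reaches 13 reads, with 95% confidence intervals over
# the five samples; coverage of the catalogued variants (full reference span,
# insertion flanks for span-0 records); the largest cutoff at which the
# PCR-free genome track is still 100% complete; and the near-miss table of
# exons whose minimum depth falls in the 7-12 read window.

suppressPackageStartupMessages(library(covaudit))

dat <- "results/audit/data"
out <- "results/audit"
T_CUTOFF <- 13L
NEAR_FLOOR <- 7L

exons <- load_annotation(file.path(dat, "annotation.tsv"))
mask <- read.delim(file.path(out, "mask.tsv"))
eligible <- exons[mask$eligible[match(exons$exon_id, mask$exon_id)], ]
gene_exons <- derive_gene_eligibility(exons, mask)
variants <- read_variants(file.path(dat, "variants.tsv"))

read_platform_tracks <- function(platform) {
  files <- list.files(dat, sprintf("^depth_%s_s[0-9]+\\.bedgraph$", platform),
                      full.names = TRUE)
  lapply(files, function(f) {
    sample_id <- sub("^depth_(.+)\\.bedgraph$", "\\1", basename(f))
    read_depth_track(f, "bedgraph", sample_id = sample_id, platform = platform)
  })
}

platforms <- c("WES", "WGS_wPCR", "WGS")
summaries <- list(); variant_summaries <- list(); near <- list()
for (pf in platforms) {
  tracks <- read_platform_tracks(pf)
  s <- completeness_summary(tracks, eligible, gene_exons, t = T_CUTOFF)
  summaries[[pf]] <- cbind(platform = pf, s, stringsAsFactors = FALSE)
  v <- variant_coverage(tracks, variants, eligible, t = T_CUTOFF)
  variant_summaries[[pf]] <- cbind(platform = pf, v, stringsAsFactors = FALSE)
  nm <- near_miss_report(tracks, eligible, t = T_CUTOFF, floor = NEAR_FLOOR)
  near[[pf]] <- cbind(platform = rep(pf, nrow(nm)), nm, stringsAsFactors = FALSE)
  message(sprintf("%s: exons %.2f%%, first exons %.2f%%, genes %.2f%%, near misses %d",
                  pf, s$mean_percent[s$stratum == "all_exons"],
                  s$mean_percent[s$stratum == "first_exons"],
                  s$mean_percent[s$stratum == "genes"], nrow(nm)))
}
summaries <- do.call(rbind, summaries)
variant_summaries <- do.call(rbind, variant_summaries)
near <- do.call(rbind, near)

# the cutoff the PCR-free genome data would itself justify: the largest t at
# which every assessed base still clears it
iv <- eligible[, c("chrom", "start", "end")]
t_star <- max_complete_threshold(read_platform_tracks("WGS"), iv)
message(sprintf("PCR-free WGS max complete threshold (global min depth): %dx", t_star))
message(sprintf("mean depth for a 20x guarantee at that performance: %.0fx",
                required_mean_depth(65, t_star, 20)))

tab <- render_report_table(rbind(summaries, variant_summaries), near)
write.table(tab, file.path(out, "report_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(near, file.path(out, "near_miss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
flat <- summaries
flat$per_sample_percent <- vapply(flat$per_sample_percent, paste,
                                  character(1), collapse = ",")
flat$n_complete <- vapply(flat$n_complete, paste, character(1), collapse = ",")
write.table(flat, file.path(out, "completeness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
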