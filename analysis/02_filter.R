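#!/usr/bin/env Rscript
# Step 2 — exon eligibility.
#
# Restricts the audit to exons that can be compared fairly across platforms:
# on a whitelisted chromosome, fully inside the unique-mappability track,
# identical between assemblies, and free of common-CNV overlap. Every failing
# criterion is recorded, and the mask is checked against the simulator's
# ground-truth sidecar.

suppressPackageStartupMessages(library(covaudit))

dat <- "results/audit/data"
out <- "results/audit"

exons <- load_annotation(file.path(dat, "annotation.tsv"))
mask <- apply_eligibility(
  exons,
  mappability = read_bed3(file.path(dat, "mappability.bed")),
  cnvs = read_bed3(file.path(dat, "cnv.bed")),
  identity = read_identity(file.path(dat, "identity.tsv")),
  allowed_chroms = unique(exons$chrom)
)
write.table(mask[c("exon_id", "eligible", "reasons")],
            file.path(out, "mask.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
summ <- eligibility_summary(mask)
jsonlite::write_json(summ, file.path(out, "filter_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("eligible: %d of %d exons", summ$n_eligible, summ$n_exons))
message(sprintf("  not uniquely mappable: %d", summ$not_uniquely_mappable))
message(sprintf("  CNV overlap:           %d", summ$cnv_overlap))
message(sprintf("  assembly mismatch:     %d", summ$assembly_mismatch))

truth <- jsonlite::read_json(file.path(dat, "truth.json"), simplifyVector = TRUE)
agree <- identical(mask$eligible[match(truth$exon_id, mask$exon_id)],
                   truth$eligible)
message("mask agrees with simulator ground truth: ", agree)
stopifnot(agree)
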