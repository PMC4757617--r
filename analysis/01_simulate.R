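#!/usr/bin/env Rscript
# Step 1 — simulate the study data.
#
# Five samples per platform on a 200-gene synthetic genome: a capture exome
# at 154x mean on-target depth with steep GC bias and reproducible per-exon
# capture efficiency, a PCR genome library at 65x with mild GC bias, and a
# PCR-free genome library at 65x with a flat GC response. Alongside the depth
# tracks we emit the audit resources: exon annotation, reference FASTA,
# unique-mappability and common-CNV intervals, an assembly-identity table, a
# variant catalog, and a ground-truth eligibility sidecar.

suppressPackageStartupMessages(library(covaudit))

out <- "results/audit/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(n_genes = 200L, n_samples = 5L, seed = 20160107L)

ann <- simulate_annotation(cfg)
write_annotation(ann$exons, file.path(out, "annotation.tsv"))
write_reference_fasta(ann$reference, file.path(out, "reference.fa"))
message(sprintf("annotation: %d exons in %d genes on %d chromosomes",
                nrow(ann$exons), length(unique(ann$exons$gene_id)),
                length(ann$reference)))

conf <- simulate_confounders(ann$exons, cfg)
write_bed3(conf$mappability, file.path(out, "mappability.bed"))
write_bed3(conf$cnvs, file.path(out, "cnv.bed"))
write_identity(conf$identity, file.path(out, "identity.tsv"))
jsonlite::write_json(conf$truth, file.path(out, "truth.json"), digits = NA)
message(sprintf("confounders: %d mappability gaps, %d CNV hits, %d identity mismatches",
                sum(conf$truth$mappability_gap), sum(conf$truth$cnv_overlap),
                sum(conf$truth$assembly_mismatch)))

variants <- simulate_variant_catalog(ann$exons, cfg)
write_variants(variants, file.path(out, "variants.tsv"))
message(sprintf("variant catalog: %d variants (%d coding, %d non-coding)",
                nrow(variants), sum(variants$is_coding), sum(!variants$is_coding)))

exons <- annotate_gc(ann$exons, ann$reference)
for (profile in list(wes_profile(), wgs_wpcr_profile(), wgs_pcrfree_profile())) {
  tracks <- simulate_depth(exons, ann$reference, profile, cfg)
  for (tr in tracks) {
    write_depth_track(tr, file.path(out, sprintf("depth_%s.bedgraph", tr$sample_id)))
  }
  message(sprintf("%s: wrote %d depth tracks at %gx", profile$name,
                  length(tracks), profile$mean_depth))
}
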