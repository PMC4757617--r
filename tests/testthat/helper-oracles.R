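# Independent per-base oracles. These deliberately avoid every package code
# path they are used to check: depth lookups go straight into the raw
# per-chromosome vectors, and interval membership is tested base by base.

oracle_depth_at <- function(depth_list, chrom, pos0) {
  d <- depth_list[[chrom]]
  if (is.null(d) || pos0 + 1L > length(d)) return(0L)
  d[pos0 + 1L]
}

oracle_interval_depths <- function(depth_list, chrom, start, end) {
  vapply(start:(end - 1L), function(b) oracle_depth_at(depth_list, chrom, b),
         integer(1))
}

oracle_interval_complete <- function(depth_list, chrom, start, end, t) {
  all(oracle_interval_depths(depth_list, chrom, start, end) >= t)
}

oracle_min_depth <- function(depth_list, chrom, start, end) {
  min(oracle_interval_depths(depth_list, chrom, start, end))
}

# base-by-base eligibility check against raw interval tables
oracle_eligible <- function(exon, mapp, cnvs, id_map, allowed) {
  in_any <- function(df, chrom, b) {
    any(df$chrom == chrom & df$start <= b & b < df$end)
  }
  bases <- exon$start:(exon$end - 1L)
  chrom_ok <- exon$chrom %in% allowed
  mapp_ok <- all(vapply(bases, function(b) in_any(mapp, exon$chrom, b), logical(1)))
  cnv_hit <- any(vapply(bases, function(b) in_any(cnvs, exon$chrom, b), logical(1)))
  id_ok <- !is.na(id_map[exon$exon_id]) && id_map[exon$exon_id] == 1
  c(non_autosomal_or_X = !chrom_ok, not_uniquely_mappable = !mapp_ok,
    assembly_mismatch = !id_ok, cnv_overlap = cnv_hit)
}

oracle_variant_covered <- function(depth_list, v, t) {
  bases <- if (v$ref_span_len >= 1L) (v$pos:(v$pos + v$ref_span_len - 1L)) - 1L
           else c(v$pos - 1L, v$pos)
  all(vapply(bases, function(b) oracle_depth_at(depth_list, v$chrom, b),
             integer(1)) >= t)
}

# fixture builders -----------------------------------------------------------

random_depth_list <- function(n_chrom = 2L, len_range = c(50L, 400L),
                              max_depth = 30L) {
  lens <- sample(len_range[1]:len_range[2], n_chrom, replace = TRUE)
  depth <- lapply(lens, function(l) sample(0:max_depth, l, replace = TRUE))
  names(depth) <- paste0("chr", seq_len(n_chrom))
  depth
}

random_intervals <- function(depth_list, n = 5L) {
  rows <- lapply(seq_len(n), function(i) {
    chrom <- sample(names(depth_list), 1L)
    len <- length(depth_list[[chrom]])
    s <- sample(0:(len - 2L), 1L)
    e <- sample((s + 1L):min(len, s + 100L), 1L)
    data.frame(chrom = chrom, start = s, end = e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$exon_id <- sprintf("iv%03d", seq_len(n))
  out
}

uniform_track <- function(depth, lens = c(chrA = 100L), sample_id = "s1",
                          platform = "p") {
  depth_track(lapply(lens, function(l) rep(as.integer(depth), l)),
              sample_id = sample_id, platform = platform)
}

# minimal hand-built exon table
toy_exons <- function() {
  ex <- data.frame(
    chrom = c("chrA", "chrA", "chrB", "chrB"),
    start = c(10L, 100L, 20L, 200L),
    end = c(60L, 180L, 120L, 260L),
    strand = c("+", "+", "-", "-"),
    gene_id = c("G1", "G1", "G2", "G2"),
    transcript_id = c("G1.t1", "G1.t1", "G2.t1", "G2.t1"),
    exon_index = c(1L, 2L, 2L, 1L),
    is_first_exon = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  ex$exon_id <- sprintf("%s:%d-%d|%s", ex$chrom, ex$start, ex$end, ex$transcript_id)
  ex
}

full_mappability <- function(exons, pad = 1000L) {
  do.call(rbind, lapply(split(exons, exons$chrom), function(e) {
    data.frame(chrom = e$chrom[1], start = 0L, end = max(e$end) + pad,
               stringsAsFactors = FALSE)
  }))
}

no_cnvs <- function() data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0))

all_identical <- function(exons) data.frame(exon_id = exons$exon_id,
                                            identical = 1L,
                                            stringsAsFactors = FALSE)
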