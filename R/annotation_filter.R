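#' @importFrom IRanges IRanges width reduce intersect countOverlaps
NULL

ELIGIBILITY_REASONS <- c("non_autosomal_or_X", "not_uniquely_mappable",
                         "assembly_mismatch", "cnv_overlap")

#' Default chromosome whitelist: human autosomes plus X
#'
#' Coverage comparisons are restricted to autosomal and X-chromosomal
#' sequence; Y and unplaced contigs are excluded by construction.
#'
#' @return character vector `chr1..chr22, chrX`.
#' @export
autosomes_and_x <- function() c(paste0("chr", 1:22), "chrX")

exon_id_of <- function(exons) {
  sprintf("%s:%d-%d|%s", exons$chrom, exons$start, exons$end, exons$transcript_id)
}

validate_exons <- function(exons) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id",
                "exon_index", "is_first_exon")
  missing <- setdiff(required, names(exons))
  if (length(missing)) stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  if (any(exons$start >= exons$end)) {
    bad <- which(exons$start >= exons$end)[1L]
    stop("exon with start >= end at row ", bad)
  }
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (nrow(exons)) {
    n_first <- tapply(exons$is_first_exon, exons$transcript_id, sum)
    if (any(n_first != 1L)) {
      stop("each transcript must have exactly one first exon; offending: ",
           paste(utils::head(names(n_first)[n_first != 1L], 3), collapse = ", "))
    }
  }
  invisible(exons)
}

#' Read an exon annotation table
#'
#' Expects a TSV with columns chrom, start, end, strand, gene_id,
#' transcript_id, exon_index, is_first_exon (0/1), optionally gc_fraction.
#' Coordinates are 0-based half-open. Records are returned sorted by
#' (chrom, start); duplicate (chrom, start, end, transcript_id) rows are
#' rejected.
#'
#' @param path annotation TSV.
#' @return data.frame of exon records with an `exon_id` column added.
#' @export
load_annotation <- function(path) {
  exons <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (nrow(exons) == 0L) {
    exons$exon_id <- character(0)
    return(exons)
  }
  exons$is_first_exon <- as.logical(exons$is_first_exon)
  key <- paste(exons$chrom, exons$start, exons$end, exons$transcript_id)
  if (anyDuplicated(key)) {
    stop("duplicate exon rows (chrom,start,end,transcript): line ",
         which(duplicated(key))[1L] + 1L)
  }
  validate_exons(exons)
  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  exons$exon_id <- exon_id_of(exons)
  exons
}

#' Write an exon annotation table
#'
#' @param exons exon data.frame.
#' @param path output TSV.
#' @export
write_annotation <- function(exons, path) {
  out <- exons[, c("chrom", "start", "end", "strand", "gene_id", "transcript_id",
                   "exon_index", "is_first_exon"), drop = FALSE]
  out$is_first_exon <- as.integer(out$is_first_exon)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file (0-based half-open) into an interval data.frame
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end.
#' @export
read_bed3 <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
}

#' Write a 3-column BED file
#' @param intervals data.frame with chrom, start, end.
#' @param path output file.
#' @export
write_bed3 <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply the exon eligibility filter
#'
#' An exon is eligible iff (a) its chromosome is on the whitelist, (b) it is
#' uniquely mappable — at least `containment_fraction` of its bases (default:
#' all of them) lie inside the unique-mappability intervals, (c) its sequence
#' is identical between the two genome assemblies per the identity table, and
#' (d) no common-CNV interval overlaps it by one or more bases. All failing
#' criteria are reported, not just the first.
#'
#' @param exons exon data.frame (with `exon_id`; see [load_annotation()]).
#' @param mappability data.frame chrom/start/end of uniquely mappable intervals
#'   (0-based half-open).
#' @param cnvs data.frame chrom/start/end of common CNVs.
#' @param identity data.frame with columns exon_id and identical (0/1).
#' @param allowed_chroms chromosome whitelist; default autosomes + X. Pass the
#'   simulated chromosome set when auditing synthetic genomes.
#' @param containment_fraction minimum mappable fraction to call an exon
#'   uniquely mappable; default 1 (full containment).
#' @param strict_identity if `TRUE`, an exon missing from the identity table is
#'   an error; otherwise it is treated as an assembly mismatch.
#' @return data.frame: exon_id, eligible, reasons (comma-joined), one logical
#'   column per reason.
#' @export
apply_eligibility <- function(exons, mappability, cnvs, identity,
                              allowed_chroms = autosomes_and_x(),
                              containment_fraction = 1.0,
                              strict_identity = FALSE) {
  if (is.null(exons$exon_id)) exons$exon_id <- exon_id_of(exons)
  n <- nrow(exons)
  bad_chrom <- !(exons$chrom %in% allowed_chroms)

  unmappable <- logical(n)
  cnv_hit <- logical(n)
  for (chrom in unique(exons$chrom)) {
    idx <- which(exons$chrom == chrom)
    ex_r <- IRanges::IRanges(exons$start[idx] + 1L, exons$end[idx])
    mp <- mappability[mappability$chrom == chrom, , drop = FALSE]
    mp_r <- IRanges::reduce(IRanges::IRanges(mp$start + 1L, mp$end))
    span <- max(exons$end[idx])
    cov <- IRanges::coverage(mp_r, width = max(span, if (length(mp_r)) max(IRanges::end(mp_r)) else 0L))
    covered <- IRanges::viewSums(IRanges::Views(cov, ex_r))
    unmappable[idx] <- covered / IRanges::width(ex_r) < containment_fraction
    cv <- cnvs[cnvs$chrom == chrom, , drop = FALSE]
    cv_r <- IRanges::IRanges(cv$start + 1L, cv$end)
    cnv_hit[idx] <- IRanges::countOverlaps(ex_r, cv_r) > 0L
  }

  id_map <- stats::setNames(as.logical(identity$identical), identity$exon_id)
  known <- exons$exon_id %in% names(id_map)
  if (strict_identity && !all(known)) {
    stop("exon(s) missing from identity table: ",
         paste(utils::head(exons$exon_id[!known], 3), collapse = ", "))
  }
  mismatch <- !known | !unname(id_map[exons$exon_id])
  mismatch[is.na(mismatch)] <- TRUE

  flags <- cbind(non_autosomal_or_X = bad_chrom,
                 not_uniquely_mappable = unmappable,
                 assembly_mismatch = mismatch,
                 cnv_overlap = cnv_hit)
  reasons <- apply(flags, 1L, function(f)
    paste(ELIGIBILITY_REASONS[f], collapse = ","))
  out <- data.frame(exon_id = exons$exon_id,
                    eligible = rowSums(flags) == 0,
                    reasons = unname(reasons),
                    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(flags, row.names = seq_len(n)))
}

#' Gene-level assessable exon sets
#'
#' Genes retain only their eligible exons; genes with no eligible exon are
#' dropped from the audit entirely.
#'
#' @param exons exon data.frame.
#' @param mask eligibility mask from [apply_eligibility()].
#' @return named list gene_id -> character vector of eligible exon_ids.
#' @export
derive_gene_eligibility <- function(exons, mask) {
  if (is.null(exons$exon_id)) exons$exon_id <- exon_id_of(exons)
  ok <- stats::setNames(mask$eligible, mask$exon_id)
  keep <- exons[ok[exons$exon_id], , drop = FALSE]
  if (nrow(keep) == 0L) return(stats::setNames(list(), character(0)))
  split(keep$exon_id, keep$gene_id)
}

#' Eligibility summary counts
#'
#' @param mask eligibility mask.
#' @return list of counts: total, eligible, and per-reason tallies.
#' @export
eligibility_summary <- function(mask) {
  c(list(n_exons = nrow(mask), n_eligible = sum(mask$eligible)),
    lapply(as.list(mask[ELIGIBILITY_REASONS]), sum))
}

#' Assembly identity by exact sequence comparison
#'
#' Helper for users who hold the exon sequences from two assemblies: flags an
#' exon identical iff the two sequences are exactly equal strings.
#'
#' @param seqs_a,seqs_b named character vectors (or DNAStringSet) keyed by
#'   exon_id.
#' @return identity data.frame (exon_id, identical) over the shared ids.
#' @export
sequence_identity_table <- function(seqs_a, seqs_b) {
  a <- stats::setNames(as.character(seqs_a), names(seqs_a))
  b <- stats::setNames(as.character(seqs_b), names(seqs_b))
  ids <- intersect(names(a), names(b))
  data.frame(exon_id = ids,
             identical = as.integer(a[ids] == b[ids]),
             stringsAsFactors = FALSE)
}
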