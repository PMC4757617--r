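#' Run configuration for the end-to-end coverage audit
#'
#' Bundles everything one audit run needs: the simulation settings, the
#' platform profiles to compare, the completeness cutoff and near-miss floor,
#' gene panels, and the output directory.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a `SimulationConfig`.
#' @param platforms list of `PlatformProfile`s.
#' @param t completeness cutoff in reads (>= 1; default 13).
#' @param near_miss_floor lowest near-miss minimum depth reported (< t).
#' @param gene_sets named list of gene_id vectors (e.g. an ACMG-like panel);
#'   `"RefSeq"` meaning all genes is always included.
#' @param dialect depth-file dialect, `"bedgraph"` or `"per_base_tsv"`.
#' @param confounder_fractions length-3 numeric: mappability-gap, CNV, and
#'   identity-mismatch fractions passed to [simulate_confounders()].
#' @return validated `RunConfig` list.
#' @export
run_config <- function(out_dir, sim = sim_config(),
                       platforms = list(wes_profile(), wgs_wpcr_profile(),
                                        wgs_pcrfree_profile()),
                       t = 13L, near_miss_floor = 7L,
                       gene_sets = NULL, dialect = "bedgraph",
                       confounder_fractions = c(0.03, 0.03, 0.02)) {
  if (t < 1) stop("completeness cutoff t must be >= 1")
  if (near_miss_floor >= t) stop("near_miss_floor must be below t")
  stopifnot(inherits(sim, "SimulationConfig"),
            all(vapply(platforms, inherits, logical(1), "PlatformProfile")),
            dialect %in% c("bedgraph", "per_base_tsv"))
  structure(list(out_dir = out_dir, sim = sim, platforms = platforms,
                 t = as.integer(t), near_miss_floor = as.integer(near_miss_floor),
                 gene_sets = gene_sets, dialect = dialect,
                 confounder_fractions = confounder_fractions),
            class = "RunConfig")
}

config_hash <- function(config) {
  # md5 of the canonical JSON serialization of the semantic fields
  semantic <- config[setdiff(names(config), "out_dir")]
  semantic$platforms <- lapply(semantic$platforms, unclass)
  semantic$sim <- unclass(semantic$sim)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(semantic, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

flatten_summary <- function(s) {
  per <- vapply(s$per_sample_percent, function(p)
    paste(sprintf("%.6f", p), collapse = ","), character(1))
  ncm <- vapply(s$n_complete, function(p) paste(p, collapse = ","), character(1))
  cols <- intersect(c("platform", "gene_set", "stratum", "threshold", "n_items",
                      "n_samples", "mean_percent", "ci_lo", "ci_hi"), names(s))
  data.frame(s[cols], per_sample_percent = per, n_complete = ncm,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full audit pipeline
#'
#' simulate -> write resources -> read back -> eligibility filter ->
#' completeness per platform and gene set -> variant coverage -> GC profile
#' -> cv decomposition -> near-miss report -> formatted table + manifest.
#' All randomness derives from the seed in `config$sim`, so re-running with
#' the same config is byte-identical.
#'
#' @param config a `RunConfig`.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with all in-memory results (`summaries`,
#'   `variant_summaries`, `gc_profiles`, `cv`, `near_misses`, `mask`, `table`,
#'   `manifest`, and the paths written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    if (!quiet) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  ann <- stage("simulate", {
    ann <- simulate_annotation(config$sim)
    write_annotation(ann$exons, out("annotation.tsv"))
    write_reference_fasta(ann$reference, out("reference.fa"))
    ann
  })
  conf <- stage("confounders", {
    fr <- config$confounder_fractions
    conf <- simulate_confounders(ann$exons, config$sim, fr[1], fr[2], fr[3])
    write_bed3(conf$mappability, out("mappability.bed"))
    write_bed3(conf$cnvs, out("cnv.bed"))
    write_identity(conf$identity, out("identity.tsv"))
    jsonlite::write_json(conf$truth, out("truth.json"), digits = NA)
    conf
  })
  exons <- stage("reload", {
    ex <- load_annotation(out("annotation.tsv"))
    annotate_gc(ex, read_reference_fasta(out("reference.fa")))
  })
  mask <- stage("filter", {
    mask <- apply_eligibility(exons, conf$mappability, conf$cnvs, conf$identity,
                              allowed_chroms = unique(exons$chrom))
    write_tsv(mask[c("exon_id", "eligible", "reasons")], out("mask.tsv"))
    jsonlite::write_json(eligibility_summary(mask), out("filter_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    mask
  })
  eligible <- exons[mask$eligible[match(exons$exon_id, mask$exon_id)], , drop = FALSE]
  gene_exons <- derive_gene_eligibility(exons, mask)

  gene_sets <- c(list(RefSeq = names(gene_exons)), config$gene_sets)
  for (nm in names(gene_sets)) {
    if (!any(gene_sets[[nm]] %in% exons$gene_id)) {
      stop("gene set '", nm, "' resolves to no known gene")
    }
  }

  variants <- stage("variants", {
    v <- simulate_variant_catalog(ann$exons, config$sim)
    write_variants(v, out("variants.tsv"))
    read_variants(out("variants.tsv"))
  })

  tracks <- stage("depth", {
    lapply(config$platforms, function(p) {
      trs <- simulate_depth(exons, ann$reference, p, config$sim)
      for (tr in trs) {
        write_depth_track(tr, out(sprintf("depth_%s.%s", tr$sample_id,
                                          if (config$dialect == "bedgraph") "bedgraph" else "tsv")),
                          config$dialect)
      }
      trs
    })
  })
  names(tracks) <- vapply(config$platforms, `[[`, character(1), "name")

  summaries <- stage("completeness", {
    res <- do.call(rbind, unlist(lapply(names(tracks), function(pf) {
      lapply(names(gene_sets), function(gs) {
        keep_genes <- intersect(gene_sets[[gs]], names(gene_exons))
        ge <- gene_exons[keep_genes]
        ex <- eligible[eligible$gene_id %in% keep_genes, , drop = FALSE]
        s <- completeness_summary(tracks[[pf]], ex, ge, t = config$t, gene_set = gs)
        cbind(platform = pf, s, stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
    write_tsv(flatten_summary(res), out("completeness.tsv"))
    res
  })

  variant_summaries <- stage("variant_coverage", {
    res <- do.call(rbind, lapply(names(tracks), function(pf) {
      cbind(platform = pf,
            variant_coverage(tracks[[pf]], variants, eligible, t = config$t),
            stringsAsFactors = FALSE)
    }))
    write_tsv(flatten_summary(res), out("variant_coverage.tsv"))
    res
  })

  gc_profiles <- stage("gc_profile", {
    res <- do.call(rbind, lapply(names(tracks), function(pf)
      gc_depth_profile(tracks[[pf]], eligible, platform = pf)))
    write_tsv(res, out("gc_profile.tsv"))
    res
  })

  cv <- stage("variability", {
    res <- lapply(names(tracks), function(pf) cv_summary(tracks[[pf]], eligible))
    names(res) <- names(tracks)
    write_tsv(data.frame(
      platform = names(res),
      intra_cv_mean = vapply(res, `[[`, numeric(1), "intra_cv_mean"),
      inter_cv_per_exon_mean = vapply(res, `[[`, numeric(1), "inter_cv_per_exon_mean"),
      n_exons = vapply(res, `[[`, numeric(1), "n_exons"),
      n_samples = vapply(res, `[[`, numeric(1), "n_samples"),
      sd_convention = vapply(res, `[[`, character(1), "sd_convention")
    ), out("cv_summary.tsv"))
    res
  })

  near <- stage("near_miss", {
    res <- do.call(rbind, lapply(names(tracks), function(pf) {
      nm <- near_miss_report(tracks[[pf]], eligible, t = config$t,
                             floor = config$near_miss_floor)
      cbind(platform = rep(pf, nrow(nm)), nm, stringsAsFactors = FALSE)
    }))
    write_tsv(res, out("near_miss.tsv"))
    res
  })

  tab <- stage("render", {
    tab <- render_report_table(rbind(summaries, variant_summaries), near)
    write_tsv(tab, out("report_table.tsv"))
    tab
  })

  manifest <- stage("manifest", {
    m <- list(package_version = as.character(utils::packageVersion("covaudit")),
              seed = config$sim$seed, threshold = config$t,
              near_miss_floor = config$near_miss_floor,
              dialect = config$dialect, ci_method = "t",
              config_hash = config_hash(config))
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE, digits = NA)
    m
  })

  # machine-readable exact fractions behind every displayed percentage
  stage("json", {
    jsonlite::write_json(list(
      completeness = flatten_summary(rbind(summaries, variant_summaries)),
      near_miss = near
    ), out("report.json"), digits = NA)
  })

  invisible(list(exons = exons, mask = mask, eligible = eligible,
                 gene_exons = gene_exons, variants = variants, tracks = tracks,
                 summaries = summaries, variant_summaries = variant_summaries,
                 gc_profiles = gc_profiles, cv = cv, near_misses = near,
                 table = tab, manifest = manifest, out_dir = config$out_dir))
}

#' Render a formatted completeness table
#'
#' One row per (gene set, stratum, platform): mean percent at two decimals,
#' the 95% CI, and a footnote summarizing near misses ("N exons partially
#' covered with lo-hi reads"). Requested strata missing from the summaries
#' are marked absent rather than dropped.
#'
#' @param summaries completeness data.frame (rows from
#'   [completeness_summary()] / [variant_coverage()], with a `platform`
#'   column).
#' @param near_misses near-miss data.frame with a `platform` column (optional).
#' @return data.frame: platform, gene_set, stratum, mean, ci, footnote.
#' @export
render_report_table <- function(summaries, near_misses = NULL) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    note <- ""
    if (!is.null(near_misses) && nrow(near_misses) &&
        s$stratum %in% c("all_exons", "first_exons", "variant_exons")) {
      nm <- near_misses[near_misses$platform == s$platform, , drop = FALSE]
      if (nrow(nm)) {
        n_ex <- length(unique(nm$exon_id))
        rng <- range(nm$min_depth)
        note <- sprintf("%d exon%s partially covered with %s reads",
                        n_ex, if (n_ex == 1L) "" else "s",
                        if (rng[1] == rng[2]) sprintf("%d", rng[1])
                        else sprintf("%d-%d", rng[1], rng[2]))
      }
    }
    data.frame(platform = s$platform, gene_set = s$gene_set, stratum = s$stratum,
               mean_percent = sprintf("%.2f", s$mean_percent),
               ci95 = if (is.na(s$ci_lo)) "absent"
                      else sprintf("[%.2f, %.2f]", s$ci_lo, s$ci_hi),
               footnote = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
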