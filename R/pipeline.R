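#' Build a pipeline configuration
#'
#' One human-editable configuration drives the full analysis; all randomness
#' flows from the single seed in `sim`.
#'
#' @param sim A [sim_config()] for the synthetic study (always required; it
#'   also carries the seed).
#' @param counts_path Optional path to a counts TSV to analyse instead of the
#'   simulated counts.
#' @param caller Deletion-caller parameters (threshold, min_bins,
#'   merge_gap_bins).
#' @param dosage Dosage thresholds (min_fpkm, low, high).
#' @param retention Retention parameters (conf, mosaic_threshold).
#' @param husbandry Offspring counts for the transmission-rate summary.
#' @return A list of class `tc_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_path = NULL,
                            caller = list(threshold = 0.25, min_bins = 3L,
                                          merge_gap_bins = 1L),
                            dosage = list(min_fpkm = 1, low = 0.8, high = 1.2),
                            retention = list(conf = 0.95,
                                             mosaic_threshold = 0.9),
                            husbandry = list(n_offspring = 90L,
                                             n_positive = 43L)) {
  stopifnot(inherits(sim, "tc_sim_config"))
  if (caller$threshold <= 0 || dosage$min_fpkm <= 0 || dosage$low <= 0 ||
      dosage$high <= 0) {
    abort("caller and dosage thresholds must be positive.")
  }
  structure(list(sim = sim, counts_path = counts_path, caller = caller,
                 dosage = dosage, retention = retention,
                 husbandry = husbandry),
            class = "tc_pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "tc_stage_error")
  })
}

#' Run the full characterization pipeline
#'
#' Simulate (or load) inputs, normalize depth and call deletions, annotate
#' deleted genes, compute dosage records and trans-dysregulation counts,
#' estimate per-tissue retention, and compute the behavioral statistics.
#' Identical configuration and seed give an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report JSON and the
#'   main tables (annotation TSV + BED, depth bedGraph, counts TSV, deletion
#'   calls BED, dosage records TSV, retention TSV) are written there.
#' @return A list of class `tc_report` with per-stage summaries.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "tc_pipeline_config"))

  study <- run_stage("simulate", sim_study(config$sim))
  counts <- run_stage("load-counts", {
    if (is.null(config$counts_path)) study$counts
    else read_counts(config$counts_path)
  })

  span <- transchromosome_span(config$sim$chrom_start, config$sim$chrom_end)
  calls <- run_stage("call-deletions", {
    study$depth |>
      normalize_depth() |>
      call_deletions(threshold = config$caller$threshold,
                     min_bins = config$caller$min_bins,
                     merge_gap_bins = config$caller$merge_gap_bins)
  })
  del_annot <- run_stage("annotate-deletions",
                         annotate_deletions(calls, study$annotation,
                                            span_bp = span$span_bp))

  dosage <- run_stage("dosage", {
    records <- dosage_records(counts, study$annotation,
                              min_fpkm = config$dosage$min_fpkm)
    fp <- fpkm_table(counts)
    host_ids <- unique(counts$gene_id[startsWith(counts$gene_id, "HG")])
    eu_host <- dplyr::filter(fp, .data$genotype == "Eu",
                             .data$gene_id %in% host_ids)
    tc_host <- dplyr::filter(fp, .data$genotype == "Tc",
                             .data$gene_id %in% host_ids)
    dys <- count_dysregulated(eu_host, tc_host,
                              min_fpkm = config$dosage$min_fpkm,
                              low = config$dosage$low,
                              high = config$dosage$high)
    deleted_ids <- del_annot$genes$gene_id[del_annot$genes$deleted]
    silence <- validate_deleted_silence(records, deleted_ids)
    # dosage bands are reported among intact pairs: a pair whose human gene
    # sits in a deleted region is disomic (R_tot ~ 1) by construction
    intact <- records[!records$human_gene_id %in% deleted_ids, , drop = FALSE]
    tiers <- fp |>
      dplyr::filter(.data$genotype == "Tc", .data$species == "human") |>
      dplyr::mutate(tier = assign_expression_tier(.data$fpkm)) |>
      dplyr::count(.data$tier, .drop = FALSE)
    list(records = records, summary = glance(intact),
         summary_all_pairs = glance(records), dysregulation = dys,
         silence = silence, tiers = tiers)
  })

  retention <- run_stage("retention", {
    tallies <- tally_cells(study$cells)
    pooled <- pool_retention(tallies, conf = config$retention$conf)
    mosaic <- test_mosaicism(tallies,
                             threshold = config$retention$mosaic_threshold)
    list(per_tissue = pooled$per_tissue, pooled = pooled$pooled,
         mosaic = mosaic)
  })

  behavior <- run_stage("behavior", {
    rm_eu <- retained_memory_summary(study$trials$Eu)
    rm_tc <- retained_memory_summary(study$trials$Tc)
    list(
      chance_circular_pct = 100 * chance_level_circular(),
      chance_square_pct = 100 * chance_level_square(37, 21.6),
      retained_memory = list(Eu = rm_eu, Tc = rm_tc),
      transmission = transmission_rate(config$husbandry$n_offspring,
                                       config$husbandry$n_positive)
    )
  })

  report <- structure(list(
    seed = config$sim$seed,
    span = span,
    deletions = list(calls = tidy(calls), summary = del_annot$summary),
    dosage = list(summary = dosage$summary,
                  summary_all_pairs = dosage$summary_all_pairs,
                  dysregulation = dosage$dysregulation,
                  tiers = dosage$tiers,
                  deleted_silent = dosage$silence$pass),
    retention = list(per_tissue = tidy(retention$per_tissue),
                     pooled = tidy(retention$pooled),
                     mosaic_suspect_tissues =
                       sum(retention$mosaic$mosaic_suspect)),
    behavior = behavior
  ), class = "tc_report")

  if (!is.null(out_dir)) {
    run_stage("write-outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_annotation(study$annotation, file.path(out_dir, "annotation.tsv"))
      write_bed(study$annotation, file.path(out_dir, "annotation.bed"),
                name_col = "gene_id")
      write_bedgraph(study$depth, file.path(out_dir, "depth.bedgraph"))
      write_counts(counts, file.path(out_dir, "counts.tsv"))
      write_bed(tidy(calls), file.path(out_dir, "deletion_calls.bed"))
      readr::write_tsv(tidy(dosage$records),
                       file.path(out_dir, "dosage_records.tsv"))
      readr::write_tsv(tidy(retention$per_tissue),
                       file.path(out_dir, "retention.tsv"))
      write_json_report(unclass(report), file.path(out_dir, "report.json"))
    })
  }
  report
}

#' @export
print.tc_report <- function(x, ...) {
  cat("Transchromosome characterization report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  span: %s bp (~%d Mb)\n",
              format(x$span$span_bp, big.mark = ","), x$span$span_mb))
  cat(sprintf("  deletions: %d calls, %.1f%% of span, %d PCGs / %d non-PCGs deleted\n",
              x$deletions$summary$n_calls,
              100 * x$deletions$summary$frac_span_deleted,
              x$deletions$summary$n_deleted_pcg,
              x$deletions$summary$n_deleted_npcg))
  s <- x$dosage$summary
  cat(sprintf("  dosage: %d pairs; bands low/expected/high = %.1f%%/%.1f%%/%.1f%%; %d within 80-120%%\n",
              s$n_pairs, 100 * s$prop_low, 100 * s$prop_expected,
              100 * s$prop_high, s$n_within_80_120))
  d <- x$dosage$dysregulation
  cat(sprintf("  trans effects: %d tested, %d down, %d up\n",
              d$n_tested, d$n_down, d$n_up))
  cat(sprintf("  retention: pooled %.3f (min per-tissue %.3f over %d tissues)\n",
              x$retention$pooled$p_hat, min(x$retention$per_tissue$p_hat),
              nrow(x$retention$per_tissue)))
  cat(sprintf("  behavior: MWM chance %.0f%%, open-field centre %.0f%%, transmission %.1f%%\n",
              x$behavior$chance_circular_pct, x$behavior$chance_square_pct,
              100 * x$behavior$transmission$proportion))
  invisible(x)
}
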