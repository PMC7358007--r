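#' Generate a synthetic transchromosome gene annotation with planted truth
#'
#' Places `n_pcg + n_npcg` non-overlapping genes uniformly on the
#' transchromosome span. A contiguous block of `n_krtap` PCGs is tagged as the
#' KRTAP family (silent, never paired); every other PCG receives a host
#' ortholog with probability `ortholog_fraction`. Genes overlapping a planted
#' deletion by at least 1 bp are flagged deleted in the returned truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with `annotation` (tibble: gene_id, chrom, start, end,
#'   biotype, family, ortholog_id, length) and `truth` (tibble: gene_id,
#'   deleted).
#' @export
sim_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "annotation"))
  n <- config$n_pcg + config$n_npcg
  span <- config$chrom_end - config$chrom_start + 1

  lengths <- as.integer(round(runif(n, config$gene_length_min,
                                    config$gene_length_max)))
  free <- span - sum(lengths) - n  # at least 1 bp gap between genes
  if (free < 0) {
    abort(sprintf(
      "cannot place %d genes (total %d bp) on a %d bp span.",
      n, sum(lengths), span))
  }
  gaps <- as.numeric(stats::rexp(n + 1))
  gaps <- floor(gaps / sum(gaps) * free) + 1L
  starts <- config$chrom_start + cumsum(gaps)[seq_len(n)] +
    c(0L, cumsum(lengths[-n]))
  ends <- starts + lengths - 1L
  stopifnot(all(ends <= config$chrom_end))

  biotype <- sample(rep(c("PCG", "nonPCG"), c(config$n_pcg, config$n_npcg)))
  family <- rep("other", n)
  pcg_idx <- which(biotype == "PCG")
  if (config$n_krtap > 0) {
    # contiguous block of PCGs, mimicking the clustered KRTAP locus
    first <- sample(length(pcg_idx) - config$n_krtap + 1L, 1L)
    family[pcg_idx[seq(first, length.out = config$n_krtap)]] <- "KRTAP"
  }
  eligible <- biotype == "PCG" & family != "KRTAP"
  has_orth <- eligible & runif(n) < config$ortholog_fraction

  gene_id <- sprintf("TC%04d", seq_len(n))
  annotation <- tibble(
    gene_id = gene_id,
    chrom = config$chrom_name,
    start = as.integer(starts),
    end = as.integer(ends),
    biotype = biotype,
    family = family,
    ortholog_id = ifelse(has_orth, paste0("m", gene_id), NA_character_),
    length = lengths
  )
  deleted <- overlaps_any(annotation$start, annotation$end,
                          config$planted_deletions)
  list(annotation = annotation,
       truth = tibble(gene_id = gene_id, deleted = deleted))
}

# 1-based inclusive interval overlap (>= 1 bp) against a table of intervals
overlaps_any <- function(start, end, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] <= intervals$end & end[i] >= intervals$start)
  }, logical(1))
}

#' Generate a binned read-depth profile with planted deletions
#'
#' Bins the span at `bin_size` (last bin truncated). Bins whose midpoint lies
#' in a planted deletion receive Poisson background at 2% of `depth_mean`
#' (mimicking mismapping); other bins are negative-binomial around
#' `depth_mean` with dispersion `depth_noise`. With `depth_noise = 0` the
#' profile is noiseless: exactly `depth_mean` outside deletions and 0 inside.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns chrom, start, end (1-based inclusive), depth.
#' @export
sim_depth <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "depth"))
  starts <- seq(config$chrom_start, config$chrom_end, by = config$bin_size)
  ends <- pmin(starts + config$bin_size - 1, config$chrom_end)
  mid <- floor((starts + ends) / 2)
  inside <- overlaps_any(mid, mid, config$planted_deletions)
  n <- length(starts)
  if (config$depth_noise == 0) {
    depth <- ifelse(inside, 0, config$depth_mean)
  } else {
    depth <- numeric(n)
    depth[!inside] <- rnbinom(sum(!inside), mu = config$depth_mean,
                              size = 1 / config$depth_noise)
    depth[inside] <- rpois(sum(inside), 0.02 * config$depth_mean)
  }
  tibble(chrom = config$chrom_name, start = as.integer(starts),
         end = as.integer(ends), depth = as.numeric(depth))
}

expected_count <- function(fpkm, length_bp, library_size) {
  fpkm * length_bp * library_size / 1e9
}

draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  as.numeric(rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

#' Generate euploid and trisomic expression count tables
#'
#' Simulates fragment counts for (i) mouse orthologs of transchromosome PCGs,
#' (ii) host-genome genes carrying planted trans-effects, and (iii) human
#' transchromosome genes in the trisomic animal. Counts follow a
#' negative-binomial model around expected counts derived from planted FPKM
#' targets; the per-pair total-expression ratio (human + mouse over euploid
#' mouse) is drawn log-normally around the configured median, human genes in
#' deleted regions are silent, and KRTAP genes are never expressed.
#'
#' @param config A [sim_config()] object.
#' @param annotation_truth The list returned by [sim_annotation()].
#' @return A list with `counts` (long tibble: gene_id, species, genotype,
#'   replicate, length, count, library_size), `library_sizes`, and `truth`
#'   (per-pair planted ratios/classes plus host-gene trans labels).
#' @export
sim_counts <- function(config, annotation_truth) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "expression"))
  ann <- annotation_truth$annotation
  deleted <- annotation_truth$truth$deleted

  reps <- seq_len(config$n_replicates)
  samples <- tidyr::expand_grid(genotype = c("Eu", "Tc"), replicate = reps)
  samples$library_size <- round(3e7 * runif(nrow(samples), 0.9, 1.1))

  # --- ortholog pairs -------------------------------------------------------
  paired <- !is.na(ann$ortholog_id)
  pairs <- tibble(
    human_gene_id = ann$gene_id[paired],
    mouse_ortholog_id = ann$ortholog_id[paired],
    length = ann$length[paired],
    deleted = deleted[paired]
  )
  np <- nrow(pairs)
  base_fpkm <- rlnorm(np, log(2), 1.2)      # euploid mouse expression level
  r_tot <- rlnorm(np, config$dosage_log_mean, config$dosage_log_sd)
  r_m <- pmin(pmax(rnorm(np, 1, 0.05), 0.5), 1.5)
  r_m_target <- pmin(r_m, r_tot)
  r_h_target <- ifelse(pairs$deleted, 0, r_tot - r_m_target)
  r_m_target <- ifelse(pairs$deleted, r_m, r_m_target)

  pair_truth <- dplyr::mutate(
    pairs,
    base_fpkm = base_fpkm,
    r_tot_target = ifelse(deleted, r_m_target, r_tot),
    r_m_target = r_m_target,
    r_h_target = r_h_target,
    dosage_class = classify_dosage(ifelse(deleted, r_m_target, r_tot))
  )

  # --- human transchromosome genes not in a pair (for tiering) --------------
  unpaired <- !paired
  up_fpkm <- ifelse(ann$biotype[unpaired] == "PCG",
                    rlnorm(sum(unpaired), log(2), 1.5),
                    rlnorm(sum(unpaired), log(0.05), 1.5))
  up_fpkm[ann$family[unpaired] == "KRTAP"] <- 0
  up_fpkm[deleted[unpaired]] <- 0

  # --- host-genome genes with trans effects ---------------------------------
  nh <- config$n_host_genes
  n_down <- round(config$trans_down_frac * nh)
  n_up <- round(config$trans_up_frac * nh)
  trans_class <- sample(rep(c("down", "up", "neutral"),
                            c(n_down, n_up, nh - n_down - n_up)))
  host <- tibble(
    gene_id = sprintf("HG%05d", seq_len(nh)),
    length = as.integer(round(runif(nh, 1e3, 1e5))),
    base_fpkm = rlnorm(nh, log(3), 1.2),
    trans_class = trans_class,
    trans_factor = dplyr::case_when(
      trans_class == "down" ~ runif(nh, 0.4, 0.7),
      trans_class == "up" ~ runif(nh, 1.3, 1.8),
      TRUE ~ 1
    )
  )

  one_sample <- function(genotype, replicate, library_size) {
    blocks <- list(
      tibble(gene_id = pairs$mouse_ortholog_id, species = "mouse",
             length = pairs$length,
             fpkm = base_fpkm * if (genotype == "Eu") 1 else r_m_target),
      tibble(gene_id = host$gene_id, species = "mouse", length = host$length,
             fpkm = host$base_fpkm *
               if (genotype == "Eu") 1 else host$trans_factor)
    )
    if (genotype == "Tc") {
      blocks <- c(blocks, list(
        tibble(gene_id = pairs$human_gene_id, species = "human",
               length = pairs$length, fpkm = base_fpkm * r_h_target),
        tibble(gene_id = ann$gene_id[unpaired], species = "human",
               length = ann$length[unpaired], fpkm = up_fpkm)
      ))
    }
    out <- dplyr::bind_rows(blocks)
    mu <- expected_count(out$fpkm, out$length, library_size)
    dplyr::mutate(out,
                  genotype = genotype, replicate = replicate,
                  count = draw_counts(mu, config$nb_dispersion),
                  library_size = library_size, fpkm = NULL)
  }
  counts <- purrr::pmap(samples, function(genotype, replicate, library_size) {
    one_sample(genotype, replicate, library_size)
  })
  counts <- dplyr::bind_rows(counts)

  list(counts = counts, library_sizes = samples,
       truth = list(pairs = pair_truth,
                    host = dplyr::select(host, "gene_id", "trans_class",
                                         "trans_factor")))
}

#' Generate per-cell transchromosome detection calls per tissue
#'
#' Independent Bernoulli detections at the configured retention probability,
#' `cells_per_tissue` cells in each of `n_tissues` tissues.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns tissue, cell, detected (0/1).
#' @export
sim_cells <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "cells"))
  tissues <- c("brain", "heart", "liver", "spleen", "kidney", "lung",
               "thymus", "tail", "muscle", "gut")
  tissues <- if (config$n_tissues <= length(tissues)) {
    tissues[seq_len(config$n_tissues)]
  } else {
    sprintf("tissue%02d", seq_len(config$n_tissues))
  }
  tidyr::expand_grid(tissue = tissues,
                     cell = seq_len(config$cells_per_tissue)) |>
    dplyr::mutate(detected = rbinom(dplyr::n(), 1, config$retention_p))
}

#' Generate probe-trial time-in-zone fractions with geometric forgetting
#'
#' Each animal starts from a baseline time fraction in the old target zone on
#' reversal day 1 and decays geometrically by `retention_decay_per_day` on
#' subsequent days, plus bounded uniform noise; fractions are clipped to
#' `[0, 1]` and baselines are resampled away from 0 so the retained-memory
#' normalization is always defined.
#'
#' @param n_animals Number of animals.
#' @param baseline_fraction Mean day-1 time fraction in the old target zone.
#' @param retention_decay_per_day Geometric day-over-day retention factor
#'   (1 = no forgetting).
#' @param seed Integer seed.
#' @param noise Half-width of the bounded uniform noise on each fraction.
#' @param n_days Number of reversal days (day 1 is the baseline).
#' @param zone_label Zone the fractions refer to.
#' @return A tibble with columns animal_id, day, trial, zone_label,
#'   time_fraction.
#' @export
sim_probe_trials <- function(n_animals, baseline_fraction = 0.30,
                             retention_decay_per_day = 0.5, seed = 1L,
                             noise = 0.05, n_days = 3L, zone_label = "SE") {
  stopifnot(n_animals > 0, n_days >= 1)
  if (baseline_fraction < 0 || baseline_fraction > 1 ||
      retention_decay_per_day < 0 || retention_decay_per_day > 1) {
    abort("`baseline_fraction` and `retention_decay_per_day` must lie in [0, 1].")
  }
  set.seed(seed %% .Machine$integer.max)
  rows <- purrr::map(seq_len(n_animals), function(a) {
    repeat {
      b <- baseline_fraction + runif(1, -noise, noise)
      if (b > 0.01) break  # guard: baseline bounded away from 0
    }
    frac <- b * retention_decay_per_day^(seq_len(n_days) - 1)
    if (noise > 0 && n_days > 1) {
      frac[-1] <- frac[-1] + runif(n_days - 1, -noise, noise)
    }
    tibble(animal_id = sprintf("A%03d", a), day = seq_len(n_days), trial = 1L,
           zone_label = zone_label,
           time_fraction = pmin(pmax(frac, 0), 1))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full synthetic study
#'
#' Runs all generators from one configuration and assembles their outputs and
#' the planted ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements annotation, depth, counts, library_sizes,
#'   cells, trials (euploid- and trisomic-like cohorts) and truth.
#' @export
sim_study <- function(config = sim_config()) {
  ann <- sim_annotation(config)
  depth <- sim_depth(config)
  expr <- sim_counts(config, ann)
  cells <- sim_cells(config)
  trials <- list(
    Eu = sim_probe_trials(10, 0.30, 0.45,
                          seed = stage_seed(config, "trials")),
    Tc = sim_probe_trials(9, 0.30, 0.85,
                          seed = stage_seed(config, "trials") + 1L)
  )
  truth <- list(
    deletion_intervals = config$planted_deletions,
    genes = dplyr::left_join(ann$truth,
                             dplyr::select(expr$truth$pairs, gene_id = "human_gene_id",
                                           "dosage_class"),
                             by = "gene_id"),
    host = expr$truth$host,
    pairs = expr$truth$pairs,
    retention = tibble(tissue = unique(cells$tissue),
                       retention_p = config$retention_p)
  )
  list(annotation = ann$annotation, depth = depth, counts = expr$counts,
       library_sizes = expr$library_sizes, cells = cells, trials = trials,
       truth = truth)
}
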