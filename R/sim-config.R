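#' Default planted deletions for the synthetic transchromosome
#'
#' Four disjoint intervals, aligned to 10 kb bin boundaries relative to the
#' span start, together covering roughly 29% of the default ~33.7 Mb span.
#' Coordinates are 1-based inclusive base pairs.
#'
#' @param chrom_start,chrom_end 1-based inclusive span of the transchromosome
#'   long arm.
#' @return A tibble with columns `start` and `end`.
#' @export
default_deletions <- function(chrom_start = 13021348, chrom_end = 46691226) {
  # offsets in bp from the span start; lengths total 9.76 Mb (~29% of span)
  off <- tibble::tribble(
    ~from,      ~to,
    2.00e6,  3.20e6,
    8.50e6, 11.50e6,
    17.00e6, 20.30e6,
    26.00e6, 28.26e6
  )
  tibble(
    start = as.integer(chrom_start + off$from),
    end   = as.integer(chrom_start + off$to - 1)
  )
}

#' Build and validate a simulation configuration
#'
#' The configuration fixes the study conditions emulated by the synthetic-data
#' generator: a ~33.7 Mb single-copy transchromosome carrying 213 protein-coding
#' and 487 non-coding genes (49 of the PCGs being silent KRTAP-family genes),
#' four planted deletions, ortholog pairing for ~75% of PCGs, a log-normal
#' total-dosage-ratio distribution with median 1.5, genome-wide trans-effects at
#' the observed down/up fractions, negative-binomial read depth at `depth_mean`
#' reads per bin, per-tissue retention near 0.96 scored over 200 cells, and two
#' expression replicates per genotype.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param chrom_name Transchromosome name used in all outputs.
#' @param chrom_start,chrom_end 1-based inclusive bp span of the analysed arm.
#' @param n_pcg,n_npcg Numbers of protein-coding and non-coding genes.
#' @param n_krtap Number of KRTAP-family PCGs (never expressed, no orthologs).
#' @param planted_deletions Tibble of 1-based inclusive `start`/`end` intervals;
#'   must be pairwise disjoint and inside the span.
#' @param ortholog_fraction Probability that a non-KRTAP PCG has a host ortholog.
#' @param dosage_log_mean,dosage_log_sd Log-scale location and spread of the
#'   per-gene total-expression ratio; defaults give a median of 1.5 with band
#'   occupancies near 35/29/36% for <1.3 / 1.3-1.7 / >1.7.
#' @param trans_down_frac,trans_up_frac Fractions of host-genome genes perturbed
#'   down (<0.8-fold) or up (>1.2-fold) in the trisomic animal.
#' @param n_host_genes Number of host-genome genes simulated for the
#'   trans-effect analysis.
#' @param depth_mean Expected reads per depth bin outside deletions.
#' @param depth_noise Negative-binomial dispersion of bin depth; 0 gives
#'   noiseless bins (exactly `depth_mean` outside deletions, 0 inside).
#' @param bin_size Depth bin width in bp.
#' @param nb_dispersion Count-model dispersion for expression counts; 0 gives
#'   deterministic rounded expected counts.
#' @param retention_p True per-cell transchromosome retention probability.
#' @param cells_per_tissue Cells scored per tissue.
#' @param n_tissues Number of tissues scored.
#' @param n_replicates Expression replicates per genotype.
#' @param gene_length_min,gene_length_max Uniform range of simulated gene
#'   lengths in bp; must leave room to pack all genes on the span.
#' @return A validated list of class `tc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_name = "HSA21q",
                       chrom_start = 13021348,
                       chrom_end = 46691226,
                       n_pcg = 213L,
                       n_npcg = 487L,
                       n_krtap = 49L,
                       planted_deletions = default_deletions(chrom_start, chrom_end),
                       ortholog_fraction = 160 / 213,
                       dosage_log_mean = log(1.5),
                       dosage_log_sd = 0.36,
                       trans_down_frac = 712 / 13976,
                       trans_up_frac = 1191 / 13976,
                       n_host_genes = 4000L,
                       depth_mean = 100,
                       depth_noise = 0.05,
                       bin_size = 10000L,
                       nb_dispersion = 0.01,
                       retention_p = 0.96,
                       cells_per_tissue = 200L,
                       n_tissues = 8L,
                       n_replicates = 2L,
                       gene_length_min = 5e3,
                       gene_length_max = 5e4) {
  cfg <- list(
    seed = as.integer(seed), chrom_name = chrom_name,
    chrom_start = chrom_start, chrom_end = chrom_end,
    n_pcg = as.integer(n_pcg), n_npcg = as.integer(n_npcg),
    n_krtap = as.integer(n_krtap),
    planted_deletions = as_tibble(planted_deletions),
    ortholog_fraction = ortholog_fraction,
    dosage_log_mean = dosage_log_mean, dosage_log_sd = dosage_log_sd,
    trans_down_frac = trans_down_frac, trans_up_frac = trans_up_frac,
    n_host_genes = as.integer(n_host_genes),
    depth_mean = depth_mean, depth_noise = depth_noise,
    bin_size = as.integer(bin_size), nb_dispersion = nb_dispersion,
    retention_p = retention_p, cells_per_tissue = as.integer(cells_per_tissue),
    n_tissues = as.integer(n_tissues), n_replicates = as.integer(n_replicates),
    gene_length_min = gene_length_min, gene_length_max = gene_length_max
  )
  validate_sim_config(cfg)
  structure(cfg, class = "tc_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$chrom_start >= cfg$chrom_end) {
    abort("`chrom_start` must be strictly less than `chrom_end`.")
  }
  if (cfg$n_pcg <= 0 || cfg$n_npcg < 0 || cfg$bin_size <= 0 ||
      cfg$cells_per_tissue <= 0 || cfg$n_tissues <= 0 || cfg$n_replicates <= 0 ||
      cfg$n_host_genes <= 0) {
    abort("gene, bin, cell, tissue and replicate counts must be positive.")
  }
  if (cfg$n_krtap < 0 || cfg$n_krtap > cfg$n_pcg) {
    abort("`n_krtap` must lie in [0, n_pcg].")
  }
  fr <- c(cfg$ortholog_fraction, cfg$trans_down_frac, cfg$trans_up_frac,
          cfg$retention_p)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1].")
  if (cfg$trans_down_frac + cfg$trans_up_frac > 1) {
    abort("`trans_down_frac` + `trans_up_frac` must not exceed 1.")
  }
  if (cfg$gene_length_min <= 0 || cfg$gene_length_max < cfg$gene_length_min) {
    abort("gene length range must be positive with min <= max.")
  }
  if (cfg$depth_mean < 0 || cfg$depth_noise < 0 || cfg$nb_dispersion < 0 ||
      cfg$dosage_log_sd < 0) {
    abort("depth, dispersion and spread parameters must be non-negative.")
  }
  del <- cfg$planted_deletions
  if (nrow(del) > 0) {
    stopifnot(all(c("start", "end") %in% names(del)))
    if (any(del$start > del$end)) abort("deletion intervals must have start <= end.")
    if (any(del$start < cfg$chrom_start) || any(del$end > cfg$chrom_end)) {
      abort("planted deletions must lie within [chrom_start, chrom_end].")
    }
    o <- order(del$start)
    if (nrow(del) > 1 && any(del$start[o][-1] <= del$end[o][-nrow(del)])) {
      abort("planted deletions must be pairwise disjoint.")
    }
  }
  invisible(cfg)
}

# fixed per-stage offsets so partial reruns of one stage are reproducible
stage_seed <- function(cfg, stage) {
  offsets <- c(annotation = 1L, depth = 2L, expression = 3L,
               cells = 4L, trials = 5L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}
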