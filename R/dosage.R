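#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_bp * library_size)`.
#'
#' @param count Non-negative fragment count (vectorized).
#' @param length_bp Transcript length in bp; must be positive.
#' @param library_size Total mapped fragments in the sample; must be positive.
#' @return Numeric FPKM values.
#' @examples
#' compute_fpkm(100, 1000, 1e6)  # 100
#' @export
compute_fpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) abort("`length_bp` must be positive.")
  if (any(library_size <= 0)) abort("`library_size` must be positive.")
  if (any(count < 0)) abort("`count` must be non-negative.")
  count * 1e9 / (length_bp * library_size)
}

#' Expression tier of a gene from its FPKM
#'
#' Off if FPKM <= 0.5, medium if 0.5 < FPKM <= 5, high if FPKM > 5 (strict
#' inequalities at the published cutoffs ">0.5" and ">5").
#'
#' @param fpkm Non-negative FPKM values.
#' @return A factor with levels off, medium, high.
#' @export
assign_expression_tier <- function(fpkm) {
  if (any(fpkm < 0)) abort("FPKM must be non-negative.")
  cut(fpkm, breaks = c(-Inf, 0.5, 5, Inf),
      labels = c("off", "medium", "high"))
}

#' Mean FPKM per gene, species and genotype from a long count table
#'
#' Computes per-sample FPKM and averages over replicates within genotype
#' (pooled mode, the default analysis mode for small replicate numbers).
#'
#' @param counts Long tibble with columns gene_id, species, genotype,
#'   replicate, length, count, library_size (as from [sim_counts()]).
#' @return Tibble with gene_id, species, genotype, fpkm (replicate mean).
#' @export
fpkm_table <- function(counts) {
  counts |>
    dplyr::mutate(fpkm = compute_fpkm(.data$count, .data$length,
                                      .data$library_size)) |>
    dplyr::summarise(fpkm = mean(.data$fpkm),
                     .by = c("gene_id", "species", "genotype"))
}

#' Genes passing the euploid expression filter
#'
#' Genes whose mean euploid FPKM is at least `min_fpkm` (inclusive, per the
#' published "FPKM >= 1" filter). These are the genes whose dosage ratios
#' have a well-defined denominator.
#'
#' @param eu_fpkm Tibble with columns gene_id and fpkm (mean euploid FPKM; if
#'   several rows share a gene_id they are averaged first).
#' @param min_fpkm Inclusive threshold.
#' @return Character vector of gene ids.
#' @export
filter_expressed <- function(eu_fpkm, min_fpkm = 1) {
  m <- dplyr::summarise(eu_fpkm, fpkm = mean(.data$fpkm), .by = "gene_id")
  m$gene_id[m$fpkm >= min_fpkm]
}

#' Dosage class from the total-expression ratio
#'
#' Low overexpression if R_tot < 1.3, expected (single-extra-copy band) if
#' 1.3 <= R_tot <= 1.7, high if R_tot > 1.7. Outer inequalities are strict as
#' published; the middle band is closed.
#'
#' @param r_tot Non-negative total-expression ratios.
#' @return Factor with levels low, expected, high.
#' @export
classify_dosage <- function(r_tot) {
  if (any(r_tot < 0)) abort("R_tot must be non-negative.")
  factor(ifelse(r_tot < 1.3, "low", ifelse(r_tot > 1.7, "high", "expected")),
         levels = c("low", "expected", "high"))
}

#' Host-ortholog expression band
#'
#' Reduced if R_m < 0.8, within 80-120% of euploid if 0.8 <= R_m <= 1.2,
#' elevated if R_m > 1.2.
#'
#' @param r_m Non-negative ortholog expression ratios (trisomic over euploid).
#' @return Factor with levels reduced, within_80_120, elevated.
#' @export
classify_ortholog_band <- function(r_m) {
  if (any(r_m < 0)) abort("R_m must be non-negative.")
  factor(ifelse(r_m < 0.8, "reduced",
                ifelse(r_m > 1.2, "elevated", "within_80_120")),
         levels = c("reduced", "within_80_120", "elevated"))
}

#' Cis dosage ratios for ortholog pairs
#'
#' For each pair, from trisomic human FPKM `f_h_tc`, trisomic mouse-ortholog
#' FPKM `f_m_tc`, and euploid mouse FPKM `f_m_eu`:
#' `R_h = f_h_tc / f_m_eu`, `R_m = f_m_tc / f_m_eu`,
#' `R_tot = (f_h_tc + f_m_tc) / f_m_eu`, so that `R_tot = R_h + R_m` exactly.
#' Denominators must pass the expression filter; an unfiltered near-zero
#' denominator is an error, never an infinity.
#'
#' @param f_h_tc,f_m_tc,f_m_eu FPKM vectors of equal length.
#' @param min_fpkm Minimum admissible denominator FPKM.
#' @return Tibble with r_h, r_m, r_tot, dosage_class, ortholog_band.
#' @export
compute_dosage_ratios <- function(f_h_tc, f_m_tc, f_m_eu, min_fpkm = 1) {
  if (any(f_m_eu < min_fpkm)) {
    abort(paste0("euploid ortholog FPKM below the expression filter (",
                 min_fpkm, "); apply filter_expressed() first."))
  }
  if (any(c(f_h_tc, f_m_tc) < 0)) abort("FPKM values must be non-negative.")
  r_h <- f_h_tc / f_m_eu
  r_m <- f_m_tc / f_m_eu
  r_tot <- (f_h_tc + f_m_tc) / f_m_eu
  tibble(r_h = r_h, r_m = r_m, r_tot = r_tot,
         dosage_class = classify_dosage(r_tot),
         ortholog_band = classify_ortholog_band(r_m))
}

#' Per-pair dosage records from count tables
#'
#' Builds the full dosage-record table for human-gene/mouse-ortholog pairs:
#' computes replicate-mean FPKM per genotype, drops KRTAP-family genes,
#' applies the euploid expression filter to the mouse ortholog, and attaches
#' the three cis ratio metrics with dosage class and ortholog band.
#'
#' @param counts Long count tibble (see [fpkm_table()]).
#' @param annotation Gene annotation with gene_id, family, ortholog_id.
#' @param min_fpkm Euploid expression filter (inclusive).
#' @return A tibble of class `tc_dosage` with one row per retained pair;
#'   `glance()` summarizes band occupancies.
#' @export
dosage_records <- function(counts, annotation, min_fpkm = 1) {
  fp <- fpkm_table(counts)
  pairs <- annotation |>
    dplyr::filter(!is.na(.data$ortholog_id), .data$family != "KRTAP") |>
    dplyr::select(human_gene_id = "gene_id", mouse_ortholog_id = "ortholog_id")
  wide <- pairs |>
    dplyr::left_join(
      fp |>
        dplyr::filter(.data$genotype == "Tc", .data$species == "human") |>
        dplyr::select(human_gene_id = "gene_id", f_h_tc = "fpkm"),
      by = "human_gene_id") |>
    dplyr::left_join(
      fp |>
        dplyr::filter(.data$genotype == "Tc", .data$species == "mouse") |>
        dplyr::select(mouse_ortholog_id = "gene_id", f_m_tc = "fpkm"),
      by = "mouse_ortholog_id") |>
    dplyr::left_join(
      fp |>
        dplyr::filter(.data$genotype == "Eu", .data$species == "mouse") |>
        dplyr::select(mouse_ortholog_id = "gene_id", f_m_eu = "fpkm"),
      by = "mouse_ortholog_id") |>
    tidyr::replace_na(list(f_h_tc = 0)) |>
    dplyr::filter(!is.na(.data$f_m_eu), .data$f_m_eu >= min_fpkm)
  out <- dplyr::bind_cols(
    wide,
    compute_dosage_ratios(wide$f_h_tc, wide$f_m_tc, wide$f_m_eu,
                          min_fpkm = min_fpkm))
  class(out) <- c("tc_dosage", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.tc_dosage <- function(x, ...) as_tibble(unclass_first(x))

#' @exportS3Method generics::glance
glance.tc_dosage <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    prop_low = mean(x$dosage_class == "low"),
    prop_expected = mean(x$dosage_class == "expected"),
    prop_high = mean(x$dosage_class == "high"),
    n_within_80_120 = sum(x$ortholog_band == "within_80_120"),
    n_reduced = sum(x$ortholog_band == "reduced"),
    n_elevated = sum(x$ortholog_band == "elevated")
  )
}

#' Count genome-wide trans-dysregulated host genes
#'
#' Among host-genome genes with euploid FPKM >= `min_fpkm`, counts genes with
#' trisomic/euploid ratio strictly below `low` (down-regulated) or strictly
#' above `high` (up-regulated). These are threshold counts, not significance
#' tests.
#'
#' @param eu_fpkm,tc_fpkm Tibbles with columns gene_id and fpkm (genotype
#'   means over replicates) for the same host-genome gene universe.
#' @param min_fpkm Euploid expression filter (inclusive).
#' @param low,high Strict ratio thresholds.
#' @return One-row tibble with n_tested, n_down, n_up.
#' @export
count_dysregulated <- function(eu_fpkm, tc_fpkm, min_fpkm = 1,
                               low = 0.8, high = 1.2) {
  joined <- dplyr::inner_join(
    dplyr::select(eu_fpkm, "gene_id", eu = "fpkm"),
    dplyr::select(tc_fpkm, "gene_id", tc = "fpkm"), by = "gene_id") |>
    dplyr::filter(.data$eu >= min_fpkm)
  ratio <- joined$tc / joined$eu
  tibble(n_tested = nrow(joined),
         n_down = sum(ratio < low),
         n_up = sum(ratio > high))
}

#' Check that genes in deleted regions are transcriptionally silent
#'
#' Flags every deleted human gene whose trisomic FPKM exceeds `max_fpkm`.
#'
#' @param records A `tc_dosage` table (or any tibble with human_gene_id and
#'   f_h_tc).
#' @param deleted_genes Character vector of deleted human gene ids.
#' @param max_fpkm Maximum FPKM compatible with "not detected".
#' @return A list with `pass` (logical) and `violations` (tibble of offending
#'   records).
#' @export
validate_deleted_silence <- function(records, deleted_genes, max_fpkm = 0.5) {
  viol <- records |>
    dplyr::filter(.data$human_gene_id %in% deleted_genes,
                  .data$f_h_tc > max_fpkm)
  list(pass = nrow(viol) == 0, violations = as_tibble(unclass_first(viol)))
}

#' Correlation between RT-PCR CT values and log10 FPKM
#'
#' Pearson correlation between cycle-threshold values and log10(FPKM) for the
#' same transcripts; CT decreases with abundance, so a strong negative r
#' validates the sequencing-based quantification. The sign is reported as
#' computed.
#'
#' @param ct_values Numeric CT values.
#' @param fpkm_values Positive FPKM values, paired with `ct_values`.
#' @return Pearson r.
#' @export
validation_correlation <- function(ct_values, fpkm_values) {
  if (length(ct_values) != length(fpkm_values) || length(ct_values) < 3) {
    abort("need at least 3 paired observations.")
  }
  if (any(fpkm_values <= 0)) abort("FPKM values must be positive for log10.")
  lx <- log10(fpkm_values)
  if (stats::sd(ct_values) == 0 || stats::sd(lx) == 0) {
    abort("zero variance in CT or log10(FPKM); correlation undefined.")
  }
  cor(ct_values, lx)
}
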