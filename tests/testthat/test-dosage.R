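test_that("FPKM follows its definition", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 123, 456), 0)
  set.seed(9)
  cnt <- rpois(50, 500); len <- sample(200:5e4, 50); lib <- runif(50, 1e6, 5e7)
  # independent re-evaluation: per-kb, per-million form
  expect_equal(compute_fpkm(cnt, len, lib),
               cnt / (len / 1e3) / (lib / 1e6))
  expect_error(compute_fpkm(1, 0, 1e6), "length")
  expect_error(compute_fpkm(1, 100, 0), "library")
})

test_that("expression tiers use strict published cutoffs", {
  expect_equal(as.character(assign_expression_tier(60.2)), "high")
  expect_equal(as.character(assign_expression_tier(2.4)), "medium")
  expect_equal(as.character(assign_expression_tier(0.5)), "off")
  expect_equal(as.character(assign_expression_tier(5)), "medium")
  expect_equal(as.character(assign_expression_tier(0)), "off")
  expect_error(assign_expression_tier(-1), "non-negative")
})

test_that("euploid expression filter is inclusive at the threshold", {
  tbl <- tibble::tibble(gene_id = c("a", "b", "c"), fpkm = c(0, 1, 5))
  expect_setequal(filter_expressed(tbl), c("b", "c"))
  expect_length(filter_expressed(tibble::tibble(gene_id = "a", fpkm = 0)), 0)
  set.seed(2)
  rnd <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                        fpkm = rlnorm(200, 0, 1.5))
  expect_setequal(filter_expressed(rnd, min_fpkm = 1.5),
                  rnd$gene_id[rnd$fpkm >= 1.5])
})

test_that("dosage ratios satisfy the additive identity and guard denominators", {
  r <- compute_dosage_ratios(0, 10, 10)
  expect_equal(r$r_tot, 1)                      # disomic limit, deleted gene
  r2 <- compute_dosage_ratios(5, 10, 10)
  expect_equal(r2$r_tot, 1.5)                   # ideal single extra copy
  set.seed(5)
  fh <- runif(500, 0, 50); fm <- runif(500, 1, 50); fe <- runif(500, 1, 50)
  rr <- compute_dosage_ratios(fh, fm, fe)
  expect_true(all(abs(rr$r_tot - (rr$r_h + rr$r_m)) <=
                    1e-12 * pmax(rr$r_tot, 1)))
  expect_error(compute_dosage_ratios(1, 1, 0.5), "filter")
})

test_that("dosage and ortholog band classification respect printed boundaries", {
  expect_equal(as.character(classify_dosage(c(1.5, 1.3, 1.7, 1.29, 1.71, 2))),
               c("expected", "expected", "expected", "low", "high", "high"))
  expect_error(classify_dosage(-0.1), "non-negative")
  expect_equal(as.character(classify_ortholog_band(c(1, 0.79, 1.21, 0.8, 1.2))),
               c("within_80_120", "reduced", "elevated", "within_80_120",
                 "within_80_120"))
  expect_error(classify_ortholog_band(-1), "non-negative")
})

test_that("ratio metrics are invariant to rescaling all library sizes", {
  cfg <- tiny_config(seed = 31, n_pcg = 30, ortholog_fraction = 1)
  res <- sim_annotation(cfg)
  expr <- sim_counts(cfg, res)
  rec1 <- dosage_records(expr$counts, res$annotation)
  scaled <- dplyr::mutate(expr$counts, library_size = library_size * 3.7)
  rec2 <- dosage_records(scaled, res$annotation,
                         min_fpkm = 1 / 3.7)  # same gene set passes
  keep <- rec2$human_gene_id %in% rec1$human_gene_id
  expect_equal(rec2$r_tot[keep], rec1$r_tot, tolerance = 1e-12)
  expect_equal(rec2$r_h[keep], rec1$r_h, tolerance = 1e-12)
  expect_equal(rec2$r_m[keep], rec1$r_m, tolerance = 1e-12)
})

test_that("trans-dysregulation counting is a strict threshold count", {
  eu <- tibble::tibble(gene_id = c("a", "b", "c", "d"), fpkm = c(2, 4, 10, 0.5))
  expect_equal(count_dysregulated(eu, eu),
               tibble::tibble(n_tested = 3L, n_down = 0L, n_up = 0L))
  # exact boundary ratios are not counted
  tc <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       fpkm = c(2 * 0.8, 4 * 1.2, 10 * 1.21, 5))
  got <- count_dysregulated(eu, tc)
  expect_equal(got$n_down, 0L)
  expect_equal(got$n_up, 1L)
  # planted 5% down / 8% up recovered exactly at zero noise
  cfg <- tiny_config(seed = 41, trans_down_frac = 0.05, trans_up_frac = 0.08,
                     nb_dispersion = 0, n_host_genes = 400L)
  res <- sim_annotation(cfg)
  expr <- sim_counts(cfg, res)
  fp <- fpkm_table(expr$counts)
  host_eu <- dplyr::filter(fp, genotype == "Eu", startsWith(gene_id, "HG"))
  host_tc <- dplyr::filter(fp, genotype == "Tc", startsWith(gene_id, "HG"))
  truth <- expr$truth$host
  tested <- filter_expressed(host_eu)
  dys <- count_dysregulated(host_eu, host_tc)
  expect_equal(dys$n_down, sum(truth$trans_class == "down" &
                                 truth$gene_id %in% tested))
  expect_equal(dys$n_up, sum(truth$trans_class == "up" &
                               truth$gene_id %in% tested))
})

test_that("deleted genes are transcriptionally silent, violations are flagged", {
  rec <- tibble::tibble(human_gene_id = c("g1", "g2", "g3"),
                        f_h_tc = c(0, 0.2, 4))
  ok <- validate_deleted_silence(rec, c("g1", "g2"))
  expect_true(ok$pass)
  expect_equal(nrow(ok$violations), 0)
  bad <- validate_deleted_silence(rec, c("g1", "g3"))
  expect_false(bad$pass)
  expect_equal(bad$violations$human_gene_id, "g3")
  expect_true(validate_deleted_silence(rec, character(0))$pass)
  # generator guarantees silence at zero noise
  del <- tibble::tibble(start = 1400001, end = 1600000)
  cfg <- tiny_config(seed = 51, n_pcg = 40, ortholog_fraction = 1,
                     planted_deletions = del, nb_dispersion = 0)
  res <- sim_annotation(cfg)
  expr <- sim_counts(cfg, res)
  recs <- dosage_records(expr$counts, res$annotation, min_fpkm = 0.5)
  expect_true(validate_deleted_silence(
    recs, res$truth$gene_id[res$truth$deleted])$pass)
})

test_that("CT / log10-FPKM correlation behaves and guards its inputs", {
  fpkm <- 2^seq(-1, 8, length.out = 40)
  ct <- 30 - 3.3 * log10(fpkm)
  expect_equal(abs(validation_correlation(ct, fpkm)), 1)
  set.seed(3)
  # destroying the pairing destroys the correlation on average
  # (mean of the permutation distribution of r is -1/(n-1))
  rs <- replicate(400, validation_correlation(sample(ct), fpkm))
  expect_lt(abs(mean(rs) + 1 / 39), 0.05)
  expect_error(validation_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(validation_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(validation_correlation(c(1, 2, 3), c(1, 2, -3)), "positive")
})
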