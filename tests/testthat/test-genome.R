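test_that("transchromosome span arithmetic and Mb rounding", {
  s <- transchromosome_span(13021348, 46691226)
  expect_equal(s$span_bp, 33669878)
  expect_equal(s$span_mb, 34)
  expect_equal(transchromosome_span(1, 1000001)$span_mb, 1)
  expect_equal(transchromosome_span(1, 1500002)$span_bp, 1500001)
  expect_equal(transchromosome_span(1, 1500002)$span_mb, 2)  # round half up
  expect_equal(transchromosome_span(1, 1500001)$span_mb, 2)  # exactly 1.5 Mb
  expect_error(transchromosome_span(10, 10), "positive")
  expect_error(transchromosome_span(10, 5), "positive")
})

test_that("depth normalization divides by the positive-bin median", {
  prof <- tibble::tibble(chrom = "c", start = 1:4, end = 1:4,
                         depth = c(2, 2, 0, 2))
  expect_equal(normalize_depth(prof)$norm_depth, c(1, 1, 0, 1))
  const <- tibble::tibble(chrom = "c", start = 1:5, end = 1:5, depth = 7)
  expect_true(all(normalize_depth(const)$norm_depth == 1))
  set.seed(1)
  rand <- tibble::tibble(chrom = "c", start = 1:50, end = 1:50,
                         depth = rpois(50, 30))
  nd <- normalize_depth(rand)
  expect_equal(median(nd$norm_depth[nd$depth > 0]), 1)
  allzero <- tibble::tibble(chrom = "c", start = 1, end = 1, depth = 0)
  expect_error(normalize_depth(allzero), "all-zero")
})

make_profile <- function(norm) {
  n <- length(norm)
  tibble::tibble(chrom = "c", start = seq(1, by = 10, length.out = n),
                 end = seq(10, by = 10, length.out = n), norm_depth = norm)
}

test_that("deletion calling matches the brute-force run-scan oracle", {
  expect_equal(nrow(call_deletions(make_profile(rep(1, 20)))), 0)
  # one clean 10-bin deletion
  norm <- rep(1, 30); norm[11:20] <- 0
  calls <- call_deletions(make_profile(norm))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 101)
  expect_equal(calls$end, 200)
  expect_equal(calls$n_bins, 10L)
  # two runs separated by more than merge_gap_bins stay separate
  norm2 <- rep(1, 30); norm2[5:8] <- 0; norm2[15:19] <- 0
  calls2 <- call_deletions(make_profile(norm2), merge_gap_bins = 1)
  expect_equal(nrow(calls2), 2)
  # property: random profiles of <= 50 bins, random caller parameters
  set.seed(42)
  for (rep_i in 1:200) {
    n <- sample(1:50, 1)
    norm <- round(runif(n), 2)
    thr <- runif(1, 0.1, 0.9)
    mb <- sample(1:4, 1)
    gap <- sample(0:2, 1)
    got <- call_deletions(make_profile(norm), threshold = thr, min_bins = mb,
                          merge_gap_bins = gap)
    want <- oracle_call_deletions(norm, thr, mb, gap)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, function(w) (w["first"] - 1) * 10 + 1,
                                     numeric(1)), ignore_attr = TRUE)
      expect_equal(got$end, vapply(want, function(w) w["last"] * 10,
                                   numeric(1)), ignore_attr = TRUE)
    }
  }
})

test_that("gene annotation of calls uses any-overlap and recovers truth", {
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "c",
                        start = c(100L, 300L, 501L), end = c(150L, 500L, 600L),
                        biotype = c("PCG", "PCG", "nonPCG"),
                        family = "other", ortholog_id = NA_character_,
                        length = c(51L, 201L, 100L))
  no_calls <- call_deletions(make_profile(rep(1, 5)))
  res0 <- annotate_deletions(no_calls, ann, span_bp = 1000)
  expect_equal(glance(res0)$n_deleted_pcg + glance(res0)$n_deleted_npcg, 0)
  expect_equal(glance(res0)$frac_span_deleted, 0)
  # call [200, 500]: overlaps g2; g3 starts at 501 (abutting) -> not deleted
  calls <- tibble::tibble(chrom = "c", start = 200L, end = 500L)
  res <- annotate_deletions(calls, ann, span_bp = 1000)
  expect_equal(tidy(res)$deleted, c(FALSE, TRUE, FALSE))
  expect_equal(glance(res)$n_deleted_pcg, 1)
  expect_equal(glance(res)$frac_span_deleted, 301 / 1000)
  # overlap decisions equal per-base set intersection
  expect_equal(tidy(res)$deleted,
               oracle_overlap(ann$start, ann$end,
                              tibble::tibble(start = 200, end = 500)))
  # coordinate-system mismatch
  bad <- tibble::tibble(chrom = "other", start = 1L, end = 2L)
  expect_error(annotate_deletions(bad, ann, span_bp = 1000), "coordinate")
})

test_that("planted deletions are recovered with exact boundaries at zero noise", {
  cfg <- sim_config(seed = 21, depth_noise = 0)
  study <- sim_study(cfg)
  calls <- call_deletions(normalize_depth(study$depth))
  expect_equal(nrow(calls), nrow(cfg$planted_deletions))
  expect_equal(calls$start, cfg$planted_deletions$start)
  expect_equal(calls$end, cfg$planted_deletions$end)
  res <- annotate_deletions(calls, study$annotation,
                            span_bp = cfg$chrom_end - cfg$chrom_start)
  expect_equal(tidy(res)$deleted, study$truth$genes$deleted)
})

test_that("variant classification against a known-allele catalog", {
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
  cat91 <- tibble::tibble(chrom = "HSA21q", pos = 1:91 * 1000L,
                          ref = "C", alt = "A")
  expect_equal(glance(classify_variants(empty, cat91))$n_known, 0)
  expect_equal(glance(classify_variants(empty, cat91))$n_novel, 0)
  # full coverage -> novel = 0
  expect_equal(glance(classify_variants(cat91, cat91))$n_novel, 0)
  # 91 variants of which 90 are catalogued (one de novo coding variant)
  vars <- cat91
  vars$pos[91] <- 33554276L  # not in catalog
  cls <- classify_variants(vars, cat91[1:90, ])
  expect_equal(glance(cls)$n_known, 90)
  expect_equal(glance(cls)$n_novel, 1)
  expect_false(cls$known[91])
  expect_error(classify_variants(rbind(cat91, cat91[1, ]), cat91), "duplicate")
  bad <- tibble::tibble(chrom = "c", pos = 1L, ref = "C", alt = "C")
  expect_error(classify_variants(bad, cat91), "differ")
})
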