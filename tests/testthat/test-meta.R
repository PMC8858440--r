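index_with <- function(study_id, sig, ref = NULL) {
  ix <- fake_index(reference = union(ref %||% character(), names(sig)),
                   significant_p = sig)
  ix$study_id <- study_id
  ix$group <- study_id
  ix
}

test_that("compound merging unions studies and keeps the best p-value", {
  a <- index_with("A", c(C1 = 0.01, C2 = 0.04))
  b <- index_with("B", c(C1 = 0.003, C3 = 0.02))

  merged <- merge_studies(list(a, b), "union")
  cmp <- merged$compounds
  expect_equal(cmp$compound_id, c("C1", "C2", "C3"))
  expect_equal(cmp$best_p, c(0.003, 0.04, 0.02))
  expect_equal(cmp$n_studies_seen, c(2L, 1L, 1L))

  shared <- merge_studies(list(a, b), "shared")
  expect_equal(shared$compounds$compound_id, "C1")
  expect_equal(shared$compounds$best_p, 0.003)

  solo_u <- merge_studies(list(a), "union")
  solo_s <- merge_studies(list(a), "shared")
  expect_equal(solo_u$compounds, solo_s$compounds)
  expect_equal(solo_u$compounds$compound_id, c("C1", "C2"))

  expect_error(merge_studies(list(a, a)), "duplicate",
               class = "pathmeta_validation_error")

  disjoint <- index_with("B", c(C9 = 0.01), ref = "C9")
  expect_error(merge_studies(list(a, disjoint), "shared"),
               "no shared", class = "pathmeta_empty_universe_error")
})

test_that("meta-analysis of a study with its own copy is idempotent", {
  m <- toy_metabolic_model()
  s1 <- random_toy_study(31)
  s2 <- random_toy_study(31)
  s2$study_id <- "copy"
  s2$group <- "copy"
  s2$features$source_tag <- "copy"

  single <- meta_analyze(list(s1), m, n_permutations = 5, seed = 9)
  double <- meta_analyze(list(s1, s2), m, n_permutations = 5, seed = 9)

  expect_equal(double$results$pathway_id, single$results$pathway_id)
  expect_equal(double$results$p_raw, single$results$p_raw)
  expect_equal(double$results$merged_hits, single$results$merged_hits)
})

test_that("results do not depend on study input order", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth("P4")
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = 50)

  fwd <- meta_analyze(studies, m, n_permutations = 20, seed = 3)
  rev <- meta_analyze(rev(studies), m, n_permutations = 20, seed = 3)
  expect_equal(fwd$results, rev$results)
  expect_identical(fwd$null$values, rev$null$values)
})

test_that("shared counts shrink as the sharing threshold rises", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth("P3")
  studies <- simulate_meta_set(m, tr, n_studies = 3, base_seed = 70)
  counts <- lapply(1:3, function(k) {
    r <- meta_analyze(studies, m, min_studies = k, n_permutations = 2,
                      seed = 1)$results
    setNames(r$shared_count, r$pathway_id)[sort(r$pathway_id)]
  })
  expect_true(all(counts[[2]] <= counts[[1]]))
  expect_true(all(counts[[3]] <= counts[[2]]))
})

test_that("a pathway spiked in both studies ranks first", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth("P3", effect = 0.05, ppm_jitter_sd = 2)
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = 205)
  meta <- meta_analyze(studies, m, n_permutations = 20, seed = 5)
  expect_equal(meta$results$pathway_id[[1]], "P3")
})

test_that("result filtering thresholds shared counts and prunes adducts", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth(c("P3", "P4"))
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = 90)
  meta <- meta_analyze(studies, m, n_permutations = 5, seed = 2)

  # identity at zero
  expect_equal(filter_results(meta, min_shared = 0)$results, meta$results)

  kept <- filter_results(meta, min_shared = 5)$results
  expect_true(all(kept$shared_count >= 5))
  expect_equal(kept$pathway_id,
               meta$results$pathway_id[meta$results$shared_count >= 5])

  # merged-count variant
  kept_m <- filter_results(meta, min_shared = 5, count = "merged")$results
  expect_true(all(kept_m$merged_hits >= 5))

  # adduct filter: a compound seen only through excluded adducts vanishes
  prov <- meta$merged$provenance
  by_cmp <- split(prov$adduct, prov$compound_id)
  only_na <- names(by_cmp)[vapply(by_cmp, function(a)
    !any(a == "M+H", na.rm = TRUE), logical(1))]
  filtered <- filter_results(meta, min_shared = 0, adduct_filter = "M+H")
  displayed <- unique(unlist(filtered$results$merged_hit_compound_ids))
  expect_length(intersect(displayed, only_na), 0)
  # p-values never recomputed by filtering
  expect_equal(
    filtered$results$p_raw,
    meta$results$p_raw[match(filtered$results$pathway_id,
                             meta$results$pathway_id)])
})

test_that("tidy and glance summarise the fitted object", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth("P4")
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = 41)
  meta <- meta_analyze(studies, m, n_permutations = 5, seed = 8)

  td <- tidy(meta)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(meta$results))
  expect_true(all(c("p_raw", "p_adjusted", "shared_count",
                    "compound_hits") %in% names(td)))

  gl <- glance(meta)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_studies, 2)
  expect_equal(gl$universe_size, length(meta$merged$merged_reference))

  expect_s3_class(autoplot(meta), "ggplot")
  expect_s3_class(autoplot(meta$null), "ggplot")
})
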