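test_that("neutral mass algebra matches standard adduct arithmetic", {
  expect_equal(neutral_mass(181.070664, 1.007276, 1, 1), 180.063388,
               tolerance = 1e-9)
  expect_equal(neutral_mass(179.056112, -1.007276, -1, 1), 180.063388,
               tolerance = 1e-9)
  expect_equal(neutral_mass(361.134052, 1.007276, 1, 2), 180.063388,
               tolerance = 1e-9)
})

test_that("mass transforms round-trip for every rule", {
  rules <- default_adducts()
  masses <- withr::with_seed(99, runif(25, 70, 900))
  for (r in seq_len(nrow(rules))) {
    mz <- adduct_mz(masses, rules$mass_shift[r], rules$charge[r],
                    rules$mol_multiplier[r])
    back <- neutral_mass(mz, rules$mass_shift[r], rules$charge[r],
                         rules$mol_multiplier[r])
    expect_equal(back, masses, tolerance = 1e-9)
  }
})

test_that("candidate enumeration applies mode, order, and positivity", {
  cands <- enumerate_adducts(181.070664, "positive")
  expect_equal(cands$neutral_mass[cands$adduct == "M+H"], 180.063388,
               tolerance = 1e-6)
  expect_equal(cands$neutral_mass[cands$adduct == "M+Na"], 158.081446,
               tolerance = 1e-6)
  # candidates come back in rule-table order
  pos_rules <- default_adducts()
  pos_rules <- pos_rules$adduct[pos_rules$mode == "positive"]
  expect_equal(cands$adduct, pos_rules[pos_rules %in% cands$adduct])

  # tiny m/z: all inferred neutral masses nonpositive -> nothing left
  tiny <- enumerate_adducts(0.5, "positive")
  expect_false("2M+H" %in% tiny$adduct)
  expect_true(all(tiny$neutral_mass > 0))

  pos_only <- default_adducts()
  pos_only <- pos_only[pos_only$mode == "positive", ]
  expect_error(enumerate_adducts(100, "negative", adducts = pos_only),
               class = "pathmeta_config_error")
})

test_that("study matching finds exact hits and respects tolerance", {
  m <- toy_metabolic_model()

  s <- ms_study(data.frame(mz = 181.070664, p_value = 0.01),
                mode = "positive", study_id = "one", mz_tol_ppm = 10)
  ix <- annotate_study(s, m)
  sig <- ix$matched_significant
  expect_true("glucose" %in% sig$compound_id)
  expect_equal(sig$best_p[sig$compound_id == "glucose"], 0.01)
  glc <- ix$matches[ix$matches$compound_id == "glucose", ]
  expect_equal(glc$adduct, "M+H")
  expect_lt(abs(glc$ppm_error), 0.1)

  # ~10.1 ppm off glucose: invisible at 1 ppm tolerance
  s2 <- ms_study(data.frame(mz = 181.072500, p_value = 0.01),
                 mode = "positive", study_id = "two", mz_tol_ppm = 1)
  ix2 <- annotate_study(s2, m)
  expect_equal(nrow(ix2$matches), 0)
})

test_that("a compound hit by several features keeps the best p-value", {
  m <- toy_metabolic_model()
  s <- ms_study(data.frame(mz = c(181.070664, 181.070664),
                           p_value = c(0.04, 0.002)),
                mode = "positive", study_id = "dup", p_cutoff = 0.05)
  ix <- annotate_study(s, m)
  sig <- ix$matched_significant
  expect_equal(sig$best_p[sig$compound_id == "glucose"], 0.002)
  expect_equal(sum(ix$matches$compound_id == "glucose"), 2)
})

test_that("matched universe grows monotonically with the ppm tolerance", {
  for (seed in c(5, 6)) {
    sizes <- vapply(c(1, 2, 5, 10, 20, 50), function(tol) {
      s <- random_toy_study(seed, mz_tol_ppm = tol)
      length(annotate_study(s, toy_metabolic_model())$
               matched_reference_compounds)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("matching agrees with the brute-force triple scan", {
  m <- toy_metabolic_model()
  for (seed in 101:110) {
    s <- random_toy_study(seed)
    got <- annotate_study(s, m)$matches
    got <- got[order(got$feature_id, got$compound_id, got$adduct),
               c("feature_id", "compound_id", "adduct")]
    want <- match_oracle(s, m)
    expect_equal(unname(as.list(got)),
                 unname(as.list(tibble::as_tibble(want))))
  }
})

test_that("confirmed metabolites join the index by the stated rules", {
  m <- toy_metabolic_model()
  s <- ms_study(data.frame(mz = 181.070664, p_value = 0.01),
                mode = "positive", study_id = "c", p_cutoff = 0.05)
  ix <- annotate_study(s, m)

  recs <- tibble::tibble(
    name = c("Glucose", "taurine"),
    name_normalized = c("glucose", "taurine"),
    compound_id = NA_character_, p_value = c(NA, 0.8))
  ix2 <- add_confirmed(ix, recs, m)

  # no p-value -> confirmed and significant by default
  expect_true("glucose" %in% ix2$matched_significant$compound_id)
  # p above the cutoff -> reference only
  expect_true("taurine" %in% ix2$matched_reference_compounds)
  expect_false("taurine" %in% ix2$matched_significant$compound_id)

  # unknown names warn and leave the index unchanged
  bad <- tibble::tibble(name = "unobtainium",
                        name_normalized = "unobtainium",
                        compound_id = NA_character_, p_value = NA_real_)
  expect_warning(ix3 <- add_confirmed(ix, bad, m), "unobtainium")
  expect_equal(ix3$matched_reference_compounds,
               ix$matched_reference_compounds)
  expect_equal(ix3$matched_significant, ix$matched_significant)

  # conservative option: confirmed-without-p stays out of the significant set
  ix4 <- add_confirmed(ix, recs[1, ], m, confirmed_as = "reference")
  expect_true("glucose" %in% ix4$matched_reference_compounds)
  # glucose is still significant via its own feature (p = 0.01), so check
  # a name-only compound instead
  recs5 <- tibble::tibble(name = "Spermine", name_normalized = "spermine",
                          compound_id = NA_character_, p_value = NA_real_)
  ix5 <- add_confirmed(ix, recs5, m, confirmed_as = "reference")
  expect_true("spermine" %in% ix5$matched_reference_compounds)
  expect_false("spermine" %in% ix5$matched_significant$compound_id)
})
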