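write_table <- function(df, sep, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

test_that("generic peak lists parse identically from tsv and csv", {
  df <- data.frame(mz = c(100.5, 200.25, 300.125),
                   p_value = c(0.01, 0.2, 0.9))
  tsv <- write_table(df, "\t", ".tsv")
  csv <- write_table(df, ",", ".csv")

  s_tsv <- read_peaklist(tsv, mode = "positive")
  s_csv <- read_peaklist(csv, mode = "positive")

  expect_equal(nrow(s_tsv$features), 3)
  expect_equal(unique(s_tsv$features$source_tag), basename(tsv))
  cols <- c("mz", "rt", "p_value", "intensity", "fold_change")
  expect_equal(s_tsv$features[cols], s_csv$features[cols])
})

test_that("missing required columns raise a dialect error naming them", {
  df <- data.frame(mz = c(100, 200), intensity = c(1, 2))
  path <- write_table(df, "\t", ".tsv")
  expect_error(read_peaklist(path, mode = "positive"), "p_value",
               class = "pathmeta_dialect_error")
})

test_that("non-numeric values fail with a line number unless skipping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tp_value", "100.5\t0.01", "oops\t0.5", "300.1\t0.9"),
             path)
  expect_error(read_peaklist(path, mode = "positive"), "line 3",
               class = "pathmeta_row_error")
  expect_warning(
    s <- read_peaklist(path, mode = "positive", skip_bad_rows = TRUE),
    "dropping")
  expect_equal(s$features$mz, c(100.5, 300.1))
})

test_that("xcms diffreport dialect maps synonyms and takes max intensity", {
  df <- data.frame(name = c("f1", "f2"), fold = c(2.5, 0.4),
                   tstat = c(3, -2), pvalue = c(0.01, 0.3),
                   mzmed = c(181.07, 90.03), rtmed = c(120, 300),
                   sampleA = c(1000, 40), sampleB = c(2500, 10))
  path <- write_table(df, "\t", ".tsv")
  s <- read_peaklist(path, dialect = "xcms", mode = "positive")
  expect_equal(s$features$mz, c(181.07, 90.03))
  expect_equal(s$features$p_value, c(0.01, 0.3))
  expect_equal(s$features$fold_change, c(2.5, 0.4))
  expect_equal(s$features$intensity, c(2500, 40))
})

test_that("workbench dialect keeps the metabolite name", {
  df <- data.frame(metabolite_name = c("Glucose", "Taurine"),
                   mz = c(181.07, 126.02), p_value = c(0.03, 0.4))
  path <- write_table(df, "\t", ".tsv")
  s <- read_peaklist(path, dialect = "workbench", mode = "positive")
  expect_equal(s$features$name, c("Glucose", "Taurine"))
})

test_that("named-metabolite tables are normalized and validated", {
  df <- data.frame(name = c("Glucose", "Taurine "), p_value = c(0.01, NA))
  path <- write_table(df, "\t", ".tsv")
  recs <- read_named_metabolites(path)
  expect_equal(recs$name_normalized, c("glucose", "taurine"))
  expect_equal(recs$p_value, c(0.01, NA))

  df2 <- data.frame(name = "x", compound_id = "C00031")
  recs2 <- read_named_metabolites(write_table(df2, "\t", ".tsv"))
  expect_equal(recs2$compound_id, "C00031")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tp_value", empty)
  expect_error(read_named_metabolites(empty), "no records",
               class = "pathmeta_format_error")
})

test_that("significance partition obeys threshold and intensity semantics", {
  feats <- data.frame(mz = 100 + 1:10,
                      p_value = c(rep(0.001, 3), rep(0.5, 7)),
                      intensity = c(NA, 10, 100, rep(50, 7)))
  s <- ms_study(feats, mode = "positive", study_id = "s",
                p_cutoff = 0.05, intensity_cutoff = 0)
  parts <- partition_significant(s)
  expect_equal(nrow(parts$significant), 3)
  expect_equal(nrow(parts$reference), 10)
  expect_true(all(parts$significant$feature_id %in%
                    parts$reference$feature_id))

  # boundary: cutoff 1 keeps everything with p < 1 significant
  s1 <- ms_study(feats, mode = "positive", study_id = "s", p_cutoff = 1)
  p1 <- partition_significant(s1)
  expect_equal(nrow(p1$significant), nrow(p1$reference))

  # intensity floor above every intensity empties both lists
  s2 <- ms_study(feats, mode = "positive", study_id = "s",
                 intensity_cutoff = 1e9)
  p2 <- partition_significant(s2)
  expect_equal(nrow(p2$reference), 0)
  expect_equal(nrow(p2$significant), 0)

  # features lacking intensity are dropped once a floor is set
  s3 <- ms_study(feats, mode = "positive", study_id = "s",
                 intensity_cutoff = 5)
  expect_false("F1" %in% partition_significant(s3)$reference$feature_id)

  expect_error(ms_study(feats, mode = "positive", p_cutoff = 0),
               class = "pathmeta_parameter_error")
  expect_error(ms_study(feats, mode = "positive", p_cutoff = 1.5),
               class = "pathmeta_parameter_error")
})

test_that("studies round-trip through the generic dialect", {
  for (seed in c(11, 22, 33)) {
    s <- random_toy_study(seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_peaklist(s, path)
    s2 <- read_peaklist(path, mode = s$mode, p_cutoff = s$params$p_cutoff,
                        mz_tol_ppm = s$params$mz_tol_ppm)
    for (col in c("mz", "p_value", "rt", "intensity", "fold_change")) {
      expect_equal(s2$features[[col]], s$features[[col]], tolerance = 1e-9)
    }
  }
})
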