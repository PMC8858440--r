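demo_meta <- function(seed = 30) {
  m <- toy_metabolic_model()
  tr <- synthetic_truth(c("P3", "P4"))
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = seed)
  list(model = m,
       meta = meta_analyze(studies, m, n_permutations = 10, seed = 4))
}

test_that("pathway results table has the documented shape", {
  d <- demo_meta()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_results(d$meta, path)

  lines <- readLines(path)
  expect_length(lines, nrow(d$meta$results) + 1)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("pathway_id", "pathway_name", "pathway_size",
                    "matched_in_reference", "hits_study1", "hits_study2",
                    "shared_metabolites", "merged_hits", "p_raw",
                    "p_adjusted", "gene_hits_n", "gene_hits",
                    "protein_hits_n", "protein_hits", "compound_hits") %in%
                    names(tab)))
  # sorted by ascending raw p
  expect_true(!is.unsorted(tab$p_raw))
  # no omics supplied: columns present but empty
  expect_true(all(tab$gene_hits_n == 0))

  # rewriting is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_results(d$meta, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("metabolite table lists every compound cited by pathways", {
  d <- demo_meta()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_results(d$meta, path, model = d$model)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(d$meta$merged$compounds))

  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_results(d$meta, ppath)
  ptab <- readr::read_tsv(ppath, show_col_types = FALSE)
  cited <- unlist(strsplit(ptab$compound_hits[!is.na(ptab$compound_hits)],
                           ";"))
  expect_true(all(cited %in% tab$compound_id))

  # a compound observed through two adducts lists both
  multi <- tab$adducts[grepl(";", tab$adducts)]
  if (length(multi) > 0) {
    expect_gt(length(strsplit(multi[[1]], ";")[[1]]), 1)
  }
})

test_that("shared merge mode restricts the metabolite table", {
  m <- toy_metabolic_model()
  tr <- synthetic_truth(c("P3", "P4"))
  studies <- simulate_meta_set(m, tr, n_studies = 2, base_seed = 33)
  meta <- meta_analyze(studies, m, merge_mode = "shared",
                       n_permutations = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_results(meta, path, model = m)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(tab$n_studies_seen >= 2))
})

test_that("the synth and run subcommands close the loop offline", {
  dir <- withr::local_tempdir()
  synth_dir <- file.path(dir, "synth")
  status <- suppressMessages(
    run_cli(c("synth", "--out", synth_dir, "--model", "toy",
              "--enriched", "P3,P4", "--seed", "5",
              "--n-background", "150")))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(synth_dir, "study1.tsv")))
  expect_true(file.exists(file.path(synth_dir, "truth.json")))

  config <- list(
    model = "toy",
    studies = list(
      list(path = file.path(synth_dir, "study1.tsv"), dialect = "generic",
           mode = "pos", p_cutoff = 0.05, ppm = 10),
      list(path = file.path(synth_dir, "study2.tsv"), dialect = "generic",
           mode = "pos", p_cutoff = 0.05, ppm = 10)),
    merge_mode = "union", min_shared = 0, permutations = 20, seed = 7,
    out = file.path(dir, "out"))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(config, cfg_path)

  expect_equal(run_cli(c("run", "--config", cfg_path)), 0L)
  expect_true(file.exists(file.path(dir, "out", "pathway_results.tsv")))
  expect_true(file.exists(file.path(dir, "out", "metabolite_results.tsv")))
  expect_true(file.exists(file.path(dir, "out", "run_manifest.json")))

  tab <- readr::read_tsv(file.path(dir, "out", "pathway_results.tsv"),
                         show_col_types = FALSE)
  expect_true(tab$pathway_id[[1]] %in% c("P3", "P4"))
})

test_that("the CLI surfaces missing inputs as nonzero exits", {
  dir <- withr::local_tempdir()
  config <- list(model = "/no/such/model.json",
                 studies = list(list(path = "also-missing.tsv")))
  cfg_path <- file.path(dir, "bad.yaml")
  yaml::write_yaml(config, cfg_path)
  expect_equal(suppressMessages(run_cli(c("run", "--config", cfg_path))), 1L)
  expect_equal(suppressMessages(run_cli(c("run"))), 1L)
  expect_equal(suppressMessages(run_cli(character())), 1L)
  expect_equal(suppressMessages(run_cli("frobnicate")), 1L)
})

test_that("validate-model accepts the bundled fixture and rejects junk", {
  fixture <- system.file("extdata", "toy_model.json", package = "pathmeta")
  expect_equal(
    suppressMessages(run_cli(c("validate-model", "--model", fixture))), 0L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"compounds": [], "pathways": []}', bad)
  expect_equal(
    suppressMessages(run_cli(c("validate-model", "--model", bad))), 1L)
})
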