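fmt6 <- function(x) {
  # 6 significant digits, fixed notation, deterministic across runs
  ifelse(is.na(x), "", formatC(signif(x, 6), format = "fg", digits = 6))
}

#' Write the pathway results table
#'
#' The main deliverable of the meta-analysis: one row per pathway, sorted
#' by ascending raw p-value, with the pathway size, the matched reference
#' count, per-study significant-hit columns (`hits_<study>`), the
#' shared-metabolite and merged hit counts, raw and adjusted p-values, the
#' omics overlay columns (present, empty when no lists were supplied), and
#' the semicolon-joined merged compound hits. Floating point numbers carry
#' 6 significant digits; rewriting the same result produces a
#' byte-identical file.
#'
#' @param x A `pathmeta_meta` object (optionally after [overlay_omics()]
#'   and [filter_results()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pathway_results <- function(x, path) {
  res <- arrange(x$results, .data$p_raw, desc(.data$merged_hits),
                 .data$pathway_id)
  out <- tibble(
    pathway_id = res$pathway_id,
    pathway_name = res$pathway_name,
    pathway_size = res$pathway_size,
    matched_in_reference = res$matched_in_reference)
  for (uid in x$unit_ids) {
    out[[paste0("hits_", uid)]] <- map_int(res$per_study_hits, function(h)
      if (uid %in% names(h)) h[[uid]] else 0L)
  }
  out$shared_metabolites <- res$shared_count
  out$merged_hits <- res$merged_hits
  out$p_raw <- fmt6(res$p_raw)
  out$p_adjusted <- fmt6(res$p_adjusted)
  out$gene_hits_n <- lengths(res$gene_hits)
  out$gene_hits <- map_chr(res$gene_hits, paste, collapse = ";")
  out$protein_hits_n <- lengths(res$protein_hits)
  out$protein_hits <- map_chr(res$protein_hits, paste, collapse = ";")
  out$compound_hits <- map_chr(res$merged_hit_compound_ids, paste,
                               collapse = ";")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the metabolite results table
#'
#' The list of dysregulated metabolites behind the pathway table: one row
#' per merged compound with the number of studies it was seen significant
#' in, its best p-value, per-study best p-value columns (`p_<study>`), and
#' the adducts and source files through which it was observed. Under
#' `"shared"` merge mode the rows are restricted to compounds meeting the
#' sharing threshold, matching the enrichment input.
#'
#' @param x A `pathmeta_meta` object.
#' @param path Output TSV path.
#' @param model Optional [metabolic_model()] used to add compound names.
#' @return `path`, invisibly.
#' @export
write_metabolite_results <- function(x, path, model = NULL) {
  cmp <- x$merged$compounds
  per_study <- x$merged$per_study
  prov <- x$merged$provenance

  out <- tibble(
    compound_id = cmp$compound_id,
    compound_name = if (!is.null(model)) {
      model$compounds$name[match(cmp$compound_id, model$compounds$id)]
    } else cmp$compound_id,
    n_studies_seen = cmp$n_studies_seen,
    best_p = fmt6(cmp$best_p))
  for (uid in sort(unique(per_study$study_id))) {
    sub <- per_study[per_study$study_id == uid, , drop = FALSE]
    out[[paste0("p_", uid)]] <- fmt6(
      sub$p[match(cmp$compound_id, sub$compound_id)])
  }
  prov_by <- split(prov, prov$compound_id)
  collapse_prov <- function(field) map_chr(cmp$compound_id, function(id) {
    p <- prov_by[[id]]
    if (is.null(p)) return("")
    paste(sort(unique(p[[field]][!is.na(p[[field]])])), collapse = ";")
  })
  out$adducts <- collapse_prov("adduct")
  out$source_files <- collapse_prov("source_tag")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "pathmeta_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$studies) || length(cfg$studies) == 0) {
    abort("config must list at least one study", class = "pathmeta_config_error")
  }
  cfg
}

resolve_model <- function(spec, base_dir = ".") {
  if (is.null(spec) || identical(spec, "toy")) return(toy_metabolic_model())
  if (is.list(spec)) {
    read_metabolic_model(file.path(base_dir, spec$compounds),
                         file.path(base_dir, spec$pathways))
  } else {
    p <- if (file.exists(spec)) spec else file.path(base_dir, spec)
    read_metabolic_model(p)
  }
}

#' Run the full meta-analysis pipeline from a configuration
#'
#' Executes read -> annotate -> merge -> enrich -> adjust -> overlay ->
#' write from a configuration list (as parsed from a YAML/JSON config
#' file): `model` (path or `"toy"`), `studies` (each with `path`,
#' `dialect`, `mode`, optional `id`, `group`, `p_cutoff`, `ppm`,
#' `intensity_cutoff`, `named`), optional `genes`/`proteins` lists,
#' `merge_mode`, `min_shared`, `permutations`, `seed`, `adjust_method`,
#' and `out` directory. Writes `pathway_results.tsv`,
#' `metabolite_results.tsv` and a `run_manifest.json` echoing the
#' configuration, seed and package version.
#'
#' @param config A configuration list, or a path to a YAML/JSON file.
#' @param out Output directory (overrides the config's `out`).
#' @param verbose Log stage progress to stderr.
#' @return The `pathmeta_meta` result, invisibly.
#' @export
run_pipeline <- function(config, out = NULL, verbose = FALSE) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- read_run_config(config)
  }
  say <- function(...) if (verbose) message("[pathmeta] ", ...)

  model <- resolve_model(config$model, base_dir)
  say("model: ", nrow(model$compounds), " compounds, ",
      nrow(model$pathways), " pathways")

  find_file <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  studies <- map(config$studies, function(sc) {
    dialect <- sc$dialect %||% "generic"
    if (dialect == "xcms_diffreport") dialect <- "xcms"
    mode <- switch(sc$mode %||% "positive",
                   pos = "positive", neg = "negative", sc$mode)
    read_peaklist(find_file(sc$path), dialect = dialect, mode = mode,
                  p_cutoff = sc$p_cutoff %||% 0.05,
                  mz_tol_ppm = sc$ppm %||% 10,
                  intensity_cutoff = sc$intensity_cutoff %||% 0,
                  study_id = sc$id %||% NULL, group = sc$group %||% NULL)
  })
  say(length(studies), " studies read")

  named <- list()
  for (sc in config$studies) {
    if (!is.null(sc$named)) {
      sid <- sc$id %||% basename(sc$path)
      named[[sid]] <- read_named_metabolites(find_file(sc$named))
    }
  }

  adducts <- if (!is.null(config$adducts)) {
    read_adducts(find_file(config$adducts))
  } else default_adducts()

  seed <- as.integer(config$seed %||% 42)
  t0 <- Sys.time()
  meta <- meta_analyze(
    studies, model, named = if (length(named) > 0) named else NULL,
    adducts = adducts,
    merge_mode = config$merge_mode %||% "union",
    min_studies = config$min_studies %||% NULL,
    n_permutations = as.integer(config$permutations %||% 100),
    seed = seed,
    adjust_method = config$adjust_method %||% "empirical")
  say("meta-analysis: ", nrow(meta$results), " pathways scored in ",
      format(round(as.numeric(Sys.time() - t0, units = "secs"), 1)), "s")

  genes <- if (!is.null(config$genes)) {
    read_omics_list(find_file(config$genes), "gene")
  }
  proteins <- if (!is.null(config$proteins)) {
    read_omics_list(find_file(config$proteins), "protein")
  }
  meta <- overlay_omics(meta, model, genes = genes, proteins = proteins)

  min_shared <- config$min_shared %||% 0
  reported <- if (min_shared > 0) {
    filter_results(meta, min_shared = min_shared)
  } else meta

  out_dir <- out %||% config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pathway_results(reported, file.path(out_dir, "pathway_results.tsv"))
  write_metabolite_results(reported,
                           file.path(out_dir, "metabolite_results.tsv"),
                           model = model)
  manifest <- list(
    package = "pathmeta",
    version = as.character(utils::packageVersion("pathmeta")),
    seed = seed, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("results written to ", out_dir)
  invisible(meta)
}
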