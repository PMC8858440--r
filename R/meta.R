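#' Merge per-study compound hits with best-p selection
#'
#' Cross-study combination of annotation results: the merged reference
#' universe is the union of the per-study matched reference compounds, and
#' any compound seen significant in more than one study is merged into a
#' single record carrying the best (smallest) per-study p-value. In
#' `"union"` mode the merged significant set contains every compound
#' significant in at least one study; in `"shared"` mode it is restricted to
#' compounds significant in at least `min_studies` studies (by default, all
#' of them).
#'
#' @param indexes A list of `annotation_index` objects with distinct study
#'   ids.
#' @param merge_mode `"union"` or `"shared"`.
#' @param min_studies Minimum number of studies a compound must be
#'   significant in for `"shared"` mode (default: the number of studies).
#' @return A list with `merged_reference` (character vector),
#'   `compounds` (tibble: `compound_id`, `n_studies_seen`, `best_p`),
#'   `per_study` (long tibble of per-study best p-values), and
#'   `provenance` (every contributing feature/adduct pair with its study
#'   and source file).
#' @export
merge_studies <- function(indexes, merge_mode = c("union", "shared"),
                          min_studies = NULL) {
  merge_mode <- match.arg(merge_mode)
  ids <- map_chr(indexes, "study_id")
  if (any(duplicated(ids))) {
    abort(paste0("duplicate study id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  min_studies <- min_studies %||% length(indexes)

  merged_reference <- sort(unique(unlist(
    map(indexes, "matched_reference_compounds"))))

  per_study <- bind_rows(map(indexes, function(ix) {
    tab <- ix$matched_significant
    if (nrow(tab) == 0) return(NULL)
    tibble(compound_id = tab$compound_id, study_id = ix$study_id,
           p = tab$best_p)
  }))
  if (nrow(per_study) == 0) {
    per_study <- tibble(compound_id = character(), study_id = character(),
                        p = numeric())
  }

  compounds <- per_study |>
    group_by(.data$compound_id) |>
    summarise(n_studies_seen = dplyr::n_distinct(.data$study_id),
              best_p = if (all(is.na(.data$p))) NA_real_
              else min(.data$p, na.rm = TRUE),
              .groups = "drop") |>
    arrange(.data$compound_id)

  if (merge_mode == "shared") {
    compounds <- compounds[compounds$n_studies_seen >= min_studies, ,
                           drop = FALSE]
    if (nrow(compounds) == 0) {
      abort("no shared compounds across the studies",
            class = "pathmeta_empty_universe_error")
    }
    per_study <- per_study[per_study$compound_id %in% compounds$compound_id, ,
                           drop = FALSE]
  }

  provenance <- bind_rows(map(indexes, function(ix) {
    sig <- ix$matches[ix$matches$significant, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    tibble(compound_id = sig$compound_id, study_id = ix$study_id,
           feature_id = sig$feature_id, adduct = sig$adduct,
           source_tag = sig$source_tag, p_value = sig$p_value)
  }))
  if (nrow(provenance) == 0) {
    provenance <- tibble(compound_id = character(), study_id = character(),
                         feature_id = character(), adduct = character(),
                         source_tag = character(), p_value = numeric())
  }
  provenance <- arrange(provenance, .data$compound_id, .data$study_id,
                        .data$feature_id, .data$adduct)

  list(merged_reference = merged_reference, compounds = compounds,
       per_study = arrange(per_study, .data$compound_id, .data$study_id),
       provenance = provenance, merge_mode = merge_mode,
       min_studies = min_studies)
}

# union the annotation indexes of studies sharing a group label (several
# analytical modalities of one biological study): feature ids are
# namespaced, compound sets unioned, best p kept per compound
combine_group <- function(indexes) {
  if (length(indexes) == 1) return(indexes[[1]])
  base <- indexes[[1]]
  tag <- function(ix, v) paste0(ix$study_id, ":", v)
  matches <- bind_rows(map(indexes, function(ix) {
    m <- ix$matches
    m$feature_id <- tag(ix, m$feature_id)
    m
  }))
  ref <- bind_rows(map(indexes, function(ix) {
    r <- ix$reference_features
    r$feature_id <- tag(ix, r$feature_id)
    r
  }))
  sig_ids <- unlist(map(indexes, function(ix)
    tag(ix, ix$significant_feature_ids)))
  pseudo <- list(study_id = base$group, group = base$group,
                 mode = base$mode, params = base$params)
  build_annotation_index(pseudo, matches, ref, sort(sig_ids))
}

#' Pathway-centric meta-analysis across studies
#'
#' The full pipeline: each study is annotated against the model separately
#' (honoring its own p-value cutoff, ppm tolerance and intensity floor) and
#' scored per pathway; studies sharing a `group` label are unioned into one
#' analytical unit; compound hits are then merged across units with best-p
#' selection ([merge_studies()]); the merged sets are scored with
#' [ease_fisher_p()]; and the merged scores are validated against a
#' permutation null that resamples each unit's feature list independently
#' before merging — the null statistic follows the construction of the
#' observed one. Results are sorted by merged `p_raw`. The shared-metabolite
#' count per pathway (compounds significant in at least `min_studies`
#' units) is always reported, whichever `merge_mode` drives the enrichment.
#'
#' @param studies A list of [ms_study()] objects with distinct ids.
#' @param model A [metabolic_model()].
#' @param named Optional named list (by study id) of confirmed-metabolite
#'   tibbles from [read_named_metabolites()].
#' @param adducts Adduct rule table.
#' @param merge_mode `"union"` (default) or `"shared"`.
#' @param min_studies Sharing threshold for `"shared"` mode and for the
#'   shared-metabolite count (default: number of units).
#' @param n_permutations Permutation rounds for the null (default 100).
#' @param seed Integer seed for the permutation null (default 42).
#' @param adjust_method `"empirical"` or `"gamma"` (see [adjust_p()]).
#' @param confirmed_as Passed to [add_confirmed()].
#' @return An object of class `pathmeta_meta`; see [tidy()] and
#'   [glance()] methods, [filter_results()], [overlay_omics()],
#'   [write_pathway_results()].
#' @export
meta_analyze <- function(studies, model, named = NULL,
                         adducts = default_adducts(),
                         merge_mode = c("union", "shared"),
                         min_studies = NULL, n_permutations = 100,
                         seed = 42,
                         adjust_method = c("empirical", "gamma"),
                         confirmed_as = c("significant", "reference")) {
  merge_mode <- match.arg(merge_mode)
  adjust_method <- match.arg(adjust_method)
  confirmed_as <- match.arg(confirmed_as)
  if (length(studies) < 1) {
    abort("at least one study is required", class = "pathmeta_parameter_error")
  }
  ids <- map_chr(studies, "study_id")
  if (any(duplicated(ids))) {
    abort(paste0("duplicate study id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  # study input order must not matter: process in sorted-id order
  studies <- studies[order(ids)]

  indexes <- map(studies, function(s) {
    ix <- tryCatch(
      annotate_study(s, model, adducts),
      error = function(e) abort(
        paste0("study '", s$study_id, "': ", conditionMessage(e)),
        class = class(e)[1], parent = e))
    recs <- named[[s$study_id]]
    if (!is.null(recs)) ix <- add_confirmed(ix, recs, model, confirmed_as)
    ix
  })

  per_study_stats <- map(indexes, function(ix) {
    tryCatch(pathway_stats(ix, model),
             error = function(e) tibble())
  })
  names(per_study_stats) <- map_chr(indexes, "study_id")

  # several modalities of one biological study -> one unit
  groups <- map_chr(indexes, "group")
  units <- map(split(indexes, groups), combine_group)
  units <- units[order(names(units))]
  min_studies <- min_studies %||% length(units)

  merged <- merge_studies(units, merge_mode, min_studies)

  obs <- pathway_table(merged$merged_reference,
                       merged$compounds$compound_id, model)

  # shared-metabolite count, reported regardless of merge_mode
  seen <- merge_studies(units, "union")
  shared_ids <- seen$compounds$compound_id[
    seen$compounds$n_studies_seen >= min_studies]
  obs$shared_compound_ids <- map(
    model$pathways$compound_ids[match(obs$pathway_id, model$pathways$id)],
    intersect, shared_ids)
  obs$shared_count <- lengths(obs$shared_compound_ids)

  per_unit_hits <- map(units, function(u) {
    sig <- u$matched_significant$compound_id
    k <- map_int(model$pathways$compound_ids, function(cids)
      length(intersect(cids, sig)))
    setNames(k, model$pathways$id)
  })
  obs$per_study_hits <- map(obs$pathway_id, function(pid)
    map_int(per_unit_hits, function(h) h[[pid]]))

  null <- merged_permutation_null(units, model, merge_mode, min_studies,
                                  n_permutations, seed)
  obs$p_adjusted <- adjust_p(obs$p_raw, null, adjust_method)

  results <- obs |>
    rename(merged_hits = "hits",
           merged_hit_compound_ids = "hit_compound_ids") |>
    mutate(gene_hits = map(.data$pathway_id, function(...) character()),
           protein_hits = map(.data$pathway_id, function(...) character())) |>
    select("pathway_id", "pathway_name", "pathway_size",
           "matched_in_reference", "per_study_hits", "shared_count",
           "merged_hits", "p_raw", "p_adjusted",
           "merged_hit_compound_ids", "shared_compound_ids",
           "gene_hits", "protein_hits")

  structure(
    list(results = results, merged = merged, null = null,
         per_study = per_study_stats,
         study_ids = map_chr(indexes, "study_id"),
         unit_ids = names(units),
         params = list(merge_mode = merge_mode, min_studies = min_studies,
                       n_permutations = n_permutations, seed = seed,
                       adjust_method = adjust_method),
         model_metadata = model$metadata),
    class = "pathmeta_meta")
}

# null for the merged statistic: resample every unit independently, merge
# the pseudo-significant compound sets the same way as the observed ones
merged_permutation_null <- function(units, model, merge_mode, min_studies,
                                    n_permutations, seed) {
  if (n_permutations < 1) {
    abort("n_permutations must be >= 1", class = "pathmeta_parameter_error")
  }
  samplers <- map(units, permutation_sampler)
  merged_reference <- sort(unique(unlist(
    map(units, "matched_reference_compounds"))))
  score <- pathway_scorer(merged_reference, model)
  N <- length(merged_reference)

  values <- withr::with_seed(seed, {
    unlist(map(seq_len(n_permutations), function(b) {
      sets <- map(samplers, function(f) f())
      sig <- if (merge_mode == "shared") {
        tab <- table(unlist(map(sets, unique)))
        names(tab)[tab >= min_studies]
      } else {
        sort(unique(unlist(sets)))
      }
      score(sig, N)
    }))
  })
  structure(list(values = values, n_permutations = n_permutations,
                 seed = seed, gamma_params = NULL),
            class = "pathmeta_null")
}

#' Filter meta-analysis results for reporting
#'
#' Reproduces the reporting filters of the pathway results table: pathways
#' are kept when their shared-metabolite count (default; `count = "merged"`
#' switches to the merged hit count) reaches `min_shared` — mirroring
#' reporting rules such as "pathways with at least 10 dysregulated
#' features". Optional adduct and study filters prune the provenance of the
#' displayed compounds and recompute the displayed counts; p-values are
#' never recomputed.
#'
#' @param x A `pathmeta_meta` object.
#' @param min_shared Minimum count to keep a pathway (default 10).
#' @param count Which count to threshold: `"shared"` (default) or
#'   `"merged"`.
#' @param adduct_filter Optional character set of adduct names; compounds
#'   whose displayed provenance is emptied by the filter are pruned.
#' @param study_filter Optional character set of study ids, same semantics.
#' @return The filtered `pathmeta_meta`.
#' @export
filter_results <- function(x, min_shared = 10,
                           count = c("shared", "merged"),
                           adduct_filter = NULL, study_filter = NULL) {
  count <- match.arg(count)
  res <- x$results

  if (!is.null(adduct_filter) || !is.null(study_filter)) {
    prov <- x$merged$provenance
    if (!is.null(adduct_filter)) {
      prov <- prov[!is.na(prov$adduct) & prov$adduct %in% adduct_filter, ,
                   drop = FALSE]
    }
    if (!is.null(study_filter)) {
      prov <- prov[prov$study_id %in% study_filter, , drop = FALSE]
    }
    kept_compounds <- unique(prov$compound_id)
    res$merged_hit_compound_ids <- map(res$merged_hit_compound_ids,
                                       intersect, kept_compounds)
    res$shared_compound_ids <- map(res$shared_compound_ids,
                                   intersect, kept_compounds)
    res$merged_hits <- lengths(res$merged_hit_compound_ids)
    res$shared_count <- lengths(res$shared_compound_ids)
    x$merged$provenance <- prov
    x$merged$compounds <- x$merged$compounds[
      x$merged$compounds$compound_id %in% kept_compounds, , drop = FALSE]
  }

  keep <- if (count == "shared") res$shared_count >= min_shared
          else res$merged_hits >= min_shared
  x$results <- res[keep, , drop = FALSE]
  x
}

#' @export
print.pathmeta_meta <- function(x, ...) {
  cat("<pathmeta_meta> ", length(x$study_ids), " studies, ",
      nrow(x$results), " scored pathways\n", sep = "")
  cat("  merge mode: ", x$params$merge_mode,
      "   universe: ", length(x$merged$merged_reference), " compounds",
      "   significant: ", nrow(x$merged$compounds), " compounds\n", sep = "")
  cat("  permutations: ", x$params$n_permutations,
      " (seed ", x$params$seed, ", ", x$params$adjust_method,
      " adjustment)\n", sep = "")
  top <- head(x$results, 5)
  if (nrow(top) > 0) {
    cat("  top pathways by p_raw:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-6s %-38s k=%d/%d p=%.3g p_adj=%.3g\n",
                  top$pathway_id[i],
                  substr(top$pathway_name[i], 1, 38),
                  top$merged_hits[i], top$matched_in_reference[i],
                  top$p_raw[i], top$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' Tidy a meta-analysis result
#'
#' @param x A `pathmeta_meta` object.
#' @param ... Unused.
#' @return A tibble with one row per pathway: ids, sizes, counts, raw and
#'   adjusted p-values, and semicolon-joined compound, gene, and protein
#'   hits.
#' @export
tidy.pathmeta_meta <- function(x, ...) {
  res <- x$results
  tibble(
    pathway_id = res$pathway_id,
    pathway_name = res$pathway_name,
    pathway_size = res$pathway_size,
    matched_in_reference = res$matched_in_reference,
    shared_count = res$shared_count,
    merged_hits = res$merged_hits,
    p_raw = res$p_raw,
    p_adjusted = res$p_adjusted,
    compound_hits = map_chr(res$merged_hit_compound_ids, paste,
                            collapse = ";"),
    gene_hits_n = lengths(res$gene_hits),
    gene_hits = map_chr(res$gene_hits, paste, collapse = ";"),
    protein_hits_n = lengths(res$protein_hits),
    protein_hits = map_chr(res$protein_hits, paste, collapse = ";"))
}

#' One-row summary of a meta-analysis
#'
#' @param x A `pathmeta_meta` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of studies, analytical units, scored
#'   pathways, universe and significant-set sizes, and the permutation
#'   settings.
#' @export
glance.pathmeta_meta <- function(x, ...) {
  tibble(
    n_studies = length(x$study_ids),
    n_units = length(x$unit_ids),
    n_pathways = nrow(x$results),
    universe_size = length(x$merged$merged_reference),
    n_significant_compounds = nrow(x$merged$compounds),
    merge_mode = x$params$merge_mode,
    n_permutations = x$params$n_permutations,
    seed = x$params$seed)
}

#' Dot plot of meta-analysis pathway results
#'
#' Pathways against `-log10` adjusted p-value, point size showing the
#' shared-metabolite count and colour the merged hit count.
#'
#' @param object A `pathmeta_meta` object.
#' @param max_pathways Show at most this many top pathways (by `p_raw`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathmeta_meta <- function(object, max_pathways = 25, ...) {
  df <- head(object$results, max_pathways)
  df$pathway_name <- factor(df$pathway_name,
                            levels = rev(df$pathway_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adjusted), y = .data$pathway_name,
    size = .data$shared_count, colour = .data$merged_hits)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10]~adjusted~italic(p)),
                  y = NULL, size = "shared\nmetabolites",
                  colour = "merged\nhits") +
    ggplot2::theme_minimal()
}
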