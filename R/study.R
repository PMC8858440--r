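#' Construct a study from a feature table
#'
#' A study is one peak list — the features detected in one analysis of one
#' pairwise comparison — together with its ionization mode and the per-study
#' analysis parameters: the significance threshold applied to feature
#' p-values, the m/z tolerance used for putative annotation, and an optional
#' intensity floor.
#'
#' @param features A data frame with columns `mz` (m/z, Da) and `p_value`,
#'   and optionally `rt` (s), `intensity`, `fold_change`, `name`, and
#'   `source_tag`.
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @param study_id Study identifier; defaults to the source tag.
#' @param p_cutoff Significance threshold in (0, 1]; features with
#'   `p_value < p_cutoff` form the significant list.
#' @param mz_tol_ppm m/z tolerance (ppm, > 0) for compound matching.
#' @param intensity_cutoff Intensity floor (>= 0) defining the reference
#'   feature list; `0` keeps every feature, including those with no
#'   intensity recorded.
#' @param source_tag Input-file identity stamped on every feature so matches
#'   remain traceable; defaults to `study_id`.
#' @param group Free-form group label; studies sharing a group (e.g. several
#'   analytical modalities of one biological study) have their matched
#'   compounds unioned before cross-study merging.
#' @return An object of class `ms_study`.
#' @export
ms_study <- function(features, mode = c("positive", "negative"),
                     study_id = NULL, p_cutoff = 0.05, mz_tol_ppm = 10,
                     intensity_cutoff = 0, source_tag = NULL, group = NULL) {
  mode <- match.arg(mode)
  features <- as_tibble(features)
  if (!all(c("mz", "p_value") %in% names(features))) {
    abort("feature table needs at least columns 'mz' and 'p_value'",
          class = "pathmeta_format_error")
  }
  for (col in c("rt", "intensity", "fold_change")) {
    if (!col %in% names(features)) features[[col]] <- NA_real_
  }
  if (!"name" %in% names(features)) features$name <- NA_character_

  source_tag <- source_tag %||% study_id %||% "study"
  study_id <- study_id %||% source_tag
  if (!"source_tag" %in% names(features) || all(is.na(features$source_tag))) {
    features$source_tag <- source_tag
  }
  features$feature_id <- paste0("F", seq_len(nrow(features)))
  features <- features[, c("feature_id", "mz", "rt", "p_value", "intensity",
                           "fold_change", "name", "source_tag")]

  check_params(p_cutoff, mz_tol_ppm, intensity_cutoff)
  if (nrow(features) > 0) {
    if (any(!is.finite(features$mz) | features$mz <= 0)) {
      abort("all m/z values must be positive and finite",
            class = "pathmeta_validation_error")
    }
    bad_p <- !is.na(features$p_value) &
      (features$p_value < 0 | features$p_value > 1)
    if (any(bad_p)) {
      abort("p-values must lie in [0, 1]", class = "pathmeta_validation_error")
    }
  }

  structure(
    list(study_id = study_id, group = group %||% study_id,
         mode = mode, features = features,
         params = list(p_cutoff = p_cutoff, mz_tol_ppm = mz_tol_ppm,
                       intensity_cutoff = intensity_cutoff)),
    class = "ms_study")
}

check_params <- function(p_cutoff, mz_tol_ppm, intensity_cutoff) {
  if (!is.finite(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1) {
    abort("p_cutoff must lie in (0, 1]", class = "pathmeta_parameter_error")
  }
  if (!is.finite(mz_tol_ppm) || mz_tol_ppm <= 0) {
    abort("mz_tol_ppm must be positive", class = "pathmeta_parameter_error")
  }
  if (!is.finite(intensity_cutoff) || intensity_cutoff < 0) {
    abort("intensity_cutoff must be nonnegative",
          class = "pathmeta_parameter_error")
  }
  invisible(TRUE)
}

# column synonyms per dialect; first synonym found wins
dialect_columns <- function(dialect) {
  switch(dialect,
    generic = list(
      required = list(mz = c("mz", "m/z", "m.z"),
                      p_value = c("p_value", "pvalue", "p.value", "p")),
      optional = list(rt = c("rt", "retention_time"),
                      intensity = c("intensity", "into", "maxint"),
                      fold_change = c("fold_change", "fold", "fc"),
                      name = c("name", "metabolite_name"))),
    xcms = list(
      required = list(mz = c("mzmed", "mz"),
                      p_value = c("pvalue", "p_value", "p.value")),
      optional = list(rt = c("rtmed", "rt"),
                      intensity = c("maxint"),
                      fold_change = c("fold", "fold_change"),
                      name = c("name"))),
    workbench = list(
      required = list(mz = c("mz", "quantified_mz", "m/z"),
                      p_value = c("p_value", "pvalue", "p.value")),
      optional = list(rt = c("rt", "retention_time"),
                      intensity = c("intensity"),
                      fold_change = c("fold_change", "fold"),
                      name = c("metabolite_name", "name"))))
}

#' Read a peak list into a study
#'
#' Parses a tsv/csv peak list — the delimiter is auto-detected — under one of
#' three header dialects: `"generic"` (columns `mz`, `p_value`, optional
#' `rt`, `intensity`, `fold_change`), `"xcms"` (a diffreport: `mzmed`,
#' `rtmed`, `pvalue`, `fold`, with `maxint` or the maximum over per-sample
#' intensity columns used as the feature intensity), or `"workbench"`
#' (feature tables with `mz`, `p_value` and an optional `metabolite_name`).
#' Every feature is tagged with the input file's basename so that matches can
#' be traced back through merging and reporting.
#'
#' @param path Path to the peak list.
#' @param dialect One of `"generic"`, `"xcms"`, `"workbench"`.
#' @param mode Ionization mode of this analysis, `"positive"` or
#'   `"negative"`.
#' @param skip_bad_rows If `FALSE` (default), a non-numeric m/z or p-value is
#'   an error naming the offending line; if `TRUE` such rows are dropped with
#'   a warning.
#' @inheritParams ms_study
#' @return An [ms_study()].
#' @export
read_peaklist <- function(path, dialect = c("generic", "xcms", "workbench"),
                          mode = c("positive", "negative"),
                          p_cutoff = 0.05, mz_tol_ppm = 10,
                          intensity_cutoff = 0, study_id = NULL,
                          group = NULL, skip_bad_rows = FALSE) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(paste0("peak list not found: ", path), class = "pathmeta_io_error")
  }

  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    abort(paste0("empty peak list: ", path), class = "pathmeta_format_error")
  }
  delim <- if (stringr::str_count(first, "\t") >=
               stringr::str_count(first, ",")) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  names(raw) <- tolower(trimws(names(raw)))

  spec <- dialect_columns(dialect)
  pick <- function(synonyms) {
    hit <- intersect(synonyms, names(raw))
    if (length(hit) > 0) hit[[1]] else NA_character_
  }
  cols <- map_chr(spec$required, pick)
  if (anyNA(cols)) {
    abort(paste0("dialect '", dialect, "' requires column(s): ",
                 paste(names(cols)[is.na(cols)], collapse = ", "),
                 " (not found in ", basename(path), ")"),
          class = "pathmeta_dialect_error")
  }
  opt <- map_chr(spec$optional, pick)

  out <- tibble(
    mz = parse_numeric_column(raw[[cols[["mz"]]]], "mz", path,
                              skip = skip_bad_rows),
    p_value = parse_numeric_column(raw[[cols[["p_value"]]]], "p_value", path,
                                   skip = skip_bad_rows))
  for (col in c("rt", "intensity", "fold_change")) {
    src <- opt[[col]]
    out[[col]] <- if (!is.na(src)) {
      suppressWarnings(as.numeric(raw[[src]]))
    } else NA_real_
  }
  out$name <- if (!is.na(opt[["name"]])) raw[[opt[["name"]]]] else NA_character_

  # diffreport: no explicit intensity column -> max over per-sample columns
  if (dialect == "xcms" && all(is.na(out$intensity))) {
    known <- c(unlist(spec$required), unlist(spec$optional),
               "mzmin", "mzmax", "rtmin", "rtmax", "npeaks", "tstat",
               "anova", "qvalue", "updown", "isotopes", "adducts")
    sample_cols <- setdiff(names(raw), known)
    num <- map(raw[sample_cols], function(v) suppressWarnings(as.numeric(v)))
    num <- num[map_lgl(num, function(v) length(v) > 0 && any(!is.na(v)))]
    if (length(num) > 0) {
      mat <- do.call(cbind, num)
      out$intensity <- apply(mat, 1, function(r) {
        if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
      })
    }
  }

  bad <- which(is.na(out$mz) | is.na(out$p_value))
  if (length(bad) > 0) {
    if (!skip_bad_rows) {
      abort(paste0("non-numeric mz or p_value at line ", bad[1] + 1L,
                   " of ", basename(path)),
            class = "pathmeta_row_error")
    }
    warn(paste0("dropping ", length(bad), " unparseable row(s) from ",
                basename(path)))
    out <- out[-bad, , drop = FALSE]
  }

  ms_study(out, mode = mode, study_id = study_id %||% basename(path),
           p_cutoff = p_cutoff, mz_tol_ppm = mz_tol_ppm,
           intensity_cutoff = intensity_cutoff,
           source_tag = basename(path), group = group)
}

parse_numeric_column <- function(x, what, path, skip) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0 && !skip) {
    abort(paste0("non-numeric ", what, " at line ", bad[1] + 1L, " of ",
                 basename(path)),
          class = "pathmeta_row_error")
  }
  num
}

#' Write a study back to a generic peak list
#'
#' Emits the study's feature table as generic-dialect TSV; reading it back
#' with [read_peaklist()] reproduces the features (numeric fields to within
#' 1e-9).
#'
#' @param study An [ms_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(study, path) {
  feats <- study$features[, c("mz", "rt", "p_value", "intensity",
                              "fold_change", "name")]
  readr::write_tsv(feats, path, progress = FALSE)
  invisible(path)
}

#' Read a named-metabolite table
#'
#' Repository studies often ship tables of already-identified compounds; such
#' a metabolite enters the analysis as a *confirmed* match (see
#' [add_confirmed()]) rather than through mass-based annotation. The table
#' needs a `name` (or `id`/`compound_id`) column; `p_value` is optional.
#'
#' @param path Path to a tsv/csv table.
#' @return A tibble with columns `name`, `name_normalized` (lower-cased,
#'   whitespace-collapsed), `compound_id` (verbatim, `NA` if absent), and
#'   `p_value`.
#' @export
read_named_metabolites <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pathmeta_io_error")
  }
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (length(first) > 0 &&
               stringr::str_count(first, ",") >
               stringr::str_count(first, "\t")) "," else "\t"
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort(paste0("failed to parse ", path, ": ",
                                     conditionMessage(e)),
                              class = "pathmeta_format_error"))
  names(raw) <- tolower(trimws(names(raw)))

  name_col <- intersect(c("name", "metabolite_name", "metabolite", "compound"),
                        names(raw))
  id_col <- intersect(c("compound_id", "id"), names(raw))
  if (length(name_col) == 0 && length(id_col) == 0) {
    abort("named-metabolite table needs a 'name' (or 'compound_id') column",
          class = "pathmeta_dialect_error")
  }
  if (nrow(raw) == 0) {
    abort(paste0("no records in ", basename(path)),
          class = "pathmeta_format_error")
  }
  p_col <- intersect(c("p_value", "pvalue", "p.value", "p"), names(raw))
  nm <- if (length(name_col) > 0) as.character(raw[[name_col[[1]]]])
        else as.character(raw[[id_col[[1]]]])
  tibble(
    name = nm,
    name_normalized = normalize_name(nm),
    compound_id = if (length(id_col) > 0)
      as.character(raw[[id_col[[1]]]]) else NA_character_,
    p_value = if (length(p_col) > 0)
      suppressWarnings(as.numeric(raw[[p_col[[1]]]])) else NA_real_)
}

#' Split a study into significant and reference feature lists
#'
#' The reference list — the background of the enrichment test — contains
#' every feature passing the intensity floor; features with no recorded
#' intensity are retained when `intensity_cutoff` is 0 and dropped otherwise.
#' The significant list is the subset of the reference with
#' `p_value < p_cutoff` (strict).
#'
#' @param study An [ms_study()].
#' @return A list with tibbles `significant` and `reference`;
#'   `significant` is always a subset of `reference`.
#' @export
#' @examples
#' s <- ms_study(data.frame(mz = c(100, 200, 300),
#'                          p_value = c(0.001, 0.5, 0.01)),
#'               mode = "positive", study_id = "demo")
#' lengths(lapply(partition_significant(s), nrow))
partition_significant <- function(study) {
  check_params(study$params$p_cutoff, study$params$mz_tol_ppm,
               study$params$intensity_cutoff)
  feats <- study$features
  cutoff <- study$params$intensity_cutoff
  keep <- if (cutoff == 0) {
    rep(TRUE, nrow(feats))
  } else {
    !is.na(feats$intensity) & feats$intensity >= cutoff
  }
  reference <- feats[keep, , drop = FALSE]
  significant <- reference[!is.na(reference$p_value) &
                             reference$p_value < study$params$p_cutoff, ,
                           drop = FALSE]
  list(significant = significant, reference = reference)
}

#' @export
print.ms_study <- function(x, ...) {
  parts <- partition_significant(x)
  cat("<ms_study> ", x$study_id, " (", x$mode, " mode)\n", sep = "")
  cat("  features: ", nrow(x$features),
      "  reference: ", nrow(parts$reference),
      "  significant (p < ", format(x$params$p_cutoff), "): ",
      nrow(parts$significant), "\n", sep = "")
  cat("  mz tolerance: ", format(x$params$mz_tol_ppm), " ppm",
      "   intensity cutoff: ", format(x$params$intensity_cutoff), "\n",
      sep = "")
  invisible(x)
}
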