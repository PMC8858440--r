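#' Construct a metabolic model
#'
#' A metabolic model is the reference the annotation step queries: a compound
#' table carrying monoisotopic masses, and a pathway table whose compound sets
#' define the enrichment test, with gene-symbol and UniProt annotations used by
#' the multi-omics overlay.
#'
#' @param compounds A data frame with columns `id`, `name`,
#'   `monoisotopic_mass` (Da, positive), and optionally `aliases` (a list
#'   column of character vectors, or a character column of semicolon-joined
#'   alternative names).
#' @param pathways A data frame with columns `id`, `name`, `compound_ids`
#'   (list column or semicolon-joined character), and optionally
#'   `gene_symbols` and `uniprot_ids` in either form.
#' @param metadata A named list of free-form model metadata (e.g. `name`,
#'   `version`).
#'
#' @return An object of class `metabolic_model`, a list with tibbles
#'   `compounds` and `pathways` plus `metadata`. Aliases are normalized to
#'   lower case with collapsed whitespace; referential integrity between the
#'   two tables is enforced.
#' @export
#' @examples
#' m <- metabolic_model(
#'   compounds = data.frame(
#'     id = c("glc", "pyr"), name = c("glucose", "pyruvate"),
#'     monoisotopic_mass = c(180.063388, 88.016044)
#'   ),
#'   pathways = data.frame(
#'     id = "gly", name = "glycolysis", compound_ids = "glc;pyr"
#'   )
#' )
#' m
metabolic_model <- function(compounds, pathways, metadata = list()) {
  compounds <- as_tibble(compounds)
  pathways <- as_tibble(pathways)

  required_c <- c("id", "name", "monoisotopic_mass")
  missing_c <- setdiff(required_c, names(compounds))
  if (length(missing_c) > 0) {
    abort(paste0("compound table lacks column(s): ",
                 paste(missing_c, collapse = ", ")),
          class = "pathmeta_format_error")
  }
  required_p <- c("id", "name", "compound_ids")
  missing_p <- setdiff(required_p, names(pathways))
  if (length(missing_p) > 0) {
    abort(paste0("pathway table lacks column(s): ",
                 paste(missing_p, collapse = ", ")),
          class = "pathmeta_format_error")
  }

  compounds$id <- as.character(compounds$id)
  compounds$name <- as.character(compounds$name)
  compounds$monoisotopic_mass <- as.numeric(compounds$monoisotopic_mass)
  compounds$aliases <- as_set_column(
    if ("aliases" %in% names(compounds)) compounds$aliases else
      vector("list", nrow(compounds)))
  compounds$aliases <- map(compounds$aliases, normalize_name)

  pathways$id <- as.character(pathways$id)
  pathways$name <- as.character(pathways$name)
  pathways$compound_ids <- as_set_column(pathways$compound_ids)
  pathways$gene_symbols <- as_set_column(
    if ("gene_symbols" %in% names(pathways)) pathways$gene_symbols else
      vector("list", nrow(pathways)))
  pathways$uniprot_ids <- as_set_column(
    if ("uniprot_ids" %in% names(pathways)) pathways$uniprot_ids else
      vector("list", nrow(pathways)))

  model <- structure(
    list(compounds = compounds[, c("id", "name", "monoisotopic_mass", "aliases")],
         pathways = pathways[, c("id", "name", "compound_ids",
                                 "gene_symbols", "uniprot_ids")],
         metadata = metadata),
    class = "metabolic_model")
  validate_metabolic_model(model)
}

# accept list columns or semicolon-joined strings; always return a list of
# sorted unique character vectors
as_set_column <- function(x) {
  if (is.null(x)) return(list())
  if (!is.list(x)) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x <- strsplit(x, ";", fixed = TRUE)
  }
  map(x, function(v) {
    v <- trimws(as.character(v))
    sort(unique(v[nzchar(v)]))
  })
}

#' Validate a metabolic model
#'
#' Checks the invariants a usable model must satisfy: positive monoisotopic
#' masses, unique compound and pathway ids, at least one pathway, nonempty
#' pathway compound sets, and referential integrity (every compound id cited
#' by a pathway resolves in the compound table).
#'
#' @param model A [metabolic_model()] object.
#' @return The model, invisibly unchanged, if valid; otherwise an error of
#'   class `pathmeta_validation_error` listing the offending ids.
#' @export
validate_metabolic_model <- function(model) {
  cmp <- model$compounds
  pw <- model$pathways

  if (any(duplicated(cmp$id))) {
    abort(paste0("duplicate compound id(s): ",
                 paste(unique(cmp$id[duplicated(cmp$id)]), collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  bad_mass <- cmp$id[!is.finite(cmp$monoisotopic_mass) | cmp$monoisotopic_mass <= 0]
  if (length(bad_mass) > 0) {
    abort(paste0("nonpositive monoisotopic mass for compound(s): ",
                 paste(bad_mass, collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  if (nrow(pw) == 0) {
    abort("model must contain at least one pathway",
          class = "pathmeta_validation_error")
  }
  if (any(duplicated(pw$id))) {
    abort(paste0("duplicate pathway id(s): ",
                 paste(unique(pw$id[duplicated(pw$id)]), collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  empty <- pw$id[map_int(pw$compound_ids, length) == 0]
  if (length(empty) > 0) {
    abort(paste0("pathway(s) with empty compound set: ",
                 paste(empty, collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  dangling <- setdiff(unique(unlist(pw$compound_ids)), cmp$id)
  if (length(dangling) > 0) {
    abort(paste0("pathway(s) reference unknown compound id(s): ",
                 paste(sort(dangling), collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  invisible(model)
}

#' Read a metabolic model from disk
#'
#' Two plain-text formats are supported: a single JSON document
#' (`{"metadata": ..., "compounds": [...], "pathways": [...]}`), or a TSV
#' pair — a compound table (`id`, `name`, `monoisotopic_mass`, `aliases`
#' semicolon-joined) plus a pathway table (`id`, `name`, `compound_ids`,
#' `gene_symbols`, `uniprot_ids` semicolon-joined).
#'
#' @param path Path to the JSON model, or to the compounds TSV when
#'   `pathways_path` is given.
#' @param pathways_path Path to the pathways TSV (TSV-pair format only).
#' @param format `"auto"` (by extension), `"json"`, or `"tsv"`.
#' @return A validated [metabolic_model()].
#' @export
read_metabolic_model <- function(path, pathways_path = NULL,
                                 format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "pathmeta_io_error")
  }
  if (format == "auto") {
    format <- if (!is.null(pathways_path)) "tsv"
              else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }

  if (format == "json") {
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = TRUE),
      error = function(e) abort(
        paste0("failed to parse model file '", path, "': ",
               conditionMessage(e)),
        class = "pathmeta_format_error"))
    for (fld in c("compounds", "pathways")) {
      if (is.null(parsed[[fld]])) {
        abort(paste0("model file '", path, "' lacks a '", fld, "' array"),
              class = "pathmeta_format_error")
      }
    }
    metabolic_model(as_tibble(parsed$compounds), as_tibble(parsed$pathways),
                    metadata = as.list(parsed$metadata))
  } else {
    if (is.null(pathways_path)) {
      abort("TSV-pair format needs both a compounds and a pathways file",
            class = "pathmeta_format_error")
    }
    if (!file.exists(pathways_path)) {
      abort(paste0("model file not found: ", pathways_path),
            class = "pathmeta_io_error")
    }
    cmp <- read_model_tsv(path)
    pw <- read_model_tsv(pathways_path)
    metabolic_model(cmp, pw,
                    metadata = list(source = basename(path)))
  }
}

read_model_tsv <- function(path) {
  out <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(
      paste0("failed to parse model file '", path, "': ",
             conditionMessage(e)),
      class = "pathmeta_format_error"))
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(paste0("failed to parse model file '", path, "' at line ",
                 prob$row[1] + 1L, ": ", prob$expected[1], " expected"),
          class = "pathmeta_format_error")
  }
  out
}

#' Write a metabolic model to disk
#'
#' Inverse of [read_metabolic_model()]: emits either the single-file JSON
#' schema or the TSV pair, such that reading the result back yields an equal
#' model field by field.
#'
#' @param model A [metabolic_model()].
#' @param path Output path (JSON file, or compounds TSV).
#' @param pathways_path Pathways TSV path (TSV-pair format only).
#' @param format `"auto"`, `"json"` or `"tsv"` as in [read_metabolic_model()].
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path, pathways_path = NULL,
                                  format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (!is.null(pathways_path)) "tsv"
              else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  if (format == "json") {
    payload <- list(
      metadata = model$metadata,
      compounds = model$compounds,
      pathways = model$pathways)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (is.null(pathways_path)) {
      abort("TSV-pair format needs both a compounds and a pathways path",
            class = "pathmeta_format_error")
    }
    cmp <- model$compounds
    cmp$aliases <- map_chr(cmp$aliases, paste, collapse = ";")
    readr::write_tsv(cmp, path, progress = FALSE)
    pw <- model$pathways
    for (col in c("compound_ids", "gene_symbols", "uniprot_ids")) {
      pw[[col]] <- map_chr(pw[[col]], paste, collapse = ";")
    }
    readr::write_tsv(pw, pathways_path, progress = FALSE)
  }
  invisible(path)
}

#' Look up compounds by id, name, or alias
#'
#' Names and aliases are compared after lower-casing and whitespace collapse,
#' the same normalization applied when the model is built.
#'
#' @param model A [metabolic_model()].
#' @param x Character vector of compound ids, names, or aliases.
#' @return A character vector the length of `x`: the resolved compound id, or
#'   `NA` where nothing matched.
#' @export
resolve_compounds <- function(model, x) {
  cmp <- model$compounds
  norm <- normalize_name(cmp$name)
  alias_tab <- tibble(
    key = unlist(cmp$aliases),
    id = rep(cmp$id, map_int(cmp$aliases, length)))
  vapply(as.character(x), function(q) {
    if (q %in% cmp$id) return(q)
    nq <- normalize_name(q)
    hit <- cmp$id[norm == nq]
    if (length(hit) > 0) return(hit[[1]])
    hit <- alias_tab$id[alias_tab$key == nq]
    if (length(hit) > 0) return(hit[[1]])
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  nm <- x$metadata$name %||% "unnamed"
  cat("<metabolic_model> ", nm, "\n", sep = "")
  cat("  compounds: ", nrow(x$compounds),
      "  (mass range ", format(min(x$compounds$monoisotopic_mass)), " - ",
      format(max(x$compounds$monoisotopic_mass)), " Da)\n", sep = "")
  cat("  pathways:  ", nrow(x$pathways), "\n", sep = "")
  invisible(x)
}
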