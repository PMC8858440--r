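#' Parse a dysregulated gene or protein list
#'
#' Reads one identifier per line (or the first column of a single-column
#' table; a lone header such as `gene_symbol` is recognised and dropped)
#' and normalizes: gene symbols and loci are upper-cased; UniProt
#' accessions are upper-cased with any isoform suffix (`-1`, `-2`, ...)
#' stripped. Duplicates and blank lines are removed; the raw line count is
#' kept for logging. The lists are expected to arrive pre-filtered — the
#' differential-expression thresholds are the uploader's business.
#'
#' @param path Path to the list file.
#' @param kind `"gene"` or `"protein"`.
#' @return An object of class `omics_list`: `kind`, `identifiers` (sorted
#'   unique character vector), `n_input`.
#' @export
read_omics_list <- function(path, kind = c("gene", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("omics list not found: ", path), class = "pathmeta_io_error")
  }
  lines <- readr::read_lines(path)
  # single-column table: take the first field of each line
  lines <- trimws(vapply(strsplit(lines, "[\t,]"), function(x)
    if (length(x) > 0) x[[1]] else "", character(1)))
  lines <- lines[nzchar(lines)]
  header_words <- c("gene", "genes", "gene_symbol", "gene_id", "symbol",
                    "id", "identifier", "locus", "protein", "protein_id",
                    "uniprot", "uniprot_id", "accession")
  if (length(lines) > 1 && tolower(lines[[1]]) %in% header_words) {
    lines <- lines[-1]
  }
  n_input <- length(lines)
  ids <- toupper(lines)
  if (kind == "protein") {
    ids <- sub("-[0-9]+$", "", ids)
  }
  ids <- sort(unique(ids))
  if (length(ids) == 0) {
    abort(paste0("no identifiers parsed from ", basename(path)),
          class = "pathmeta_format_error")
  }
  structure(list(kind = kind, identifiers = ids, n_input = n_input),
            class = "omics_list")
}

#' @export
print.omics_list <- function(x, ...) {
  cat("<omics_list> ", x$kind, ": ", length(x$identifiers),
      " unique identifiers (", x$n_input, " input lines)\n", sep = "")
  invisible(x)
}

#' Superimpose dysregulated gene and protein lists on pathway results
#'
#' Annotation-only multi-omics overlay: for each pathway, the gene hits are
#' the intersection of the pathway's gene symbols with the uploaded gene
#' list, and the protein hits the intersection of its UniProt accessions
#' with the protein list. When a pathway carries no UniProt annotation, the
#' protein list is matched against the pathway's gene symbols instead
#' (protein lists may be supplied as gene symbols). The metabolite-level
#' statistics — p-values, hit counts, ordering — are never altered; the
#' overlay offers a systems-level glance, not a joint test.
#'
#' @param x A `pathmeta_meta` object.
#' @param model The [metabolic_model()] used for the analysis.
#' @param genes Optional `omics_list` of kind `"gene"`.
#' @param proteins Optional `omics_list` of kind `"protein"`.
#' @return The `pathmeta_meta` with `gene_hits` and `protein_hits` filled.
#' @export
overlay_omics <- function(x, model, genes = NULL, proteins = NULL) {
  if (is.null(genes) && is.null(proteins)) return(x)
  res <- x$results
  pw <- model$pathways
  pos <- match(res$pathway_id, pw$id)

  if (!is.null(genes)) {
    res$gene_hits <- map(pos, function(i)
      sort(intersect(toupper(pw$gene_symbols[[i]]), genes$identifiers)))
  }
  if (!is.null(proteins)) {
    res$protein_hits <- map(pos, function(i) {
      acc <- toupper(pw$uniprot_ids[[i]])
      if (length(acc) == 0) {
        # model lacks UniProt annotation here: gene-symbol fallback
        sort(intersect(toupper(pw$gene_symbols[[i]]), proteins$identifiers))
      } else {
        sort(intersect(acc, proteins$identifiers))
      }
    })
  }
  x$results <- res
  x
}
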