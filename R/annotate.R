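#' Default adduct rule table
#'
#' The adduct forms enumerated on every feature mass during putative
#' annotation. Each rule turns an observed m/z into a candidate neutral
#' monoisotopic mass via `M = (mz * |charge| - mass_shift) / mol_multiplier`
#' (the `n` in `nM` cluster ions). The default table covers the common
#' electrospray species: positive mode M+H, M+Na, M+K, M+NH4, M+H-H2O and
#' the 2M+H dimer; negative mode M-H, M+Cl, M-H-H2O and 2M-H. Mass shifts
#' are ion masses (electron mass included).
#'
#' @return A tibble with columns `adduct`, `mass_shift` (Da), `charge`,
#'   `mol_multiplier`, `mode`.
#' @export
#' @examples
#' default_adducts()
default_adducts <- function() {
  tibble::tribble(
    ~adduct,    ~mass_shift, ~charge, ~mol_multiplier, ~mode,
    "M+H",        1.007276,   1L, 1L, "positive",
    "M+Na",      22.989218,   1L, 1L, "positive",
    "M+K",       38.963158,   1L, 1L, "positive",
    "M+NH4",     18.033823,   1L, 1L, "positive",
    "M+H-H2O",  -17.003289,   1L, 1L, "positive",
    "2M+H",       1.007276,   1L, 2L, "positive",
    "M-H",       -1.007276,  -1L, 1L, "negative",
    "M+Cl",      34.969402,  -1L, 1L, "negative",
    "M-H-H2O",  -19.017841,  -1L, 1L, "negative",
    "2M-H",      -1.007276,  -1L, 2L, "negative"
  )
}

#' Read a user adduct table
#'
#' A TSV with columns `adduct` (or `name`), `mass_shift`, `charge`,
#' `mol_multiplier`, `mode` replacing [default_adducts()].
#'
#' @param path Path to the table.
#' @return A validated adduct tibble.
#' @export
read_adducts <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("adduct table not found: ", path),
          class = "pathmeta_io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  if ("name" %in% names(tab) && !"adduct" %in% names(tab)) {
    tab <- rename(tab, adduct = "name")
  }
  need <- c("adduct", "mass_shift", "charge", "mol_multiplier", "mode")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("adduct table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pathmeta_format_error")
  }
  validate_adducts(tab[need])
}

validate_adducts <- function(adducts) {
  adducts <- as_tibble(adducts)
  adducts$charge <- as.integer(adducts$charge)
  adducts$mol_multiplier <- as.integer(adducts$mol_multiplier)
  if (any(adducts$charge == 0L) || any(adducts$mol_multiplier < 1L)) {
    abort("adduct rules need nonzero charge and mol_multiplier >= 1",
          class = "pathmeta_validation_error")
  }
  bad_sign <- (adducts$mode == "positive" & adducts$charge < 0) |
    (adducts$mode == "negative" & adducts$charge > 0)
  if (any(bad_sign)) {
    abort(paste0("charge sign inconsistent with mode for: ",
                 paste(adducts$adduct[bad_sign], collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  adducts
}

#' Neutral mass from an observed m/z under an adduct rule
#'
#' `M = (mz * |charge| - mass_shift) / mol_multiplier`. Vectorized over all
#' arguments.
#'
#' @param mz Observed m/z (Da).
#' @param mass_shift Signed ion mass shift (Da).
#' @param charge Ion charge (sign carries the polarity; only its magnitude
#'   enters the arithmetic).
#' @param mol_multiplier Number of molecules in the ion (`n` in `nM`).
#' @return Candidate neutral monoisotopic mass in Da (may be nonpositive, in
#'   which case the candidate should be discarded).
#' @seealso [adduct_mz()] for the inverse transform.
#' @export
#' @examples
#' neutral_mass(181.070664, 1.007276, 1, 1) # glucose via M+H
neutral_mass <- function(mz, mass_shift, charge = 1L, mol_multiplier = 1L) {
  (mz * abs(charge) - mass_shift) / mol_multiplier
}

#' Observed m/z of a neutral mass under an adduct rule
#'
#' Inverse of [neutral_mass()]: `mz = (M * mol_multiplier + mass_shift) /
#' |charge|`.
#'
#' @param m Neutral monoisotopic mass (Da).
#' @inheritParams neutral_mass
#' @return The m/z at which the ion would be observed.
#' @export
adduct_mz <- function(m, mass_shift, charge = 1L, mol_multiplier = 1L) {
  (m * mol_multiplier + mass_shift) / abs(charge)
}

#' Enumerate candidate neutral masses for one m/z
#'
#' Applies every adduct rule of the requested mode to an observed m/z and
#' keeps the candidates with a positive inferred neutral mass, in rule-table
#' order.
#'
#' @param mz A single observed m/z (Da).
#' @param mode Ionization mode.
#' @param adducts Adduct rule table, by default [default_adducts()].
#' @return A tibble with columns `adduct` and `neutral_mass`.
#' @export
#' @examples
#' enumerate_adducts(181.070664, "positive")
enumerate_adducts <- function(mz, mode = c("positive", "negative"),
                              adducts = default_adducts()) {
  mode <- match.arg(mode)
  rules <- validate_adducts(adducts)
  rules <- rules[rules$mode == mode, , drop = FALSE]
  if (nrow(rules) == 0) {
    abort(paste0("no adduct rules defined for ", mode, " mode"),
          class = "pathmeta_config_error")
  }
  out <- tibble(
    adduct = rules$adduct,
    neutral_mass = neutral_mass(mz, rules$mass_shift, rules$charge,
                                rules$mol_multiplier))
  out[out$neutral_mass > 0, , drop = FALSE]
}

#' Annotate a study against a metabolic model
#'
#' The putative-annotation step: every reference feature is expanded under
#' the mode-appropriate adduct rules and each candidate neutral mass is
#' matched against the model's compound masses; a feature matches a compound
#' when the relative error `|M_inferred - mass| / mass * 1e6` is within the
#' study's ppm tolerance. Each match records its adduct, inferred neutral
#' mass, signed ppm error, and the source file of the feature. A compound
#' hit by several features or adducts appears once in the compound sets,
#' retaining the smallest significant-feature p-value.
#'
#' @param study An [ms_study()].
#' @param model A [metabolic_model()].
#' @param adducts Adduct rule table.
#' @return An `annotation_index`: a list with the study's identity and
#'   parameters, the `matches` tibble, the reference feature table, the
#'   matched reference compound ids, and the significant compound set with
#'   best p-values.
#' @export
annotate_study <- function(study, model, adducts = default_adducts()) {
  parts <- partition_significant(study)
  ref <- parts$reference
  sig_ids <- parts$significant$feature_id

  rules <- validate_adducts(adducts)
  rules <- rules[rules$mode == study$mode, , drop = FALSE]
  if (nrow(rules) == 0) {
    abort(paste0("no adduct rules defined for ", study$mode, " mode"),
          class = "pathmeta_config_error")
  }

  masses <- model$compounds$monoisotopic_mass
  ord <- order(masses)
  sorted_mass <- masses[ord]
  sorted_id <- model$compounds$id[ord]
  tol <- study$params$mz_tol_ppm

  match_list <- vector("list", nrow(rules))
  for (r in seq_len(nrow(rules))) {
    m_cand <- neutral_mass(ref$mz, rules$mass_shift[r], rules$charge[r],
                           rules$mol_multiplier[r])
    ok <- which(m_cand > 0)
    if (length(ok) == 0) next
    # window on sorted compound masses; tolerance is relative to the
    # compound (model) mass: mass in [M/(1+tol), M/(1-tol)]. The window is
    # opened by 1e-9 relative and the exact ppm criterion applied below, so
    # the result is identical to a direct |ppm| <= tol scan.
    t_rel <- tol * 1e-6
    lo <- findInterval(m_cand[ok] / (1 + t_rel) * (1 - 1e-9), sorted_mass,
                       left.open = TRUE) + 1L
    hi <- findInterval(m_cand[ok] / (1 - t_rel) * (1 + 1e-9), sorted_mass)
    n_hit <- pmax(hi - lo + 1L, 0L)
    if (all(n_hit == 0L)) next
    idx <- which(n_hit > 0L)
    feat_rep <- rep(ok[idx], n_hit[idx])
    cmp_pos <- unlist(map2(lo[idx], hi[idx], seq.int))
    match_list[[r]] <- tibble(
      feature_id = ref$feature_id[feat_rep],
      compound_id = sorted_id[cmp_pos],
      adduct = rules$adduct[r],
      inferred_neutral_mass = m_cand[ok][rep(idx, n_hit[idx])],
      compound_mass = sorted_mass[cmp_pos])
  }
  matches <- bind_rows(match_list)
  if (nrow(matches) == 0) {
    matches <- tibble(feature_id = character(), compound_id = character(),
                      adduct = character(),
                      inferred_neutral_mass = numeric(),
                      compound_mass = numeric())
  }
  matches$ppm_error <- (matches$inferred_neutral_mass -
                          matches$compound_mass) /
    matches$compound_mass * 1e6
  matches <- matches[abs(matches$ppm_error) <= tol, , drop = FALSE]
  matches$confirmed <- rep(FALSE, nrow(matches))
  matches <- left_join(matches,
                       ref[, c("feature_id", "mz", "p_value", "source_tag")],
                       by = "feature_id")
  matches$significant <- matches$feature_id %in% sig_ids
  matches$compound_mass <- NULL

  build_annotation_index(study, matches, ref, sig_ids)
}

build_annotation_index <- function(study, matches, ref, sig_ids) {
  ref_compounds <- sort(unique(matches$compound_id))
  sig_matches <- matches[matches$significant, , drop = FALSE]
  sig_best <- if (nrow(sig_matches) > 0) {
    sig_matches |>
      group_by(.data$compound_id) |>
      summarise(best_p = if (all(is.na(.data$p_value))) NA_real_
                else min(.data$p_value, na.rm = TRUE),
                .groups = "drop") |>
      arrange(.data$compound_id)
  } else {
    tibble(compound_id = character(), best_p = numeric())
  }

  structure(
    list(study_id = study$study_id, group = study$group, mode = study$mode,
         params = study$params,
         matches = matches,
         reference_features = ref[, c("feature_id", "p_value", "source_tag")],
         significant_feature_ids = sort(sig_ids),
         matched_reference_compounds = ref_compounds,
         matched_significant = sig_best),
    class = "annotation_index")
}

#' Attach confirmed metabolites to an annotation index
#'
#' An already-identified metabolite from a repository study bypasses
#' mass-based matching: each record is resolved against the model by
#' compound id, normalized name, or alias, and added as a confirmed match.
#' Confirmed compounds always join the reference universe; they join the
#' significant set when their p-value is below the study's cutoff, or when
#' they carry no p-value and `confirmed_as = "significant"` (the default —
#' an archived identification is treated as a reported dysregulation).
#' Records that resolve to nothing are reported in a warning, never an
#' error.
#'
#' @param index An `annotation_index` from [annotate_study()].
#' @param records A named-metabolite tibble from [read_named_metabolites()].
#' @param model The [metabolic_model()] the index was built against.
#' @param confirmed_as How to treat confirmed records lacking a p-value:
#'   `"significant"` or `"reference"`.
#' @return The updated `annotation_index`.
#' @export
add_confirmed <- function(index, records, model,
                          confirmed_as = c("significant", "reference")) {
  confirmed_as <- match.arg(confirmed_as)
  if (nrow(records) == 0) return(index)

  resolved <- ifelse(!is.na(records$compound_id) &
                       records$compound_id %in% model$compounds$id,
                     records$compound_id,
                     resolve_compounds(model, records$name))
  unmatched <- records$name[is.na(resolved)]
  if (length(unmatched) > 0) {
    warn(paste0("confirmed metabolite(s) not in model: ",
                paste(unique(unmatched), collapse = ", ")))
  }
  keep <- !is.na(resolved)
  if (!any(keep)) return(index)
  records <- records[keep, , drop = FALSE]
  resolved <- resolved[keep]

  p <- records$p_value
  cutoff <- index$params$p_cutoff
  sig <- (!is.na(p) & p < cutoff) |
    (is.na(p) & confirmed_as == "significant")
  fid <- paste0("confirmed:", records$name_normalized)

  new_matches <- tibble(
    feature_id = fid, compound_id = resolved,
    adduct = NA_character_, inferred_neutral_mass = NA_real_,
    ppm_error = NA_real_, confirmed = TRUE,
    mz = NA_real_, p_value = p, source_tag = "confirmed",
    significant = sig)
  matches <- bind_rows(index$matches, new_matches)
  ref <- bind_rows(index$reference_features,
                   tibble(feature_id = fid, p_value = p,
                          source_tag = "confirmed"))
  ref <- distinct(ref, .data$feature_id, .keep_all = TRUE)
  sig_ids <- union(index$significant_feature_ids, fid[sig])

  pseudo_study <- list(study_id = index$study_id, group = index$group,
                       mode = index$mode, params = index$params)
  build_annotation_index(pseudo_study, matches, ref, sig_ids)
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("<annotation_index> study ", x$study_id, " (", x$mode, " mode)\n",
      sep = "")
  cat("  matches: ", nrow(x$matches),
      "  reference compounds: ", length(x$matched_reference_compounds),
      "  significant compounds: ", nrow(x$matched_significant), "\n",
      sep = "")
  invisible(x)
}
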