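#' Describe the ground truth of a synthetic study
#'
#' The generator's contract: which pathways are enriched, how strong the
#' enrichment is, and how noisy the measurements are. Features of enriched
#' pathway compounds get p-values from `Beta(effect, 1)` — the standard
#' one-parameter alternative; `effect` well below 1 concentrates p near 0
#' (with the default 0.05, about 86% of enriched features fall under a
#' 0.05 cutoff). Background features carry uniform p-values, and a
#' fraction of decoy features have m/z drawn uniformly over the model's
#' mass range so that false matches arise only through the tolerance
#' window.
#'
#' @param enriched_pathway_ids Character vector of enriched pathway ids;
#'   empty for a null-mode study with no enrichment.
#' @param effect Beta shape `a` for enriched p-values (> 0; smaller is a
#'   stronger effect). Default 0.05.
#' @param n_background Number of background features drawn from
#'   non-enriched model compounds. Default 100.
#' @param frac_decoy Fraction (of `n_background`) of decoy features with
#'   random m/z. Default 0.2.
#' @param ppm_jitter_sd Gaussian mass-error standard deviation in ppm
#'   applied to real-compound features. Default 2.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(enriched_pathway_ids = character(),
                            effect = 0.05, n_background = 100,
                            frac_decoy = 0.2, ppm_jitter_sd = 2) {
  if (!is.finite(effect) || effect <= 0) {
    abort("effect (Beta shape) must be > 0",
          class = "pathmeta_parameter_error")
  }
  if (!is.finite(frac_decoy) || frac_decoy < 0 || frac_decoy > 1) {
    abort("frac_decoy must lie in [0, 1]", class = "pathmeta_parameter_error")
  }
  if (n_background < 0) {
    abort("n_background must be nonnegative",
          class = "pathmeta_parameter_error")
  }
  structure(list(enriched_pathway_ids = sort(unique(enriched_pathway_ids)),
                 effect = effect, n_background = as.integer(n_background),
                 frac_decoy = frac_decoy, ppm_jitter_sd = ppm_jitter_sd),
            class = "synthetic_truth")
}

#' Generate one synthetic study from a metabolic model
#'
#' Builds a peak list with known enrichment: one feature per compound of
#' each enriched pathway (m/z from a randomly chosen mode-appropriate
#' adduct rule plus Gaussian ppm jitter, p from `Beta(effect, 1)`),
#' `n_background` features from random non-enriched compounds with uniform
#' p, and `floor(frac_decoy * n_background)` decoy features with m/z
#' uniform over the model's compound-mass range. Output is fully
#' deterministic given the seed.
#'
#' @param model A [metabolic_model()].
#' @param truth A [synthetic_truth()].
#' @param mode Ionization mode of the simulated analysis.
#' @param seed Integer seed.
#' @param study_id Study identifier.
#' @param adducts Adduct rule table used for the forward mass transform.
#' @inheritParams ms_study
#' @return An [ms_study()] with the truth stored in
#'   `attr(study, "truth")`.
#' @export
simulate_study <- function(model, truth, mode = c("positive", "negative"),
                           seed = 1, study_id = "synthetic",
                           adducts = default_adducts(), p_cutoff = 0.05,
                           mz_tol_ppm = 10, intensity_cutoff = 0,
                           group = NULL) {
  mode <- match.arg(mode)
  missing_pw <- setdiff(truth$enriched_pathway_ids, model$pathways$id)
  if (length(missing_pw) > 0) {
    abort(paste0("enriched pathway id(s) absent from model: ",
                 paste(missing_pw, collapse = ", ")),
          class = "pathmeta_validation_error")
  }
  rules <- validate_adducts(adducts)
  rules <- rules[rules$mode == mode, , drop = FALSE]
  if (nrow(rules) == 0) {
    abort(paste0("no adduct rules defined for ", mode, " mode"),
          class = "pathmeta_config_error")
  }

  cmp <- model$compounds
  enriched_ids <- sort(unique(unlist(
    model$pathways$compound_ids[model$pathways$id %in%
                                  truth$enriched_pathway_ids])))
  background_pool <- setdiff(cmp$id, enriched_ids)
  mass_of <- setNames(cmp$monoisotopic_mass, cmp$id)
  mass_range <- range(cmp$monoisotopic_mass)
  n_decoy <- as.integer(floor(truth$frac_decoy * truth$n_background))

  feats <- withr::with_seed(seed, {
    spike_mz <- function(compound_ids) {
      r <- sample.int(nrow(rules), length(compound_ids), replace = TRUE)
      true_mz <- adduct_mz(mass_of[compound_ids], rules$mass_shift[r],
                           rules$charge[r], rules$mol_multiplier[r])
      true_mz * (1 + rnorm(length(true_mz), 0, truth$ppm_jitter_sd) * 1e-6)
    }
    enriched <- tibble(
      mz = if (length(enriched_ids) > 0) spike_mz(enriched_ids)
           else numeric(),
      p_value = rbeta(length(enriched_ids), truth$effect, 1))
    bg_ids <- if (truth$n_background > 0 && length(background_pool) > 0) {
      sample(background_pool, truth$n_background, replace = TRUE)
    } else character()
    background <- tibble(
      mz = if (length(bg_ids) > 0) spike_mz(bg_ids) else numeric(),
      p_value = runif(length(bg_ids)))
    decoy <- tibble(
      mz = runif(n_decoy, mass_range[1], mass_range[2]),
      p_value = runif(n_decoy))
    out <- bind_rows(enriched, background, decoy)
    out$rt <- runif(nrow(out), 30, 900)
    out$intensity <- rlnorm(nrow(out), meanlog = 12, sdlog = 1)
    out
  })

  study <- ms_study(feats, mode = mode, study_id = study_id,
                    p_cutoff = p_cutoff, mz_tol_ppm = mz_tol_ppm,
                    intensity_cutoff = intensity_cutoff,
                    source_tag = study_id, group = group)
  attr(study, "truth") <- truth
  study
}

#' Generate a set of synthetic studies sharing the same biology
#'
#' Emulates independent studies of one biological question: each study is
#' generated by [simulate_study()] with the same truth (the same enriched
#' pathways) but a distinct derived seed (`base_seed + i`), so feature
#' lists differ while the spiked enrichment is shared.
#'
#' @param model A [metabolic_model()].
#' @param truth A [synthetic_truth()].
#' @param n_studies Number of studies (>= 2).
#' @param base_seed Base integer seed; study `i` uses `base_seed + i`.
#' @inheritParams simulate_study
#' @return A list of [ms_study()] objects with ids `"study1"`, `"study2"`,
#'   ...
#' @export
simulate_meta_set <- function(model, truth, n_studies = 2, base_seed = 1,
                              mode = c("positive", "negative"),
                              adducts = default_adducts(), p_cutoff = 0.05,
                              mz_tol_ppm = 10, intensity_cutoff = 0) {
  if (n_studies < 2) {
    abort("a meta set needs at least 2 studies",
          class = "pathmeta_parameter_error")
  }
  mode <- match.arg(mode)
  map(seq_len(n_studies), function(i) {
    simulate_study(model, truth, mode = mode, seed = base_seed + i,
                   study_id = paste0("study", i), adducts = adducts,
                   p_cutoff = p_cutoff, mz_tol_ppm = mz_tol_ppm,
                   intensity_cutoff = intensity_cutoff)
  })
}
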