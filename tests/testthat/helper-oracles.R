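# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: tail probabilities come from explicit binomial
# sums, and the matcher oracle is a plain triple scan.

# P(X >= kp) for X ~ Hypergeometric(N, m, n), by explicit enumeration
hyper_tail_oracle <- function(kp, m, n, N) {
  hi <- min(m, n)
  if (kp > hi) return(0)
  if (kp <= max(0, m + n - N)) return(1)
  i <- kp:hi
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# the EASE decrement applied to the oracle tail
ease_oracle <- function(k, m, n, N) {
  kp <- max(k - 1, 0)
  if (kp == 0) return(1)
  hyper_tail_oracle(kp, m, n, N)
}

# all EASE values for one (N, m, n) at k = 0..min(m, n), via a reverse
# cumulative sum of the enumerated pmf
ease_oracle_all_k <- function(m, n, N) {
  hi <- min(m, n)
  lo <- max(0, m + n - N)
  pmf <- rep(0, hi + 1)
  i <- lo:hi
  pmf[i + 1] <- choose(m, i) * choose(N - m, n - i) / choose(N, n)
  tails <- rev(cumsum(rev(pmf)))          # tails[j] = P(X >= j - 1)
  vapply(0:hi, function(k) {
    kp <- max(k - 1, 0)
    if (kp == 0) 1 else min(tails[kp + 1], 1)
  }, numeric(1))
}

# brute-force matcher: plain (feature x rule x compound) scan
match_oracle <- function(study, model, adducts = default_adducts()) {
  parts <- partition_significant(study)
  ref <- parts$reference
  rules <- adducts[adducts$mode == study$mode, , drop = FALSE]
  masses <- model$compounds$monoisotopic_mass
  ids <- model$compounds$id
  tol <- study$params$mz_tol_ppm
  rows <- list()
  for (f in seq_len(nrow(ref))) {
    for (r in seq_len(nrow(rules))) {
      M <- (ref$mz[f] * abs(rules$charge[r]) - rules$mass_shift[r]) /
        rules$mol_multiplier[r]
      if (M <= 0) next
      hit <- which(abs(M - masses) / masses * 1e6 <= tol)
      for (ci in hit) {
        rows[[length(rows) + 1]] <- data.frame(
          feature_id = ref$feature_id[f], compound_id = ids[ci],
          adduct = rules$adduct[r], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(feature_id = character(), compound_id = character(),
               adduct = character())
  out[order(out$feature_id, out$compound_id, out$adduct), , drop = FALSE]
}

# a random study against the toy model: a mix of true adduct ions with
# jitter and uniform decoys, exercising both match and no-match paths
random_toy_study <- function(seed, n_real = 40, n_decoy = 15,
                             mode = "positive", mz_tol_ppm = 10) {
  model <- toy_metabolic_model()
  rules <- default_adducts()
  rules <- rules[rules$mode == mode, , drop = FALSE]
  withr::with_seed(seed, {
    cid <- sample(model$compounds$id, n_real, replace = TRUE)
    r <- sample.int(nrow(rules), n_real, replace = TRUE)
    mz_real <- adduct_mz(
      model$compounds$monoisotopic_mass[match(cid, model$compounds$id)],
      rules$mass_shift[r], rules$charge[r], rules$mol_multiplier[r]) *
      (1 + rnorm(n_real, 0, 4) * 1e-6)
    mz <- c(mz_real, runif(n_decoy, 70, 550))
    p <- runif(n_real + n_decoy)
    ms_study(data.frame(mz = mz, p_value = p), mode = mode,
             study_id = paste0("rand", seed), p_cutoff = 0.1,
             mz_tol_ppm = mz_tol_ppm)
  })
}

# minimal valid model for constructed-index tests
mini_model <- function() {
  metabolic_model(
    compounds = data.frame(
      id = c("A", "B", "C", "D", "E"),
      name = c("alpha", "beta", "gamma", "delta", "epsilon"),
      monoisotopic_mass = c(100.1, 150.2, 200.3, 250.4, 300.5)),
    pathways = data.frame(
      id = c("PW1", "PW2", "PW3"),
      name = c("pw one", "pw two", "pw three"),
      compound_ids = c("A;B", "C;D", "E"),
      gene_symbols = c("ODC1;SAT1", "MYC;TP53", "GAPDH;ACTB"),
      uniprot_ids = c("P11926;P21673", "P01106;P04637", "")))
}

# index-shaped object from explicit compound sets (for pathway_stats tests)
fake_index <- function(reference, significant_p) {
  structure(list(
    study_id = "fake", group = "fake", mode = "positive",
    params = list(p_cutoff = 0.05, mz_tol_ppm = 10, intensity_cutoff = 0),
    matches = tibble::tibble(
      feature_id = paste0("F", seq_along(names(significant_p))),
      compound_id = names(significant_p), adduct = "M+H",
      inferred_neutral_mass = NA_real_, ppm_error = 0, confirmed = FALSE,
      mz = NA_real_, p_value = unname(significant_p),
      source_tag = "fake.tsv", significant = TRUE),
    reference_features = tibble::tibble(
      feature_id = paste0("R", seq_along(reference)),
      p_value = NA_real_, source_tag = "fake.tsv"),
    significant_feature_ids = paste0("F", seq_along(names(significant_p))),
    matched_reference_compounds = sort(reference),
    matched_significant = tibble::tibble(
      compound_id = names(significant_p),
      best_p = unname(significant_p)) |>
      dplyr::arrange(compound_id)),
    class = "annotation_index")
}
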