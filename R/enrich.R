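#' EASE-adjusted Fisher's exact pathway p-value
#'
#' One-sided enrichment p-value for `k` significant pathway compounds out of
#' `m` pathway compounds present in a universe of `N` matched compounds, of
#' which `n_sig` are significant. The EASE variant decrements the observed
#' hit count by one before taking the hypergeometric upper tail:
#' `p = P(X >= max(k - 1, 0))` with `X ~ Hypergeometric(N, m, n_sig)`, and
#' `p = 1` when the decremented count is 0. The decrement makes the score
#' conservative for single-compound hits, which putative annotation produces
#' in abundance.
#'
#' @param k Observed hits (pathway compounds in the significant set).
#' @param m Pathway compounds present in the universe.
#' @param n_sig Size of the significant compound set.
#' @param N Universe size (all matched reference compounds).
#' @return The EASE p-value; vectorized over the arguments.
#' @export
#' @examples
#' ease_fisher_p(k = 3, m = 5, n_sig = 5, N = 20) # 0.366099...
#' ease_fisher_p(k = 1, m = 5, n_sig = 5, N = 20) # 1: decrement clamps to 0
ease_fisher_p <- function(k, m, n_sig, N) {
  n <- max(length(k), length(m), length(n_sig), length(N))
  k <- rep_len(as.numeric(k), n)
  m <- rep_len(as.numeric(m), n)
  n_sig <- rep_len(as.numeric(n_sig), n)
  N <- rep_len(as.numeric(N), n)

  bad <- k < 0 | m < 0 | n_sig < 0 | N < 0 |
    k > pmin(m, n_sig) | m > N | n_sig > N
  if (any(bad)) {
    abort(paste0("ease_fisher_p: bounds violated (need 0 <= k <= min(m, ",
                 "n_sig), m <= N, n_sig <= N)"),
          class = "pathmeta_parameter_error")
  }
  kp <- pmax(k - 1, 0)
  out <- rep(1, n)
  pos <- kp > 0
  # P(X >= kp) = upper tail at kp - 1
  out[pos] <- phyper(kp[pos] - 1, m[pos], N[pos] - m[pos], n_sig[pos],
                     lower.tail = FALSE)
  pmin(pmax(out, 0), 1)
}

# shared core: pathway table from explicit compound sets
pathway_table <- function(reference_ids, significant_ids, model) {
  N <- length(reference_ids)
  if (N == 0) {
    abort("no compounds matched; check mode/tolerance",
          class = "pathmeta_empty_universe_error")
  }
  n_sig <- length(significant_ids)
  pw <- model$pathways
  in_ref <- map(pw$compound_ids, intersect, reference_ids)
  m <- lengths(in_ref)
  keep <- m >= 1
  hit_ids <- map(pw$compound_ids[keep], intersect, significant_ids)

  out <- tibble(
    pathway_id = pw$id[keep],
    pathway_name = pw$name[keep],
    pathway_size = map_int(pw$compound_ids[keep], length),
    matched_in_reference = m[keep],
    hits = lengths(hit_ids),
    hit_compound_ids = map(hit_ids, sort))
  out$p_raw <- ease_fisher_p(out$hits, out$matched_in_reference, n_sig, N)
  arrange(out, .data$p_raw, desc(.data$hits), .data$pathway_id)
}

#' Per-pathway enrichment statistics for one study
#'
#' Computes, for every pathway with at least one compound in the matched
#' reference universe, the hit counts and the EASE p-value
#' ([ease_fisher_p()]) with universe size `N` = number of matched reference
#' compounds and significant-set size `n_sig` = number of matched
#' significant compounds. Pathways sharing no compound with the universe
#' are omitted. Rows are sorted by ascending `p_raw`, ties broken by
#' descending hits then pathway id.
#'
#' @param index An `annotation_index` from [annotate_study()].
#' @param model The [metabolic_model()].
#' @return A tibble with one row per scored pathway.
#' @export
pathway_stats <- function(index, model) {
  pathway_table(index$matched_reference_compounds,
                index$matched_significant$compound_id, model)
}

#' Permutation null distribution of pathway scores
#'
#' Statistical validation of the matched pathways by resampling: each
#' permutation draws, uniformly without replacement from the study's
#' reference features, a pseudo-significant feature list of the same size as
#' the observed significant feature list, re-derives its compound set
#' through the already-computed annotation, and scores every pathway with
#' [ease_fisher_p()]. The pooled scores estimate the distribution of
#' pathway p-values under no association between significance and pathway
#' membership, while preserving the many-to-many structure of mass-based
#' annotation.
#'
#' @param index An `annotation_index`.
#' @param model The [metabolic_model()].
#' @param n_permutations Number of resampling rounds (>= 1).
#' @param seed Integer seed; the null is fully deterministic given it.
#' @return An object of class `pathmeta_null`: pooled `values`,
#'   `n_permutations`, `seed`, and `gamma_params` (`NULL` until a gamma fit
#'   is requested via [adjust_p()]).
#' @export
permutation_null <- function(index, model, n_permutations = 100, seed = 42) {
  if (n_permutations < 1) {
    abort("n_permutations must be >= 1", class = "pathmeta_parameter_error")
  }
  draw <- permutation_sampler(index)
  N <- length(index$matched_reference_compounds)
  score <- pathway_scorer(index$matched_reference_compounds, model)

  values <- withr::with_seed(seed, {
    unlist(map(seq_len(n_permutations), function(b) {
      sig <- draw()
      score(sig, N)
    }))
  })
  structure(list(values = values, n_permutations = n_permutations,
                 seed = seed, gamma_params = NULL),
            class = "pathmeta_null")
}

# closure drawing a pseudo-significant compound set by feature resampling
permutation_sampler <- function(index) {
  ref_ids <- index$reference_features$feature_id
  n_draw <- length(index$significant_feature_ids)
  if (n_draw > length(ref_ids)) {
    abort("significant feature list larger than reference list",
          class = "pathmeta_parameter_error")
  }
  feat_compounds <- split(index$matches$compound_id, index$matches$feature_id)
  function() {
    take <- sample(ref_ids, n_draw)
    sort(unique(unlist(feat_compounds[take], use.names = FALSE)))
  }
}

# closure scoring all pathways (m >= 1) for a given significant compound set
pathway_scorer <- function(reference_ids, model) {
  pw_in_ref <- map(model$pathways$compound_ids, intersect, reference_ids)
  m <- lengths(pw_in_ref)
  pw_in_ref <- pw_in_ref[m >= 1]
  m <- m[m >= 1]
  function(sig_ids, N) {
    k <- map_int(pw_in_ref, function(cids) sum(cids %in% sig_ids))
    ease_fisher_p(k, m, length(sig_ids), N)
  }
}

#' Adjust pathway p-values against a permutation null
#'
#' `"empirical"` (default): `p_adj = (1 + #{v in null : v <= p_raw}) /
#' (1 + |null|)` — assumption-free, never 0, and monotone in `p_raw`.
#' `"gamma"`: a gamma distribution is fitted to `-log10` of the null values
#' and the adjusted p-value is its upper tail at `-log10(p_raw)`, a
#' smoothing useful when permutations are few; a degenerate null makes the
#' fit fall back to the empirical estimate with a warning.
#'
#' @param p_raw Numeric vector of raw pathway p-values.
#' @param null A `pathmeta_null` from [permutation_null()].
#' @param method `"empirical"` or `"gamma"`.
#' @return Adjusted p-values in (0, 1].
#' @export
adjust_p <- function(p_raw, null, method = c("empirical", "gamma")) {
  method <- match.arg(method)
  values <- null$values
  if (length(values) == 0) {
    abort("null distribution is empty", class = "pathmeta_parameter_error")
  }
  if (method == "gamma") {
    x <- -log10(values)
    fit <- tryCatch({
      if (stats::sd(x) < 1e-12) stop("degenerate null")
      suppressWarnings(MASS::fitdistr(pmax(x, 1e-12), "gamma"))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warn("gamma fit failed on degenerate null; falling back to empirical")
      return(adjust_p(p_raw, null, "empirical"))
    }
    adj <- pgamma(-log10(pmax(p_raw, .Machine$double.xmin)),
                  shape = fit$estimate[["shape"]],
                  rate = fit$estimate[["rate"]], lower.tail = FALSE)
    return(pmin(pmax(adj, .Machine$double.xmin), 1))
  }
  sorted <- sort(values)
  counts <- findInterval(p_raw, sorted)  # #{v <= p_raw}
  (1 + counts) / (1 + length(sorted))
}

#' @export
print.pathmeta_null <- function(x, ...) {
  cat("<pathmeta_null> ", length(x$values), " pooled scores from ",
      x$n_permutations, " permutations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Histogram of a permutation null
#'
#' @param object A `pathmeta_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathmeta_null <- function(object, ...) {
  df <- tibble(p = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "permutation pathway p-value", y = "count",
                  title = paste0("Permutation null (",
                                 object$n_permutations, " rounds)")) +
    ggplot2::theme_minimal()
}
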