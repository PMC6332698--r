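# Linear combination of the composition and amyloid terms, three-class
# labelling, and the two user-facing comparison modes.

#' Combination parameters
#'
#' Bundles the weights, normalisations and classification thresholds of the
#' combined score: `score = max(floor, w_c * (c - c_offset)/c_scale +
#' w_a * (a - a_offset)/a_scale)`. The defaults are this package's
#' documented calibration choice: equal weights, the composition term
#' normalised by the classic 0.05 composition-score decision threshold, the
#' amyloid term by its 100-point scale. With these defaults a sequence at
#' the composition decision threshold with a mid-range amyloid core scores
#' near the middle of the low/high band, and strongly prion-promoting
#' sequences can exceed 1.0. The thresholds 0.45 and 0.78 separate the
#' low / increased / high classes; both are strict inequalities, so a score
#' exactly at a threshold falls in the middle class.
#'
#' @param w_c,w_a Non-negative weights of the composition and amyloid terms
#'   (`w_c + w_a > 0`).
#' @param c_offset,c_scale Affine normalisation of the composition term
#'   (`c_scale > 0`).
#' @param a_offset,a_scale Affine normalisation of the amyloid term
#'   (`a_scale > 0`).
#' @param floor Lower clamp of the combined score.
#' @param theta_low,theta_high Class thresholds, `theta_low < theta_high`.
#' @return A list of class `"combination_params"`.
#' @export
#' @examples
#' p <- combination_params()
#' combine_terms(0.05, 50, p)
combination_params <- function(w_c = 0.5, w_a = 0.5,
                               c_offset = 0, c_scale = 0.05,
                               a_offset = 0, a_scale = 100,
                               floor = 0,
                               theta_low = 0.45, theta_high = 0.78) {
  p <- list(w_c = w_c, w_a = w_a, c_offset = c_offset, c_scale = c_scale,
            a_offset = a_offset, a_scale = a_scale, floor = floor,
            theta_low = theta_low, theta_high = theta_high)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1)))) {
    abort("all combination parameters must be finite scalars")
  }
  if (w_c < 0 || w_a < 0 || w_c + w_a <= 0) {
    abort("weights must be non-negative with w_c + w_a > 0")
  }
  if (c_scale <= 0 || a_scale <= 0) abort("normalisation divisors must be positive")
  if (theta_low >= theta_high) abort("theta_low must be below theta_high")
  structure(p, class = "combination_params")
}

#' @export
print.combination_params <- function(x, ...) {
  cat("Combined-score parameters\n")
  cat(sprintf("  score = max(%g, %g * (c - %g)/%g + %g * (a - %g)/%g)\n",
              x$floor, x$w_c, x$c_offset, x$c_scale,
              x$w_a, x$a_offset, x$a_scale))
  cat(sprintf("  classes: low < %g <= increased <= %g < high\n",
              x$theta_low, x$theta_high))
  invisible(x)
}

norm_c <- function(c, p) (c - p$c_offset) / p$c_scale
norm_a <- function(a, p) (a - p$a_offset) / p$a_scale

#' Combine composition and amyloid terms
#'
#' The linear blend at the heart of the predictor. Vectorised; deterministic;
#' non-decreasing in either term (for non-negative weights).
#'
#' @param composition Raw composition term(s) (see [composition_score()]).
#' @param amyloid Raw amyloid term(s) on the 0-100 scale (see
#'   [amyloid_core()]).
#' @param params A [combination_params()] object.
#' @return Numeric vector of combined scores, clamped below at
#'   `params$floor`.
#' @export
combine_terms <- function(composition, amyloid, params = combination_params()) {
  stopifnot(inherits(params, "combination_params"))
  if (!all(is.finite(composition)) || !all(is.finite(amyloid))) {
    abort("composition and amyloid terms must be finite")
  }
  pmax(params$floor,
       params$w_c * norm_c(composition, params) +
       params$w_a * norm_a(amyloid, params))
}

#' Classify a combined score
#'
#' Three-class labelling against the low/high thresholds: `score <
#' theta_low` is `"low"`, `score > theta_high` is `"high"`, everything in
#' between (including scores exactly at a threshold) is `"increased"`.
#'
#' @param score Numeric vector of combined scores.
#' @param params A [combination_params()] object.
#' @return Factor with levels `low`, `increased`, `high`.
#' @export
#' @examples
#' classify_score(c(0.34, 0.45, 0.78, 0.93))
classify_score <- function(score, params = combination_params()) {
  stopifnot(inherits(params, "combination_params"))
  out <- ifelse(score < params$theta_low, "low",
                ifelse(score > params$theta_high, "high", "increased"))
  factor(out, levels = c("low", "increased", "high"))
}

#' Score protein records end to end
#'
#' The full pipeline for a table of records: composition term
#' ([composition_score()]), amyloid core ([amyloid_core()]), linear
#' combination and class label. By default the amyloid search is coupled to
#' the composition step: it runs inside the contiguous disordered region
#' containing the composition argmax (amyloid cores are sought within the
#' PrLD), falling back to the whole sequence when the gate leaves no region.
#' Set `couple_region = FALSE` to always search the whole sequence.
#'
#' @param proteins Tibble of validated protein records.
#' @param params A [combination_params()] object.
#' @param scale Propensity scale, default [propensity_scale()].
#' @param matrix Amyloid matrix, default [amyloid_matrix()].
#' @param window Composition/disorder window size (odd, default 41).
#' @param core_length Amyloid core length (default 21).
#' @param couple_region Restrict the amyloid search to the disordered region
#'   around the composition argmax (default `TRUE`).
#' @return A tibble of class `"prion_scores"`, one row per record, in input
#'   order: `id`, `length`, `composition`, `composition_norm`, `amyloid`,
#'   `amyloid_norm`, `score`, `class`, `comp_center`, `core_start`, `core`,
#'   `all_ordered`, `floored`, `sequence`. The parameters used are kept in
#'   attribute `"params"`.
#' @export
score_proteins <- function(proteins, params = combination_params(),
                           scale = propensity_scale(),
                           matrix = amyloid_matrix(),
                           window = 41L, core_length = 21L,
                           couple_region = TRUE) {
  proteins <- validate_proteins(proteins)
  stopifnot(inherits(params, "combination_params"))
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    rec <- proteins[i, ]
    comp <- composition_score(rec, scale = scale, window = window)
    region <- NULL
    if (couple_region && !comp$all_ordered) {
      fi <- foldindex_profile(rec, window)
      region <- disordered_region(fi, comp$window_start, window)
    }
    amy <- amyloid_core(rec, matrix = matrix, core_length = core_length,
                        region = region)
    raw <- params$w_c * norm_c(comp$score, params) +
      params$w_a * norm_a(amy$score, params)
    score <- max(params$floor, raw)
    tibble(id = rec$id,
           length = rec$length,
           composition = comp$score,
           composition_norm = norm_c(comp$score, params),
           amyloid = amy$score,
           amyloid_norm = norm_a(amy$score, params),
           score = score,
           class = classify_score(score, params),
           comp_center = comp$position,
           core_start = amy$start,
           core = amy$core,
           all_ordered = comp$all_ordered,
           floored = raw < params$floor,
           sequence = rec$sequence)
  })
  out <- list_rbind(rows)
  attr(out, "params") <- params
  class(out) <- c("prion_scores", class(out))
  out
}

# fixed three-tier phrasing keyed to class and delta sign
impact_statement <- function(class, delta) {
  dir <- dplyr::case_when(
    delta > 0 ~ "increases the predicted aggregation propensity relative to the reference",
    delta < 0 ~ "decreases the predicted aggregation propensity relative to the reference",
    TRUE ~ "leaves the predicted aggregation propensity unchanged")
  tier <- dplyr::case_when(
    class == "high" ~ "the variant is predicted highly aggregation-prone",
    class == "increased" ~ "the variant is predicted to have increased aggregation propensity",
    TRUE ~ "the variant remains of low predicted aggregation propensity")
  paste0(dir, "; ", tier, ".")
}

#' Compare variant sequences against a reference
#'
#' Scores the reference and each variant with [score_proteins()] and
#' annotates every variant with its score difference from the reference and
#' a textual impact statement. Rows come back in input order, reference
#' first.
#'
#' @param reference One-row tibble of the reference record.
#' @param variants Tibble of variant records (may include the reference
#'   itself).
#' @param params A [combination_params()] object.
#' @param ... Passed on to [score_proteins()].
#' @return A `"prion_scores"` tibble with additional columns `role`
#'   (`reference`/`variant`), `delta` (score minus reference score) and
#'   `impact`.
#' @export
compare_sequences <- function(reference, variants,
                              params = combination_params(), ...) {
  reference <- one_protein(reference, "reference")
  variants <- as_protein_tbl(variants, "variants")
  all <- bind_rows(reference, variants)
  scored <- score_proteins(all, params = params, ...)
  ref_score <- scored$score[1]
  scored$role <- c("reference", rep("variant", nrow(variants)))
  scored$delta <- scored$score - ref_score
  scored$impact <- ifelse(
    scored$role == "reference", "reference sequence.",
    impact_statement(scored$class, scored$delta))
  scored
}

#' Saturation scan of one residue position
#'
#' Evaluates the wild type and all 19 possible substitutions at `position`:
#' the in-silico mutation scan mode. The wild-type row comes first, then the
#' 19 variants in alphabetical order of the substituted residue; deltas are
#' relative to the wild type.
#'
#' @param protein One-row tibble of the wild-type record.
#' @param position 1-based residue position to scan.
#' @param params A [combination_params()] object.
#' @param ... Passed on to [score_proteins()].
#' @return A 20-row `"prion_scores"` tibble (see [compare_sequences()]),
#'   with an extra `substitution` column (`NA` for the wild type).
#' @export
single_mutation_scan <- function(protein, position,
                                 params = combination_params(), ...) {
  protein <- one_protein(protein)
  variants <- enumerate_substitutions(protein, position)
  out <- compare_sequences(protein, variants, params = params, ...)
  out$role <- c("wild_type", rep("variant", nrow(variants)))
  wt <- substr(protein$sequence, position, position)
  out$substitution <- c(NA_character_,
                        paste0(wt, position, setdiff(AA_ALPHABET, wt)))
  out$impact[1] <- "wild-type sequence."
  out
}
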