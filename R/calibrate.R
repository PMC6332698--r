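# Calibration of the combination weights against anchor sequences with
# published scores. The combined score is linear in (w_c, w_a) given the
# normalised terms, so the fit is ordinary least squares through the origin
# with any non-free parameter held at its current value.

#' Calibrate combination weights against anchor scores
#'
#' Given anchor records with published combined scores, computes each
#' anchor's normalised composition and amyloid terms and least-squares fits
#' the free parameters of the linear combination to the published values
#' (closed-form normal equations via [stats::lm()]; deterministic). Fixed
#' parameters keep their values from `params`; their contribution is
#' subtracted from the response before fitting.
#'
#' @param anchors Tibble with columns `id`, `sequence` and `published` (the
#'   anchor's published combined score); at least two anchors with distinct
#'   published scores.
#' @param params Starting [combination_params()]; normalisations and any
#'   parameter not in `free` are taken from here.
#' @param free Character vector of parameters to fit: any of `"w_c"`,
#'   `"w_a"`.
#' @param ... Passed on to [score_proteins()] (e.g. `couple_region`).
#'
#' @details Anchors whose published score sits at the floor (e.g. the
#' exact-zero scores of non-prionic wild types) are excluded from the
#' least-squares fit: a clamped score only bounds the linear predictor from
#' above, it does not pin it. They remain in the returned anchor table with
#' `in_fit = FALSE` and a residual computed from the clamped fitted score.
#'
#' @return An object of class `"prion_calibration"`: a list with `params`
#'   (refitted [combination_params()]), `fit` (the underlying `lm`),
#'   `anchors` (input plus per-anchor terms, `in_fit` flag, fitted scores
#'   and residuals) and `free`. Supports [tidy()], [glance()] and
#'   `print()`.
#' @export
#' @examples
#' \donttest{
#' anchors <- dplyr::mutate(
#'   tibble::tibble(id = c("a", "b", "c"),
#'                  sequence = c(strrep("QNYG", 30), strrep("QNSA", 30),
#'                               strrep("NGSY", 30))),
#'   published = score_proteins(
#'     tibble::tibble(id = id, sequence = sequence))$score)
#' calibrate_params(anchors)
#' }
calibrate_params <- function(anchors, params = combination_params(),
                             free = c("w_c", "w_a"), ...) {
  stopifnot(inherits(params, "combination_params"))
  free <- match.arg(free, c("w_c", "w_a"), several.ok = TRUE)
  if (!is.data.frame(anchors) ||
      !all(c("id", "sequence", "published") %in% names(anchors))) {
    abort("`anchors` must have columns id, sequence, published")
  }
  anchors <- as_tibble(anchors)
  if (nrow(anchors) < length(free) ||
      length(unique(anchors$published)) < 2L) {
    abort("need at least two anchors with distinct published scores",
          class = "prionscore_calibration_error")
  }
  scored <- score_proteins(anchors[, c("id", "sequence")], params = params, ...)
  terms <- tibble(nc = scored$composition_norm, na = scored$amyloid_norm)
  design <- as.matrix(terms[, c(w_c = "nc", w_a = "na")[free], drop = FALSE])
  colnames(design) <- free
  fixed <- setdiff(c("w_c", "w_a"), free)
  offset <- rep(0, nrow(anchors))
  for (f in fixed) {
    offset <- offset + params[[f]] * terms[[c(w_c = "nc", w_a = "na")[f]]]
  }
  in_fit <- anchors$published > params$floor
  if (sum(in_fit) < max(2L, length(free)) ||
      length(unique(anchors$published[in_fit])) < 2L) {
    abort("need at least two unclamped anchors with distinct published scores",
          class = "prionscore_calibration_error")
  }
  y <- anchors$published - offset
  qrd <- qr(design[in_fit, , drop = FALSE])
  if (qrd$rank < ncol(design)) {
    abort("anchors are rank-deficient in a fitted term (all identical?)",
          class = "prionscore_calibration_error")
  }
  fit <- lm(y[in_fit] ~ 0 + design[in_fit, , drop = FALSE])
  est <- setNames(unname(coef(fit)), free)
  new <- params
  for (f in free) new[[f]] <- est[[f]]
  new_params <- do.call(combination_params, unclass(new))
  fitted_scores <- pmax(params$floor, offset + as.vector(design %*% est))
  out <- list(
    params = new_params,
    fit = fit,
    free = free,
    anchors = mutate(bind_cols(anchors, terms),
                     in_fit = in_fit,
                     fitted = fitted_scores,
                     residual = fitted_scores - anchors$published))
  class(out) <- "prion_calibration"
  out
}

#' @export
print.prion_calibration <- function(x, ...) {
  cat("Calibrated combined-score parameters\n")
  cat(sprintf("  fitted: %s\n",
              paste(sprintf("%s = %.4f", x$free,
                            unlist(x$params[x$free])), collapse = ", ")))
  cat(sprintf("  anchors: %d, RMSE %.4f\n",
              nrow(x$anchors), sqrt(mean(x$anchors$residual^2))))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `"prion_calibration"` object.
#' @param ... Unused.
#' @return Tibble with one row per fitted parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy prion_calibration
#' @export
tidy.prion_calibration <- function(x, ...) {
  # summary.lm warns on an essentially perfect fit (noiseless anchors)
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = x$free,
         estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]))
}

#' One-row summary of a calibration fit
#'
#' @param x A `"prion_calibration"` object.
#' @param ... Unused.
#' @return Tibble with `n` (anchors), `rmse`, `max_abs_residual` and
#'   `r.squared` of fitted vs published scores.
#' @method glance prion_calibration
#' @export
glance.prion_calibration <- function(x, ...) {
  r <- x$anchors$residual
  r2 <- if (sd(x$anchors$fitted) > 0) {
    cor(x$anchors$fitted, x$anchors$published)^2
  } else NA_real_
  tibble(n = nrow(x$anchors), rmse = sqrt(mean(r^2)),
         max_abs_residual = max(abs(r)), r.squared = r2)
}

#' Predict combined scores with calibrated parameters
#'
#' @param object A `"prion_calibration"` object.
#' @param proteins Tibble of protein records to score.
#' @param ... Passed on to [score_proteins()].
#' @return A `"prion_scores"` tibble (see [score_proteins()]).
#' @export
predict.prion_calibration <- function(object, proteins, ...) {
  score_proteins(proteins, params = object$params, ...)
}
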