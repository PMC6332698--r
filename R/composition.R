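# Composition term: disorder-gated, doubly window-averaged per-residue prion
# propensity. The double averaging first scores each 41-residue window by the
# mean propensity of its residues, then smooths window scores across
# neighbouring windows, so a single favourable stretch must be embedded in a
# favourable neighbourhood to reach a high score.

#' Sliding-window mean of a numeric track
#'
#' The windowing kernel shared by the composition, disorder and amyloid
#' tracks. Only full windows are scored: for a track of length `L` and an
#' odd window `w` the result has `L - w + 1` values, `out[i]` being the
#' arithmetic mean of `values[i..(i + w - 1)]`.
#'
#' @param values Numeric vector.
#' @param window Odd window size, `window <= length(values)`.
#' @return Numeric vector of full-window means.
#' @export
#' @examples
#' window_average(c(0, 0, 0, 3, 0, 0, 0), 3)
window_average <- function(values, window) {
  stopifnot(is.numeric(values), length(window) == 1L)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("`window` must be a positive odd integer")
  }
  if (length(values) < window) {
    abort(sprintf("track of length %d is shorter than window %d",
                  length(values), window))
  }
  running_mean(values, window)
}

# running mean over full windows of arbitrary (not necessarily odd) width,
# via cumulative sums; numerical error is far below the 1e-12 oracle bound
# for the track lengths used here
running_mean <- function(values, width) {
  cs <- cumsum(c(0, values))
  (cs[(width + 1L):length(cs)] - cs[1:(length(cs) - width)]) / width
}

# lowest index attaining the maximum, treating values within `tol` of the
# maximum as tied: cumulative-sum windowing leaves ~1e-16 wobble on
# mathematically equal windows (e.g. homopolymers), which must not steal
# the lowest-position tie-break
argmax_low <- function(x, tol = 1e-9) {
  which(x >= max(x) - tol)[1]
}

# per-residue lookup of a named scale along a sequence string
residue_values <- function(sequence, scale) {
  unname(scale[strsplit(sequence, "", fixed = TRUE)[[1]]])
}

#' FoldIndex-style disorder profile
#'
#' Windowed fold/disorder index: `2.785 * <H> - |<q>| - 1.151`, where `<H>`
#' is the window mean Kyte-Doolittle hydropathy rescaled to `[0, 1]`
#' (`(value + 4.5) / 9`) and `<q>` the window mean net charge (K, R = +1;
#' D, E = -1; others 0). Negative values predict disorder. Computed over the
#' same full windows as the composition term so the two tracks align by
#' window start.
#'
#' @param protein One-row protein tibble (or a bare sequence string).
#' @param window Odd window size; 41 matches the composition default.
#' @return A tibble with one row per full window: `start`, `center`
#'   (1-based), `value` and `disordered` (`value < 0`).
#' @export
foldindex_profile <- function(protein, window = 41L) {
  seq <- one_protein(protein)$sequence
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd")
  if (nchar(seq) < window) {
    abort(sprintf("sequence of length %d is shorter than window %d",
                  nchar(seq), window))
  }
  kd <- hydrophobicity_scale()
  hyd <- (residue_values(seq, kd) + 4.5) / 9
  charge_scale <- setNames(numeric(20), AA_ALPHABET)
  charge_scale[c("K", "R")] <- 1
  charge_scale[c("D", "E")] <- -1
  chg <- residue_values(seq, charge_scale)
  value <- 2.785 * running_mean(hyd, window) -
    abs(running_mean(chg, window)) - 1.151
  half <- (window - 1L) %/% 2L
  tibble(start = seq_along(value),
         center = seq_along(value) + half,
         value = value,
         disordered = value < 0)
}

# second averaging pass over first-pass window scores: centred window of the
# same nominal width, shrinking symmetrically near the profile edges so every
# first-pass window receives a value; strict mode scores only positions with
# a full second-pass window
second_pass <- function(p, window, edges = c("shrink", "strict")) {
  edges <- match.arg(edges)
  half <- (window - 1L) %/% 2L
  m <- length(p)
  cs <- cumsum(c(0, p))
  idx <- seq_len(m)
  if (edges == "shrink") {
    h_eff <- pmin(half, idx - 1L, m - idx)
    (cs[idx + h_eff + 1L] - cs[idx - h_eff]) / (2L * h_eff + 1L)
  } else {
    out <- rep(NA_real_, m)
    ok <- idx[idx - half >= 1L & idx + half <= m]
    out[ok] <- (cs[ok + half + 1L] - cs[ok - half]) / window
    out
  }
}

#' Composition-based prion propensity score
#'
#' The composition term of the combined score. Per-residue propensities from
#' `scale` are window-averaged twice (each 41-residue window scored by its
#' mean propensity, then window scores averaged across neighbouring windows,
#' shrinking symmetrically at the profile edges), and the maximum is taken
#' over windows whose disorder index ([foldindex_profile()]) is negative.
#' When no window is predicted disordered the score falls back to the scale
#' minimum (a floor) and `all_ordered` flags it: the method targets
#' disordered PrLDs but must still return a defined value. Argmax ties break
#' to the lowest sequence position.
#'
#' @param protein One-row protein tibble (or bare sequence string), already
#'   validated.
#' @param scale Named propensity vector, default [propensity_scale()].
#' @param window Odd window size (default 41).
#' @param gate Apply the disorder gate (default `TRUE`); with `FALSE` all
#'   windows are candidates.
#' @param edges Second-pass edge handling: `"shrink"` (default, symmetric
#'   shrink) or `"strict"` (full second-pass windows only).
#' @return One-row tibble: `score`, `position` (center of the winning
#'   window), `window_start`, `all_ordered`, `n_disordered`.
#' @export
composition_score <- function(protein, scale = propensity_scale(),
                              window = 41L, gate = TRUE,
                              edges = c("shrink", "strict")) {
  protein <- one_protein(protein)
  edges <- match.arg(edges)
  check_scale(scale, "scale")
  seq <- protein$sequence
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd")
  if (nchar(seq) < window) {
    abort(sprintf("sequence '%s' (length %d) is shorter than window %d",
                  protein$id, nchar(seq), window))
  }
  p <- running_mean(residue_values(seq, scale), window)
  q <- second_pass(p, window, edges)
  fi <- foldindex_profile(protein, window)
  candidates <- if (gate) which(fi$disordered & !is.na(q)) else which(!is.na(q))
  half <- (window - 1L) %/% 2L
  if (length(candidates) == 0L) {
    return(tibble(score = min(scale), position = NA_integer_,
                  window_start = NA_integer_, all_ordered = TRUE,
                  n_disordered = 0L))
  }
  best <- candidates[argmax_low(q[candidates])]
  tibble(score = q[best],
         position = best + half,
         window_start = as.integer(best),
         all_ordered = FALSE,
         n_disordered = sum(fi$disordered))
}

#' Windowed composition propensity profile
#'
#' The doubly-averaged composition track underlying [composition_score()],
#' exposed for inspection and plotting.
#'
#' @inheritParams composition_score
#' @return Tibble with one row per full window: `start`, `center`, `value`
#'   (doubly-averaged propensity) and `disordered` (disorder gate for that
#'   window).
#' @export
composition_profile <- function(protein, scale = propensity_scale(),
                                window = 41L, edges = c("shrink", "strict")) {
  protein <- one_protein(protein)
  edges <- match.arg(edges)
  seq <- protein$sequence
  p <- running_mean(residue_values(seq, scale), as.integer(window))
  q <- second_pass(p, as.integer(window), edges)
  fi <- foldindex_profile(protein, window)
  half <- (as.integer(window) - 1L) %/% 2L
  tibble(start = seq_along(q), center = seq_along(q) + half,
         value = q, disordered = fi$disordered)
}

# contiguous run of disordered windows containing window `start`; returns
# c(first_residue, last_residue) covered by that run, or NULL
disordered_region <- function(fi, start, window) {
  if (is.na(start) || !isTRUE(fi$disordered[start])) return(NULL)
  runs <- rle(fi$disordered)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  k <- which(begins <= start & ends >= start)
  c(begins[k], ends[k] + as.integer(window) - 1L)
}
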