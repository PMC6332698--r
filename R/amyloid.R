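# Amyloid term: best 21-residue stretch under a hexapeptide PSSM. A
# 21-residue window contains 16 overlapping hexapeptides; the window score is
# their mean (not sum), so core scores are length-stable. The raw maximum is
# mapped to 0-100 against the matrix's stored min/max anchors.

#' Score hexapeptides under an amyloid matrix
#'
#' Sum over the six positions of the matrix entry for the residue at that
#' position. Vectorised over hexapeptides.
#'
#' @param hex Character vector of 6-residue peptides (standard residues
#'   only).
#' @param matrix An `"amyloid_matrix"` object, default [amyloid_matrix()].
#' @return Numeric vector of raw (un-normalised) hexapeptide scores.
#' @export
#' @examples
#' hexapeptide_score(c("ILVFYW", "QNQNQN"))
hexapeptide_score <- function(hex, matrix = amyloid_matrix()) {
  stopifnot(inherits(matrix, "amyloid_matrix"))
  if (any(nchar(hex) != 6L)) {
    abort("hexapeptides must be exactly 6 residues long")
  }
  res <- strsplit(hex, "", fixed = TRUE)
  bad <- !vapply(res, function(r) all(r %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    abort(sprintf("non-standard residue in hexapeptide '%s'", hex[which(bad)[1]]))
  }
  m <- matrix$matrix
  vapply(res, function(r) sum(m[cbind(1:6, match(r, colnames(m)))]),
         numeric(1))
}

# raw (un-normalised) score track over all core windows of `seq`:
# value[t] = mean of the (core_length - 5) hexapeptide scores starting in
# window t
amyloid_track <- function(seq, matrix, core_length) {
  n_hex <- nchar(seq) - 5L
  starts <- seq_len(n_hex)
  hexes <- substring(seq, starts, starts + 5L)
  h <- hexapeptide_score(hexes, matrix)
  running_mean(h, core_length - 5L)
}

#' Locate and score the amyloid core
#'
#' Scans every `core_length`-residue window (21 by default), scoring each by
#' the mean of its overlapping hexapeptide scores, and returns the best
#' window min-max normalised to `[0, 100]` against the matrix anchors. Ties
#' break to the lowest start. When `region` is supplied (e.g. the disordered
#' region from the composition step) the search is restricted to it, but
#' reported positions stay in whole-sequence coordinates.
#'
#' @param protein One-row protein tibble (or bare sequence string).
#' @param matrix An `"amyloid_matrix"` object, default [amyloid_matrix()].
#' @param core_length Core window length; 21 is the only supported default.
#' @param region Optional `c(start, end)` residue range to search within.
#' @return One-row tibble: `score` (0-100), `start`, `end` (1-based, whole
#'   sequence), `core` (the core subsequence).
#' @export
amyloid_core <- function(protein, matrix = amyloid_matrix(),
                         core_length = 21L, region = NULL) {
  protein <- one_protein(protein)
  stopifnot(inherits(matrix, "amyloid_matrix"))
  core_length <- as.integer(core_length)
  if (core_length < 6L) abort("`core_length` must be at least 6")
  seq <- protein$sequence
  offset <- 0L
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] < 1L ||
        region[2] > nchar(seq) || region[1] > region[2]) {
      abort("`region` must be c(start, end) within the sequence")
    }
    seq <- substr(seq, region[1], region[2])
    offset <- region[1] - 1L
  }
  if (nchar(seq) < core_length) {
    abort(sprintf("search region of length %d is shorter than the %d-residue core",
                  nchar(seq), core_length))
  }
  track <- amyloid_track(seq, matrix, core_length)
  best <- argmax_low(track)              # lowest start on (near-)ties
  raw <- track[best]
  anchors <- matrix$anchors
  score <- 100 * (raw - anchors[1]) / (anchors[2] - anchors[1])
  start <- best + offset
  tibble(score = score,
         start = as.integer(start),
         end = as.integer(start + core_length - 1L),
         core = substr(protein$sequence, start, start + core_length - 1L))
}
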