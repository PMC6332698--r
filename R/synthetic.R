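# Synthetic prion-like domain generator. Samples sequences from a Q/N-rich
# background composition modelled on yeast prion domains, optionally
# embedding an amyloidogenic 21-mer; gives the package deterministic,
# realistic fixtures without any external data.

#' Default Q/N-rich PrLD residue composition
#'
#' Background residue frequencies emulating the biased, low-complexity
#' composition of yeast prion domains: glutamine/asparagine-rich, high in
#' glycine, serine and tyrosine, nearly devoid of hydrophobics, charge and
#' cysteine. Frequencies sum to 1.
#'
#' @return Named numeric vector of length 20 (frequencies by residue).
#' @export
prld_composition <- function() {
  c(A = 0.050, C = 0.005, D = 0.020, E = 0.020, F = 0.020,
    G = 0.120, H = 0.020, I = 0.010, K = 0.030, L = 0.020,
    M = 0.020, N = 0.180, P = 0.060, Q = 0.180, R = 0.030,
    S = 0.100, T = 0.040, V = 0.010, W = 0.005, Y = 0.060)
}

#' Generate a synthetic prion-like domain sequence
#'
#' Samples a sequence of `length` residues from `composition`, optionally
#' overwriting a stretch with a fixed `core` (e.g. an amyloidogenic 21-mer)
#' at `core_position`. With a `seed` the record is fully reproducible and
#' the caller's RNG state is untouched.
#'
#' @param length Sequence length (>= 60).
#' @param seed Optional integer seed for reproducibility.
#' @param composition Named residue frequency vector summing to 1; default
#'   [prld_composition()].
#' @param core Optional subsequence to embed verbatim (standard residues
#'   only).
#' @param core_position 1-based start of the embedded core; default centres
#'   it.
#' @param id Record id.
#' @return One-row protein tibble (`id`, `description`, `sequence`,
#'   `length`).
#' @export
#' @examples
#' generate_synthetic_prld(80, seed = 1)
generate_synthetic_prld <- function(length = 120L, seed = NULL,
                                    composition = prld_composition(),
                                    core = NULL, core_position = NULL,
                                    id = "synthetic_prld") {
  length <- as.integer(length)
  if (length < 60L) abort("`length` must be at least 60")
  if (!is.numeric(composition) ||
      !setequal(names(composition), AA_ALPHABET) ||
      any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8) {
    abort("`composition` must be non-negative frequencies over the 20 standard residues, summing to 1")
  }
  draw <- function() {
    sample(names(composition), length, replace = TRUE, prob = composition)
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  seq <- paste(res, collapse = "")
  if (!is.null(core)) {
    core <- toupper(core)
    core_res <- strsplit(core, "", fixed = TRUE)[[1]]
    if (!all(core_res %in% AA_ALPHABET)) {
      abort("`core` must use only the 20 standard residues")
    }
    if (is.null(core_position)) {
      core_position <- max(1L, (length - nchar(core)) %/% 2L + 1L)
    }
    core_position <- as.integer(core_position)
    if (core_position < 1L || core_position + nchar(core) - 1L > length) {
      abort("embedded core does not fit inside the sequence")
    }
    substr(seq, core_position, core_position + nchar(core) - 1L) <- core
  }
  tibble(id = id, description = "synthetic Q/N-rich prion-like domain",
         sequence = seq, length = nchar(seq))
}
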