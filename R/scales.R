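# Reference scoring tables shipped as package data. Swapping a scale is a
# configuration choice (pass a different file/vector), never a code change.

#' Read a two-column residue scale file
#'
#' Scale files are plain text: `#` comment lines carry provenance, data lines
#' are `residue<TAB>value`. The file must define exactly the 20 standard
#' amino acids with finite values.
#'
#' @param path Path to the scale file.
#' @return Named numeric vector of length 20 (names are residues). The
#'   provenance comment lines are kept in attribute `"provenance"`.
#' @export
#' @examples
#' scale <- read_scale(system.file("extdata", "prion_propensity_sup35.tsv",
#'                                 package = "prionscore"))
#' scale[["Q"]]
read_scale <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  dat <- utils::read.table(text = lines, comment.char = "#",
                           col.names = c("residue", "value"),
                           colClasses = c("character", "numeric"))
  vals <- setNames(dat$value, dat$residue)
  check_scale(vals, basename(path))
  attr(vals, "provenance") <- prov
  vals
}

check_scale <- function(vals, label) {
  if (!setequal(names(vals), AA_ALPHABET) || length(vals) != 20L) {
    abort(sprintf("scale '%s' must define exactly the 20 standard amino acids", label))
  }
  if (!all(is.finite(vals))) {
    abort(sprintf("scale '%s' contains non-finite values", label))
  }
  invisible(vals)
}

#' Built-in per-residue prion propensity scale
#'
#' The Sup35-mutagenesis-derived prion propensity scale used by the
#' composition term (the scale distributed with the PAPA predictor).
#' Dimensionless; higher values are more prion-promoting.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
propensity_scale <- function() {
  cached_scale("prion_propensity_sup35.tsv")
}

#' Built-in Kyte-Doolittle hydropathy scale
#'
#' Raw hydropathy values; the disorder index rescales them to `[0, 1]` as
#' `(value + 4.5) / 9`.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
hydrophobicity_scale <- function() {
  cached_scale("hydrophobicity_kyte_doolittle.tsv")
}

# small per-session cache so repeated scoring calls do not re-read files
.scale_cache <- new.env(parent = emptyenv())

cached_scale <- function(file) {
  if (is.null(.scale_cache[[file]])) {
    .scale_cache[[file]] <- read_scale(
      system.file("extdata", file, package = "prionscore", mustWork = TRUE))
  }
  .scale_cache[[file]]
}

#' Read an amyloid hexapeptide scoring matrix
#'
#' Matrix files are plain text: `#` comments, a header line
#' `pos <residue...>`, six data rows (hexapeptide positions 1-6 by the 20
#' residues), and a final `anchors <min> <max>` line giving the minimum and
#' maximum achievable hexapeptide sums. Anchors are stored in the file, not
#' recomputed, so normalised scores stay stable across matrix revisions.
#'
#' @param path Path to the matrix file.
#' @return A list of class `"amyloid_matrix"` with elements `matrix` (6 x 20
#'   numeric, rownames 1-6, colnames residues), `anchors` (length-2 numeric,
#'   min then max) and `provenance` (comment lines).
#' @export
read_amyloid_matrix <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  anchor_line <- grep("^anchors\\b", body, value = TRUE)
  if (length(anchor_line) != 1L) {
    abort(sprintf("matrix file '%s' must contain exactly one 'anchors' line", basename(path)))
  }
  anchors <- as.numeric(strsplit(anchor_line, "\t")[[1]][-1])
  tab <- utils::read.table(text = setdiff(body, anchor_line),
                           header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(dim(m), c(6L, 20L)) || !setequal(colnames(m), AA_ALPHABET)) {
    abort(sprintf("matrix file '%s' must be 6 positions x 20 standard residues", basename(path)))
  }
  m <- m[, AA_ALPHABET, drop = FALSE]
  if (!all(is.finite(m))) abort("amyloid matrix contains non-finite entries")
  if (length(anchors) != 2L || !all(is.finite(anchors)) || anchors[1] >= anchors[2]) {
    abort("anchors line must hold two finite values with min < max")
  }
  structure(list(matrix = m, anchors = anchors, provenance = prov),
            class = "amyloid_matrix")
}

#' Built-in amyloid hexapeptide scoring matrix (synthetic)
#'
#' A synthetic stand-in position-specific scoring matrix for amyloid
#' hexapeptides, constructed from the canonical beta-aggregation propensity
#' ordering of the residues (I/V/F/Y/W/L favourable, P/K/E/D/G unfavourable)
#' with mild position dependence. It reproduces the qualitative behaviour of
#' published amyloid hexapeptide matrices; absolute scores are not comparable
#' to any published predictor. Users holding a published matrix can supply it
#' via [read_amyloid_matrix()] everywhere this default is accepted.
#'
#' @return An `"amyloid_matrix"` object (see [read_amyloid_matrix()]).
#' @export
amyloid_matrix <- function() {
  file <- "amyloid_pssm_synthetic.tsv"
  if (is.null(.scale_cache[[file]])) {
    .scale_cache[[file]] <- read_amyloid_matrix(
      system.file("extdata", file, package = "prionscore", mustWork = TRUE))
  }
  .scale_cache[[file]]
}

#' @export
print.amyloid_matrix <- function(x, ...) {
  cat("Amyloid hexapeptide scoring matrix (6 positions x 20 residues)\n")
  cat(sprintf("  anchors: min %.4f, max %.4f\n", x$anchors[1], x$anchors[2]))
  if (length(x$provenance)) cat(sub("^#\\s?", "  ", x$provenance[1]), "\n")
  invisible(x)
}
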