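# Run manifests, report rendering and the two shell-facing run modes
# (compare, scan). The JSON report is the machine contract: full precision,
# schema-versioned, and free of wall-clock fields so identical inputs give
# byte-identical files. The text report carries the human-readable summary
# with 2-decimal scores.

REPORT_SCHEMA_VERSION <- "1.0"

# md5 of a string, via a temp file (tools::md5sum is file-based)
content_hash <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(text, tf)
  unname(tools::md5sum(tf))
}

#' Build a run manifest
#'
#' Identifies one invocation of a run mode. The job identifier derives from
#' the input content (md5 of the input files), not from the wall clock, so
#' reruns of the same inputs are traceable to the same id; the creation
#' time is carried separately and never enters the machine-readable report.
#'
#' @param mode `"compare"` or `"scan"`.
#' @param inputs Character vector of input file paths.
#' @param position Scanned position (scan mode only).
#' @return A list of class `"run_manifest"`: `id`, `mode`, `inputs`
#'   (basenames), `position`, `created`.
#' @export
run_manifest <- function(mode = c("compare", "scan"), inputs,
                         position = NULL) {
  mode <- match.arg(mode)
  if (mode == "scan" && is.null(position)) {
    abort("scan mode requires `position`")
  }
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else content_hash(f)
  }, character(1))
  id <- paste0(mode, "-", substr(content_hash(paste(
    c(hashes, position), collapse = "|")), 1, 12))
  structure(list(id = id, mode = mode, inputs = basename(inputs),
                 position = position, created = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}

#' Render a report bundle to disk
#'
#' Writes the standard output set for one run: `report.txt` (human summary,
#' scores to 2 decimals, class words and impact statements), `report.json`
#' (full precision, schema-versioned), `scores.png` (bar chart with the
#' low/high threshold guides; skipped with a warning if plotting fails) and
#' `inputs/sequences.fasta` (the scored sequences). Optionally zips the
#' bundle.
#'
#' @param bundles A `"prion_scores"` tibble (from [compare_sequences()] or
#'   [single_mutation_scan()]).
#' @param manifest A [run_manifest()].
#' @param out_dir Output directory (created if needed).
#' @param params The [combination_params()] used (defaults to the attribute
#'   carried by `bundles`).
#' @param zip Also produce `report.zip` (default `FALSE`; skipped with a
#'   warning when no zip tool is available).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(bundles, manifest, out_dir,
                          params = attr(bundles, "params"), zip = FALSE) {
  stopifnot(is.data.frame(bundles), nrow(bundles) >= 1L,
            inherits(manifest, "run_manifest"))
  if (is.null(params)) params <- combination_params()
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list()

  # -- human-readable text
  txt <- c(
    sprintf("Job %s (%s mode)", manifest$id, manifest$mode),
    sprintf("Created: %s UTC", manifest$created),
    sprintf("Inputs: %s", paste(manifest$inputs, collapse = ", ")),
    if (!is.null(manifest$position))
      sprintf("Scanned position: %d", manifest$position),
    "",
    sprintf("Classification thresholds: low < %.2f, high > %.2f",
            params$theta_low, params$theta_high),
    "")
  for (i in seq_len(nrow(bundles))) {
    b <- bundles[i, ]
    txt <- c(txt, sprintf(
      "%s: score %.2f (%s)%s%s", b$id, b$score, as.character(b$class),
      if (!is.null(b$delta) && !is.na(b$delta) &&
          !identical(b$role, "reference") && !identical(b$role, "wild_type"))
        sprintf(", delta %+.2f vs reference", b$delta) else "",
      if (!is.null(b$impact)) paste0(" -- ", b$impact) else ""))
  }
  paths$txt <- file.path(out_dir, "report.txt")
  writeLines(txt, paths$txt)

  # -- machine-readable JSON (no wall-clock fields: byte-stable)
  json_bundles <- bundles
  json_bundles$class <- as.character(json_bundles$class)
  json_bundles$sequence <- NULL
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    job = list(id = manifest$id, mode = manifest$mode,
               inputs = manifest$inputs,
               position = manifest$position),
    params = unclass(params),
    scores = json_bundles)
  paths$json <- file.path(out_dir, "report.json")
  # 17 significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)

  # -- input sequences
  paths$fasta <- file.path(out_dir, "inputs", "sequences.fasta")
  write_fasta(bundles[, c("id", "sequence")], paths$fasta)

  # -- chart (convenience output; JSON is the contract)
  paths$png <- file.path(out_dir, "scores.png")
  ok <- tryCatch({
    p <- plot_scores(bundles, params = params)
    ggplot2::ggsave(paths$png, p, width = 7,
                    height = 4 + 0.1 * nrow(bundles), dpi = 120)
    TRUE
  }, error = function(e) {
    warn(sprintf("chart rendering skipped: %s", conditionMessage(e)))
    FALSE
  })
  if (!ok) paths$png <- NULL

  if (zip) {
    zip_path <- file.path(out_dir, "report.zip")
    status <- tryCatch(
      utils::zip(zip_path, unlist(paths), flags = "-jq9X"),
      error = function(e) -1L, warning = function(w) -1L)
    if (identical(status, 0L)) paths$zip <- zip_path
    else warn("zip archive skipped: no working zip tool")
  }
  invisible(paths)
}

#' Run compare mode end to end
#'
#' The reference-versus-variants mode: reads a single-record reference FASTA
#' and a (multi-)FASTA of variants, validates every record, scores them with
#' [compare_sequences()] and renders the report bundle.
#'
#' @param ref_file FASTA with exactly one reference record.
#' @param variants_file FASTA with one or more variant records.
#' @param out_dir Output directory.
#' @param params A [combination_params()] object.
#' @param zip Also produce a zip archive.
#' @param ... Passed on to [score_proteins()].
#' @return Invisibly, a list with `status` (0 on success), `scores` (the
#'   scored tibble), `manifest` and `paths`. Validation failures abort with
#'   an error naming the record and rule; a multi-record reference file is a
#'   usage error.
#' @export
run_compare <- function(ref_file, variants_file, out_dir,
                        params = combination_params(), zip = FALSE, ...) {
  reference <- read_fasta(ref_file)
  if (nrow(reference) != 1L) {
    abort(sprintf("reference file '%s' must hold exactly one record, found %d",
                  ref_file, nrow(reference)),
          class = "prionscore_usage_error")
  }
  variants <- read_fasta(variants_file)
  validate_proteins(reference)
  validate_proteins(variants)
  scores <- compare_sequences(reference, variants, params = params, ...)
  manifest <- run_manifest("compare", c(ref_file, variants_file))
  paths <- render_report(scores, manifest, out_dir, params = params, zip = zip)
  invisible(list(status = 0L, scores = scores, manifest = manifest,
                 paths = paths))
}

#' Run single-mutation scan mode end to end
#'
#' Reads a single-record FASTA, evaluates all 19 substitutions at
#' `position` with [single_mutation_scan()], writes the 19 generated mutant
#' records as `mutants.fasta`, and renders the report bundle.
#'
#' @param seq_file FASTA with exactly one record.
#' @param position 1-based residue position to scan.
#' @param out_dir Output directory.
#' @param params A [combination_params()] object.
#' @param zip Also produce a zip archive.
#' @param ... Passed on to [score_proteins()].
#' @return Invisibly, a list with `status`, `scores` (20-row tibble),
#'   `manifest` and `paths` (including `mutants`).
#' @export
run_scan <- function(seq_file, position, out_dir,
                     params = combination_params(), zip = FALSE, ...) {
  protein <- read_fasta(seq_file)
  if (nrow(protein) != 1L) {
    abort(sprintf("scan mode requires exactly one record in '%s', found %d",
                  seq_file, nrow(protein)),
          class = "prionscore_usage_error")
  }
  validate_proteins(protein)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > protein$length) {
    abort(sprintf("position %s is outside sequence '%s' (length %d)",
                  position, protein$id, protein$length),
          class = "prionscore_usage_error")
  }
  scores <- single_mutation_scan(protein, position, params = params, ...)
  manifest <- run_manifest("scan", seq_file, position = position)
  paths <- render_report(scores, manifest, out_dir, params = params, zip = zip)
  mutants <- scores[scores$role == "variant", c("id", "sequence")]
  paths$mutants <- file.path(out_dir, "mutants.fasta")
  write_fasta(mutants, paths$mutants)
  invisible(list(status = 0L, scores = scores, manifest = manifest,
                 paths = paths))
}
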