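# FASTA I/O, validation and mutation construction. Parsing and writing go
# through Biostrings; everything downstream works on a plain tibble of
# records so results compose with dplyr verbs.

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-)FASTA file into a tibble of protein records. Sequence
#' lines are concatenated and upper-cased; the first whitespace-delimited
#' token of each header is the record id, the remainder its description
#' (preserved but unused). Ids must be unique within one file. Validation of
#' residues and length is a separate step ([validate_proteins()]) so that
#' files can be inspected before being rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, `length`,
#'   one row per record, in file order.
#' @seealso [write_fasta()], [validate_proteins()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(
      sprintf("'%s' is not readable as FASTA (no header line?): %s",
              path, conditionMessage(e)),
      class = "prionscore_format_error")
  )
  if (length(set) == 0L) {
    abort(sprintf("'%s' contains no FASTA records", path),
          class = "prionscore_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    abort("FASTA header with empty id", class = "prionscore_format_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("duplicate sequence id(s) in '%s': %s",
                  path, paste(dup, collapse = ", ")),
          class = "prionscore_input_error")
  }
  seqs <- toupper(as.character(set))
  tibble(id = ids, description = desc, sequence = unname(seqs),
         length = unname(nchar(seqs)))
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: writes `id` (plus `description`, when present)
#' headers and sequences wrapped at 60 columns.
#'
#' @param proteins Tibble with at least `id` and `sequence` columns.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  proteins <- as_protein_tbl(proteins)
  headers <- proteins$id
  if ("description" %in% names(proteins)) {
    has_desc <- nzchar(proteins$description %||% "")
    headers[has_desc] <- paste(proteins$id[has_desc],
                               proteins$description[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(proteins$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# coerce / sanity-check a protein record table
as_protein_tbl <- function(proteins, arg = "proteins") {
  if (is.character(proteins)) {
    proteins <- tibble(
      id = if (!is.null(names(proteins))) names(proteins)
           else paste0("seq", seq_along(proteins)),
      description = "",
      sequence = unname(toupper(proteins)))
  }
  if (!is.data.frame(proteins) ||
      !all(c("id", "sequence") %in% names(proteins))) {
    abort(sprintf("`%s` must be a tibble with 'id' and 'sequence' columns (see read_fasta())", arg))
  }
  proteins <- as_tibble(proteins)
  proteins$length <- nchar(proteins$sequence)
  proteins
}

# single-record variant of the above
one_protein <- function(protein, arg = "protein") {
  protein <- as_protein_tbl(protein, arg)
  if (nrow(protein) != 1L) {
    abort(sprintf("`%s` must contain exactly one record, got %d", arg, nrow(protein)))
  }
  protein
}

#' Validate protein records
#'
#' Enforces the scoring pipeline's input contract: each sequence must be at
#' least `min_length` residues long (default 60) and may contain only the 20
#' standard proteinogenic amino acids -- no ambiguity codes (B, J, O, U, X,
#' Z), digits or gap characters. Validation is idempotent and returns its
#' input unchanged so it can sit in a pipe.
#'
#' @param proteins Tibble of protein records (see [read_fasta()]).
#' @param min_length Minimum accepted sequence length.
#' @return `proteins`, unchanged, if every record passes; otherwise an error
#'   naming the offending record, rule, position and character.
#' @export
#' @examples
#' recs <- tibble::tibble(id = "p1", sequence = strrep("QNSG", 20))
#' validate_proteins(recs)
validate_proteins <- function(proteins, min_length = 60L) {
  proteins <- as_protein_tbl(proteins)
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    seq <- proteins$sequence[i]
    if (nchar(seq) < min_length) {
      abort(sprintf(
        "sequence '%s' is %d residues long; at least %d residues are required",
        id, nchar(seq), min_length),
        class = "prionscore_length_error")
    }
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    bad <- which(!(res %in% AA_ALPHABET))
    if (length(bad)) {
      abort(sprintf(
        "sequence '%s' contains non-standard character '%s' at position %d; only the 20 standard amino acids are allowed",
        id, res[bad[1]], bad[1]),
        class = "prionscore_alphabet_error")
    }
  }
  proteins
}

#' Parse a point-mutation string
#'
#' Accepts UniProt-style variant notation such as `"D290V"`: original
#' residue, 1-based position, replacement residue.
#'
#' @param spec Mutation string.
#' @return A one-row tibble with columns `from`, `position`, `to`.
#' @export
parse_mutation <- function(spec) {
  m <- regmatches(spec, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", spec))[[1]]
  if (length(m) != 4L) {
    abort(sprintf("cannot parse mutation '%s'; expected e.g. 'D290V'", spec))
  }
  out <- tibble(from = toupper(m[2]), position = as.integer(m[3]),
                to = toupper(m[4]))
  if (!(out$from %in% AA_ALPHABET) || !(out$to %in% AA_ALPHABET)) {
    abort(sprintf("mutation '%s' uses a non-standard residue", spec))
  }
  out
}

#' Apply a point mutation to a protein record
#'
#' Builds the variant record for a single substitution. The expected original
#' residue is checked against the sequence (guarding against off-by-one
#' position errors) and the record id is suffixed with the mutation notation,
#' e.g. `myseq_D290V`.
#'
#' @param protein One-row tibble of the wild-type record.
#' @param mutation Mutation string (`"D290V"`) or a one-row tibble as
#'   returned by [parse_mutation()].
#' @return One-row tibble for the variant; differs from the input sequence at
#'   exactly the mutated position.
#' @export
#' @examples
#' wt <- tibble::tibble(id = "p1", sequence = strrep("QNSG", 20))
#' apply_mutation(wt, "Q1M")
apply_mutation <- function(protein, mutation) {
  protein <- one_protein(protein)
  if (is.character(mutation)) mutation <- parse_mutation(mutation)
  pos <- mutation$position
  seq <- protein$sequence
  if (pos < 1L || pos > nchar(seq)) {
    abort(sprintf("position %d is outside sequence '%s' (length %d)",
                  pos, protein$id, nchar(seq)))
  }
  observed <- substr(seq, pos, pos)
  if (observed != mutation$from) {
    abort(sprintf(
      "sequence '%s' has '%s' at position %d, not '%s'",
      protein$id, observed, pos, mutation$from),
      class = "prionscore_mutation_error")
  }
  substr(seq, pos, pos) <- mutation$to
  out <- protein
  out$id <- paste0(protein$id, "_", mutation$from, pos, mutation$to)
  out$sequence <- seq
  out$length <- nchar(seq)
  out
}

#' Enumerate all substitutions at one position
#'
#' Generates the 19 single-residue variants of `protein` at a 1-based
#' `position` (every standard residue except the wild-type one), in
#' alphabetical order of the substituted residue. This is the variant set
#' behind the saturation scan.
#'
#' @param protein One-row tibble of the wild-type record.
#' @param position 1-based residue position.
#' @return A 19-row tibble of variant records, each differing from `protein`
#'   at exactly `position`.
#' @seealso [single_mutation_scan()]
#' @export
enumerate_substitutions <- function(protein, position) {
  protein <- one_protein(protein)
  if (position < 1L || position > nchar(protein$sequence)) {
    abort(sprintf("position %d is outside sequence '%s' (length %d)",
                  position, protein$id, nchar(protein$sequence)))
  }
  wt <- substr(protein$sequence, position, position)
  subs <- setdiff(AA_ALPHABET, wt)
  purrr::map(subs, function(aa) {
    apply_mutation(protein, tibble(from = wt, position = position, to = aa))
  }) |> list_rbind()
}
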