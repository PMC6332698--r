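#!/usr/bin/env Rscript
# Populate inst/extdata/anchors/anchors.fasta with the anchor variant
# sequences listed in published_scores.tsv. Requires network access to
# UniProt; run from the package root. Variant records are built by applying
# the listed substitution to the downloaded canonical sequence, so position
# conventions should be checked against the isoform actually intended.

suppressMessages(library(prionscore))

anchor_dir <- file.path("inst", "extdata", "anchors")
tab <- utils::read.table(file.path(anchor_dir, "published_scores.tsv"),
                         header = TRUE, sep = "\t", comment.char = "#",
                         na.strings = "NA", stringsAsFactors = FALSE)

fetch_uniprot <- function(accession) {
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  tf <- tempfile(fileext = ".fasta")
  utils::download.file(url, tf, quiet = TRUE)
  read_fasta(tf)
}

wt_cache <- new.env()
records <- lapply(seq_len(nrow(tab)), function(i) {
  acc <- tab$accession[i]
  if (is.null(wt_cache[[acc]])) wt_cache[[acc]] <- fetch_uniprot(acc)
  wt <- wt_cache[[acc]]
  rec <- if (is.na(tab$variant[i])) wt else apply_mutation(wt, tab$variant[i])
  rec$id <- tab$id[i]
  rec$description <- sprintf("anchor variant of %s", acc)
  rec
})

out <- do.call(rbind, records)
write_fasta(out, file.path(anchor_dir, "anchors.fasta"))
cat(sprintf("wrote %d anchor records to %s\n", nrow(out),
            file.path(anchor_dir, "anchors.fasta")))
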