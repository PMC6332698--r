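test_that("synthetic PrLD generation is seed-deterministic and composition-faithful", {
  a <- generate_synthetic_prld(120, seed = 601)
  b <- generate_synthetic_prld(120, seed = 601)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence,
                         generate_synthetic_prld(120, seed = 602)$sequence))
  # generation does not disturb the caller's RNG stream
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(generate_synthetic_prld(100, seed = 601))
  expect_identical(runif(1), before)
  # law of large numbers: 10,000-residue sample within 1% per residue
  big <- generate_synthetic_prld(10000, seed = 603)
  freq <- table(factor(strsplit(big$sequence, "")[[1]], levels = AA)) / 10000
  expect_true(all(abs(as.numeric(freq) - unname(prld_composition())) < 0.01))
  expect_error(generate_synthetic_prld(50), "at least 60")
  badf <- prld_composition(); badf["Q"] <- badf["Q"] + 0.1
  expect_error(generate_synthetic_prld(100, composition = badf), "summing to 1")
})

test_that("an embedded amyloidogenic core raises the amyloid term over its core-free twin", {
  core <- "IVIVFYIVLVIVFYIVLVIVF"
  plain <- generate_synthetic_prld(120, seed = 604, id = "plain")
  seeded <- generate_synthetic_prld(120, seed = 604, id = "seeded", core = core)
  expect_equal(nchar(seeded$sequence), 120L)
  expect_match(seeded$sequence, core, fixed = TRUE)
  s_plain <- amyloid_core(plain)$score
  s_core <- amyloid_core(seeded)$score
  expect_gt(s_core, s_plain)
  expect_error(generate_synthetic_prld(60, core = strrep("I", 80)), "fit")
})

test_that("compare mode writes the full report bundle and self-delta of zero", {
  dir <- withr::local_tempdir()
  ref <- generate_synthetic_prld(100, seed = 605, id = "refseq")
  ref_file <- file.path(dir, "ref.fasta")
  write_fasta(ref, ref_file)
  var_file <- file.path(dir, "vars.fasta")
  write_fasta(dplyr::bind_rows(
    ref |> dplyr::mutate(id = "self"),
    apply_mutation(ref, paste0(substr(ref$sequence, 40, 40), "40I"))), var_file)
  out_dir <- file.path(dir, "out")
  res <- run_compare(ref_file, var_file, out_dir)
  expect_equal(res$status, 0L)
  expect_equal(res$scores$delta[res$scores$id == "self"], 0)
  expect_true(file.exists(file.path(out_dir, "report.txt")))
  expect_true(file.exists(file.path(out_dir, "report.json")))
  expect_true(file.exists(file.path(out_dir, "inputs", "sequences.fasta")))
  # JSON round-trips every score at full precision
  parsed <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$scores$score, res$scores$score, tolerance = 1e-15)
  expect_equal(parsed$schema_version, "1.0")
  # the written FASTA is parseable by the package's own reader
  expect_equal(read_fasta(file.path(out_dir, "inputs", "sequences.fasta"))$id,
               res$scores$id)
})

test_that("compare mode rejects bad usage with informative errors", {
  dir <- withr::local_tempdir()
  ref <- generate_synthetic_prld(100, seed = 606, id = "r1")
  two <- dplyr::bind_rows(ref, ref |> dplyr::mutate(id = "r2"))
  two_file <- file.path(dir, "two.fasta")
  write_fasta(two, two_file)
  ok_file <- file.path(dir, "ok.fasta")
  write_fasta(ref, ok_file)
  expect_error(run_compare(two_file, ok_file, file.path(dir, "o1")),
               class = "prionscore_usage_error")
  short_file <- file.path(dir, "short.fasta")
  writeLines(c(">tiny", strrep("Q", 59)), short_file)
  expect_error(run_compare(ok_file, short_file, file.path(dir, "o2")),
               "59", class = "prionscore_length_error")
})

test_that("scan mode writes 19 mutants and is byte-identical across reruns", {
  dir <- withr::local_tempdir()
  seq_file <- file.path(dir, "seq.fasta")
  write_fasta(generate_synthetic_prld(90, seed = 607, id = "scanme"), seq_file)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  r1 <- run_scan(seq_file, 45, out1)
  r2 <- run_scan(seq_file, 45, out2)
  expect_equal(r1$status, 0L)
  expect_equal(nrow(r1$scores), 20L)
  muts <- read_fasta(file.path(out1, "mutants.fasta"))
  expect_equal(nrow(muts), 19L)
  # byte-identical machine reports and mutant FASTA
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_identical(readLines(file.path(out1, "mutants.fasta")),
                   readLines(file.path(out2, "mutants.fasta")))
  # cross-mode consistency: scan wild-type row equals compare self-row
  ref <- read_fasta(seq_file)
  self <- compare_sequences(ref, ref)
  expect_equal(r1$scores$score[1], self$score[2])
  expect_error(run_scan(seq_file, 95, file.path(dir, "bad")),
               class = "prionscore_usage_error")
})

test_that("manifests derive their identifier from input content", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fasta")
  write_fasta(generate_synthetic_prld(80, seed = 608), f1)
  m1 <- run_manifest("compare", c(f1, f1))
  m2 <- run_manifest("compare", c(f1, f1))
  expect_identical(m1$id, m2$id)
  f2 <- file.path(dir, "b.fasta")
  write_fasta(generate_synthetic_prld(80, seed = 609), f2)
  expect_false(identical(run_manifest("compare", c(f1, f2))$id, m1$id))
  expect_error(run_manifest("scan", f1), "position")
})

test_that("score charts build with class colours and threshold guides", {
  ref <- generate_synthetic_prld(90, seed = 610, id = "w")
  scores <- compare_sequences(ref, enumerate_substitutions(ref, 45)[1:3, ])
  p <- plot_scores(scores)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(scores), "ggplot")
  prof <- foldindex_profile(ref)
  expect_s3_class(plot_profile(prof), "ggplot")
})
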