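# prionscore

Mutation-impact scoring for prion-like protein aggregation.

About 1% of human proteins carry a prion-like domain (PrLD) — an
intrinsically disordered, low-complexity region resembling yeast prion
domains. Point mutations in PrLDs (hnRNPA1, hnRNPA2, hnRNP DL, TDP-43, …)
can convert dynamic liquid-like assemblies into solid amyloid aggregates,
causing ALS, multisystem proteinopathy and related disorders. `prionscore`
is for researchers who want to rank such variants in silico: it scores each
sequence by blending a composition-based prion propensity with a localized
amyloid-core score, and reads a mutation's impact off the difference
between variant and reference scores.

## The score

For a validated sequence (≥ 60 residues, 20 standard amino acids) the
combined score is

    S = max( floor,  w_c · (c − c₀)/c_s  +  w_a · (a − a₀)/a_s )

* **c — composition term**: per-residue prion propensities (a
  Sup35-mutagenesis-derived scale) averaged over 41-residue windows, then
  averaged again across neighbouring windows; the maximum is taken over
  windows predicted disordered by a FoldIndex-style index
  `2.785·⟨H⟩ − |⟨q⟩| − 1.151` (Kyte–Doolittle hydropathy rescaled to
  [0, 1]; K/R = +1, D/E = −1).
* **a — amyloid term**: every 21-residue stretch scored by the mean of its
  16 overlapping hexapeptide scores under a 6×20 position-specific scoring
  matrix, min–max normalised to 0–100; by default the search runs inside
  the disordered region around the composition argmax.
* Classification: **low** if S < 0.45, **high** if S > 0.78, **increased**
  in between. Scores above 1.0 are possible and flag sequences beyond the
  most aggregation-prone calibration variant.

Default weights/normalisations are the package's documented calibration
choice (`combination_params()`); `calibrate_params()` refits them against
any anchor set with published scores. The shipped hexapeptide matrix is a
clearly-labelled synthetic stand-in (see
`vignettes/scoring-prion-like-mutations.Rmd`); a published matrix can be
dropped in via `read_amyloid_matrix()` without code changes.

## Worked example

```r
library(prionscore)
library(dplyr)

wt      <- generate_synthetic_prld(120, seed = 7, id = "wt")
variant <- generate_synthetic_prld(120, seed = 7, id = "core_variant",
                                   core = "IVIVFYIVLVIVFYIVLVIVF")

compare_sequences(wt, variant) |>
  select(id, composition, amyloid, score, class, delta)
#> # A tibble: 2 × 6
#>   id           composition amyloid score class delta
#>   <chr>              <dbl>   <dbl> <dbl> <fct> <dbl>
#> 1 wt                0.0102    64.7 0.425 low    0
#> 2 core_variant      0.132     66.6 1.65  high   1.23
```

The wild-type Q/N-rich domain sits just below the low threshold
(score 0.43). Embedding a hydrophobic 21-mer core raises both terms and
lifts the variant deep into the high class; `delta = +1.23` is the
predicted mutation impact.

```r
single_mutation_scan(wt, 21) |>
  filter(delta != 0) |> arrange(desc(delta)) |> head(3) |>
  select(substitution, score, class, delta)
#> # A tibble: 3 × 4
#>   substitution score class delta
#>   <chr>        <dbl> <fct> <dbl>
#> 1 P21F         0.953 high  0.528
#> 2 P21I         0.947 high  0.521
#> 3 P21V         0.946 high  0.520
```

Replacing the proline at position 21 with an aromatic or β-branched
residue pushes the wild type from *low* to *high* — prolines are strong
aggregation gatekeepers, and the scan quantifies that.

A shell front end mirrors the two analysis modes and writes a report
bundle (`report.txt`, schema-versioned `report.json`, `scores.png`,
input/mutant FASTA):

```sh
exec/prionscore compare --ref ref.fasta --variants vars.fasta --out results/
exec/prionscore scan    --seq  seq.fasta --pos 290           --out results/
```

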