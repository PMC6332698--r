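---
title: "Scoring mutation impact on prion-like protein aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mutation impact on prion-like protein aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionscore)
library(dplyr)
```

## The problem

Roughly 1% of human proteins carry a prion-like domain (PrLD): an
intrinsically disordered, low-complexity region compositionally similar to
yeast prion domains. Point mutations in PrLDs can tip proteins such as the
hnRNP family from dynamic, liquid-like assemblies into solid amyloid
aggregates, with direct disease relevance. Two sequence signals are known to
matter: the *overall composition* of the disordered region, and the presence
of a short, localized *amyloid-nucleating core*. A predictor using either
signal alone misses variants that the other catches; `prionscore` blends
both into one calibrated score per sequence, so the effect of a mutation is
read off as the difference between variant and reference scores.

## The model

For a validated sequence (at least 60 residues, standard amino acids only)
the combined score is

$$S = \max\!\left(\mathrm{floor},\;
      w_c\,\frac{c - c_0}{c_s} + w_a\,\frac{a - a_0}{a_s}\right)$$

with classification *low* for $S < 0.45$, *high* for $S > 0.78$, and
*increased* in between (both thresholds belong to the middle class: the
low/high bands are defined by strict inequalities).

### Composition term $c$

Each residue is assigned a prion propensity from a scale derived from
mutagenesis of the Sup35 yeast prion domain (shipped as
`propensity_scale()`). The per-residue track is averaged over 41-residue
windows, and the window scores are averaged again over a 41-window
neighbourhood — this double averaging demands that a favourable stretch sit
in a favourable neighbourhood, which is what distinguishes genuinely
prion-prone regions from isolated lucky windows. Candidate windows are
restricted to those predicted *disordered* by a FoldIndex-style track
computed over the same windows:

$$\mathrm{FI} = 2.785\,\langle H\rangle - |\langle q\rangle| - 1.151$$

where $\langle H\rangle$ is the window-mean Kyte–Doolittle hydropathy
rescaled to $[0,1]$ and $\langle q\rangle$ the window-mean net charge
(K, R = +1; D, E = −1). Negative values predict disorder. The composition
term is the maximal doubly-averaged propensity over disordered windows.

Numerical and edge choices, fixed once and used everywhere:

* **Only full windows are scored** — no truncated edge windows in the first
  pass; the 60-residue minimum guarantees at least 20 of them at $w = 41$.
* **Second-pass edges shrink symmetrically** so every first-pass window
  receives a second-pass value and the profile keeps its length;
  `edges = "strict"` restricts to full second-pass windows instead
  (returning `NA` at the edges) for users who prefer the conservative
  variant. The symmetric shrink keeps windows centred, so a constant track
  is reproduced exactly at any position.
* **No-disorder fallback**: if no window passes the gate, the term falls to
  the scale minimum and the result is flagged (`all_ordered`). The method
  targets disordered PrLDs; a fully ordered protein is outside its domain
  but still gets a defined, conservative value.
* **Argmax ties break to the lowest sequence position.** Windows whose
  scores differ by less than $10^{-9}$ are treated as tied: cumulative-sum
  windowing leaves $\sim 10^{-16}$ wobble between mathematically equal
  windows (homopolymers are the extreme case) and must not override the
  tie-break.

### Amyloid term $a$

Every 21-residue window is scored by the *mean* of its 16 overlapping
hexapeptide scores under a position-specific scoring matrix (6 positions ×
20 residues); the maximum over windows is min–max normalised to $[0, 100]$
against the matrix's stored anchors (its minimum and maximum achievable
hexapeptide sums). Using the mean rather than the sum keeps core scores
comparable across core lengths; storing the anchors in the matrix file keeps
normalised scores stable across matrix revisions. By default the search is
*coupled* to the composition step — it runs inside the contiguous disordered
region containing the composition argmax, because amyloid cores of interest
are those inside the PrLD — and falls back to the whole sequence when the
gate leaves no region. `couple_region = FALSE` always searches the whole
sequence; both behaviours are exposed because the choice of search region is
a genuine modelling decision, not a formula.

The shipped matrix (`amyloid_matrix()`) is a **synthetic stand-in**,
constructed from the canonical beta-aggregation propensity ordering of the
residues (I/V/F/Y/W/L favourable; P/K/E/D/G unfavourable) with asymmetric
position weights (central hexapeptide positions count more, proline is
penalised extra mid-core, glycine is tolerated at the ends). It reproduces
the qualitative behaviour of published amyloid hexapeptide matrices —
hydrophobic/aromatic cores score high, charged and proline-rich stretches
score low, reversal of an asymmetric hexapeptide changes its score — but
absolute values are not comparable to any published predictor. A user
holding a published matrix drops it in via `read_amyloid_matrix()`; every
scoring function accepts it as an argument, and no code changes.

### Combination parameters

| parameter | default | meaning |
|---|---|---|
| $w_c, w_a$ | 0.5, 0.5 | weights of the two terms |
| $c_0, c_s$ | 0, 0.05 | composition normalisation: the classic 0.05 composition-score decision threshold maps to 1 |
| $a_0, a_s$ | 0, 100 | amyloid normalisation: the 0–100 core score maps to $[0,1]$ |
| floor | 0 | lower clamp; firing is flagged (`floored`) |
| $\theta_{low}, \theta_{high}$ | 0.45, 0.78 | class thresholds |

The defaults are this package's documented calibration choice: with them, a
sequence at the composition decision threshold carrying a mid-range core
scores near the middle of the low/high band, strongly prion-promoting
sequences exceed 1.0, and the zero floor reproduces the exact-zero scores
expected of non-prionic, fully ordered wild types. Published predictors in
this family normalise the composition term either by a fixed decision
threshold or by the scale range; we take the former and let
`calibrate_params()` absorb the residual scale freedom into the weights, so
the choice is recoverable from data rather than hard-coded.

### Calibration

`calibrate_params()` refits any subset of $\{w_c, w_a\}$ by ordinary least
squares of published anchor scores on the normalised terms (closed-form
normal equations; deterministic). Two details matter:

* **Floor-clamped anchors are excluded from the fit.** An anchor published
  at exactly the floor (the typical non-prionic wild type) tells us only
  that the linear predictor was at or below the floor — an inequality, not
  a point. Including it would bias the weights; it stays in the output
  table flagged `in_fit = FALSE`.
* **Anchor panels must span both terms.** With anchors that vary only in
  composition, the amyloid column of the design matrix is nearly constant
  and the weights are ill-determined — exactly the behaviour seen with
  panels of plain background draws. The experimentally validated variant
  series this procedure models span the score range by construction, so the
  package's test panels do the same: 21-mer cores of graded amyloidogenicity
  (Q/N/S/G → I/V/F/Y gradient) embedded in Q/N-rich backgrounds.

## The synthetic-data generator

`generate_synthetic_prld()` samples sequences from a Q/N-rich residue
frequency table (`prld_composition()`: Q = N = 0.18, G = 0.12, S = 0.10,
Y = P = 0.06, near-zero hydrophobics, charge and cysteine) modelled on the
biased, low-complexity composition of yeast prion domains, optionally
embedding a fixed 21-mer core. It emulates the two features the scorer
reads — disordered, prion-biased composition and a localized amyloidogenic
stretch — and is seed-deterministic without touching the caller's RNG.

What it does **not** emulate: real PrLD boundary structure (flanking folded
domains), positional composition gradients, oligopeptide repeats, and
correlated residue order generally (draws are i.i.d.). Passing tests
therefore demonstrate algorithmic correctness and statistical behaviour of
the pipeline under realistic composition, not predictive accuracy on real
proteomes — that validation requires the published anchor sequences (see
`tools/fetch_anchors.R`) and a published amyloid matrix.

## Worked example

```{r example}
wt <- generate_synthetic_prld(120, seed = 7, id = "wt")
variant <- generate_synthetic_prld(120, seed = 7, id = "core_variant",
                                   core = "IVIVFYIVLVIVFYIVLVIVF")
compare_sequences(wt, variant) |>
  select(id, composition, amyloid, score, class, delta)
```

The embedded hydrophobic 21-mer raises the amyloid term and lifts the
variant's combined score; the `delta` column carries the mutation impact.

```{r scan}
scan <- single_mutation_scan(wt, 21)
scan |> filter(delta != 0) |> arrange(desc(delta)) |> head(3) |>
  select(substitution, score, class, delta)
```

## Problem sizes and test design

The package's own verification uses: 200 random fixtures of length 60–200
for oracle equivalence of both windowed scores (brute-force enumeration of
every window and hexapeptide, agreement within $10^{-12}$, identical argmax
positions); 20-anchor panels over 100 seeded replicates for calibration
behaviour under additive Gaussian noise ($\sigma = 0.05$); a
10,000-residue draw for generator composition fidelity (within 1% per
residue); and byte-identity of repeated scan-mode machine reports. These
sizes make the whole suite run in about a minute while leaving the
statistical checks well-powered.

## Known limitations

* The shipped amyloid matrix is synthetic (above); absolute combined scores
  are internally consistent but not comparable to published server scores
  until a published matrix and calibrated weights are supplied.
* Only single-sequence, single-chain protein input; no nucleotides,
  ambiguity codes, alignments, or alternative disorder predictors.
* The disorder gate and the composition scale are fixed package data;
  swapping them is configuration, but no other disorder model is bundled.
* Insertions and deletions are compared as whole sequences via
  `compare_sequences()`; `single_mutation_scan()` covers substitutions
  only.
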