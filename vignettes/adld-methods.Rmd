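---
title: "ADLD: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADLD: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adld)
```

## The model

ADLD analysis treats a protein sequence pair as a numeric dot plot. Its
premise is that a single well-chosen real number per amino acid preserves
enough physicochemical identity to make exact-match diagonal structure
meaningful, while keeping the whole comparison free of alignment algorithms
and substitution matrices.

### Per-residue scores

The 20 amino acids are summarized by 9 properties (molecular weight,
hydropathy index, the two terminal pKa values, isoelectric point,
solubility, codon multiplicity, frequency in human proteins, van der Waals
radius). Treating amino acids as samples and properties as variables, the
20×9 matrix is column-standardized, the 9×9 Pearson correlation matrix is
eigendecomposed, and components are retained until the accumulated
contribution rate reaches the 85% threshold — four components here
(ACR₄ = 0.8588). The total score of amino acid *i* collapses its four
component scores with the contribution rates as weights:

$$\mathrm{TotalScore}_i = \sum_{k=1}^{t} (x^*_i \cdot a_k)\,\mathrm{CR}_k .$$

```{r}
fit <- aa_pca()
fit$n_retained
round(fit$total_scores, 4)
```

Two numerical conventions matter and are fixed in the package:

* **Standardization divisor.** Column variances use the sample divisor
  (m − 1 = 19). This choice does not affect the correlation matrix or its
  spectrum, but it scales the component scores; the divisor-19 variant is
  the one that reproduces the published 4-dp score table, which the test
  suite asserts in full.
* **Eigenvector sign.** Eigenvectors are defined only up to sign; each is
  normalized so its largest-magnitude entry is positive. With the property
  data the dominant loadings (0.5036 on mW, 0.6464 on pI, 0.6298 on pK1,
  0.6547 on hI) are then all positive. Eigenvalue ties would be ordered by
  the first differing eigenvector component after normalization; the actual
  spectrum is simple, so this rule exists purely for determinism.

All 20 scores are pairwise distinct (also after 4-dp rounding), which is
what makes exact matching at ε = 0 equivalent to residue identity.

### The diagram

For an encoded pair with lengths N₁ ≥ N₂ and band half-width
w = ξ (widened to N₁ − N₂ when the length difference exceeds ξ), the point
(i, j) is an alignment plot when |t_i − t_j| ≤ ε. Maximal runs of at least
δ consecutive diagonal points form similar fragments; main-diagonal points
left outside every fragment are free points. The similarity degree
SD = Σ fragment lengths + #free points feeds the distance
s_ij = 1 − min(1, d_ij/d_ii).

```{r}
d <- adld("MTMHTTMTTL", "MTMYATMTTL")
summary(d)
```

## Tunable parameters

| parameter | meaning | units | default | rationale |
|---|---|---|---|---|
| ε | score tolerance for a match | score units | 0 | exact identity; any ε below the smallest gap between two scores (≈ 0.018) behaves identically |
| δ | minimum fragment length | points | 3 | the smallest value that suppresses isolated coincidences; long sequences warrant larger δ (the spike-protein analyses use 5) |
| ξ | band half-width threshold | positions | 10 | recommended floor; the published β-globin diagrams use 12 and 16, so ξ is always user-settable |

δ = 1 degenerates the diagram into the raw scatter plot (every point is a
fragment, no free points). ε is compared at full floating precision; at
ε = 0 this is exact equality, which is safe because both sequences draw
scores from the same 20-value table.

## Numerical and design choices

* **Padding.** Equalizing lengths conceptually pads the shorter sequence;
  a literal zero pad could spuriously match real scores once ε > 0, so
  padded positions never generate points (enforced as j ≤ N₂). At ε = 0 the
  two readings coincide because no total score equals 0.
* **Coordinates** are 1-based inclusive in every report and plot. The track
  offset is o = j − i, so tracks below the main diagonal carry negative
  offsets (an insertion of k residues in the longer sequence shifts the
  suffix to offset −k).
* **Consecutive** means unit diagonal steps with no gap tolerance; maximal
  runs on one track can neither overlap nor tie, so no tie-breaking is
  needed.
* **Pair ordering.** The longer sequence is first; equal lengths are
  ordered lexicographically by id, so results are reproducible regardless
  of argument order (swapping an equal-length pair exactly mirrors the
  diagram, which the tests check).
* **Self-degree.** d_ii is computed by running the full diagram of a
  sequence against itself — internal repeats genuinely contribute by-path
  fragments — never shortcut to the sequence length.
* **Asymmetric normalization.** The distance divides by the *row*
  sequence's self-degree, exactly as defined; a symmetric variant dividing
  by min(d_ii, d_jj) is available behind an explicit `normalize = "min"`
  option and is clearly flagged as an extension.
* **Degenerate inputs.** A constant property column, an all-zero spectrum,
  a zero self-degree and residues outside the 20-letter alphabet are all
  hard errors naming the offender; ambiguity codes can be dropped only by
  an explicit opt-in, because silently dropping positions changes the whole
  diagram geometry.
* **Banded evaluation.** The N₁×N₁ matrix is never materialized; points are
  evaluated per diagonal inside the band, O((2w+1)·N₁) time and memory.
  A full-matrix brute-force oracle (test code only) checks equivalence on
  hundreds of random pairs.

## Tree building

The published workflow delegates tree construction to external software
without fixing a method; the package provides standard Saitou–Nei neighbor
joining (via ape) on the mirrored lower triangle as a convenience, with
negative branch lengths clamped to zero. No claim is made of reproducing
any particular published tree figure node-for-node; the packaged reference
distance matrix for the 16 ND5 proteins is used only for a qualitative
check (gallus and opossum fall outside the placental clade). The Newick
writer quotes labels containing metacharacters or spaces, since the
standard writer in ape rewrites such labels.

## What the synthetic generator does and does not emulate

`random_sequence()` draws residues uniformly; `edit_recipe()` applies
controlled substitutions, insertions and deletions. This is deliberately
*not* an evolutionary model — no substitution-rate matrix, no indel length
distribution, no compositional bias. It exists to instantiate the method's
qualitative predictions as exact constructions: a block insertion of length
k moves the suffix fragment to track offset −k; a single substitution at
position q removes exactly the point (q, q) at ε = 0; substituting every
δ-th position leaves free points only. Passing these tests shows the
diagram machinery is correct, not that the distance is biologically
calibrated — real protein families have skewed composition and repeat
structure that uniform sequences lack.

## Problem sizes used in the checks

The test suite works at desk scale: the full 20-amino-acid scoring
pipeline, 10-residue worked pairs, random pairs of length ≤ 60 (240 of them
against the brute-force oracle), and collections of ≤ 6 sequences for the
distance-matrix properties. These sizes were chosen because every expected
value can be verified independently (by hand or by the oracle); the
implementation itself is banded and handles the published full-length use
cases (600-residue ND5, 1400-residue spike proteins) directly.

## Known limitations

* Distances are not additive tree metrics; neighbor joining on them is a
  visualization aid, not an estimator with guarantees.
* The lower-triangular distance definition is asymmetric for unequal
  self-degrees; only the documented row normalization matches the published
  definition.
* The 85% retention rule, the property set and their printed values are a
  fixed calibration: the scoring pipeline is not a general PCA API and
  user-supplied property tables are intentionally unsupported.
* The band threshold ξ used for the published full-length analyses is not
  stated; reproduction tests therefore scan ξ ∈ {10, 12, 16} and report
  the sensitivity instead of asserting a single value.
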