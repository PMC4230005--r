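# adld

Alignment-free similarity/dissimilarity analysis of protein sequences via
**Alignment Diagonal Line Diagrams** (ADLDs) — a graphical, dot-plot-style
representation of a sequence pair built on a PCA-derived numeric encoding of
the amino acids. It is aimed at researchers comparing homologous protein
sets (mitochondrial ND5 proteins, coronavirus spike proteins, globins, ...)
who want an intuitive pairwise picture plus a distance matrix they can feed
straight into tree building.

## The method

1. **Scoring.** Each of the 20 amino acids is described by 9 physicochemical
   properties (molecular weight mW, hydropathy index hI, pK1, pK2,
   isoelectric point pI, solubility S, codon count cN, frequency in human
   proteins F, van der Waals radius vR). The 20×9 matrix *X* is
   column-standardized to *X\**, its 9×9 Pearson correlation matrix *R* is
   eigendecomposed (λ₁ ≥ … ≥ λ₉, eigenvectors a₁…a₉), and the leading *t*
   components are kept — the smallest *t* whose accumulated contribution
   rate ACR_t = Σ_{k≤t} λ_k/Σλ reaches 85% (*t* = 4 here, ACR₄ = 0.8588).
   Each amino acid *i* then gets a single **total score**
   TotalScore_i = Σ_{k=1..t} (x*_i · a_k) · CR_k,
   a unique real number (e.g. M → 0.5735, G → −1.1780, W → 1.4729).
2. **Encoding.** A protein sequence Ψ = p₁…p_N becomes the numerical
   sequence S_Ψ = (t₁,…,t_N) by positionwise score substitution.
3. **Diagram.** For a pair (s₁, s₂) with N₁ ≥ N₂, a point (i, j) is an
   *alignment plot* (AP) when |t_i − t_j| ≤ ε inside the diagonal band
   |i − j| ≤ w, where w = ξ unless N₁ − N₂ > ξ (then w = N₁ − N₂).
   Maximal diagonal runs of ≥ δ consecutive APs are *similar fragments*
   (SFs); main-diagonal APs outside every fragment are *free points* (FPs).
   Fragments off the main diagonal reveal insertions/deletions; gaps on it
   reveal substitutions.
4. **Distance.** The *similarity degree* of a pair is
   SD = Σ fragment lengths + #FPs; over a collection this gives the
   matching matrix d_ij = SD(Ψ_i, Ψ_j) (lower triangle) and the
   similarity/dissimilarity matrix s_ij = 1 − min(1, d_ij/d_ii),
   with 0 = identical and 1 = nothing shared. A neighbor-joining tree can
   be built from the (symmetrized) matrix and written as Newick.

Defaults are ε = 0 (exact score identity), δ = 3, ξ = 10.

## Worked example

```r
library(adld)

round(aa_score_table()[c("M", "T", "H", "Y", "A")], 4)
#>       M       T       H       Y       A
#>  0.5735 -0.4525  0.4476  0.9050 -0.9324

d <- adld("MTMHTTMTTL", "MTMYATMTTL")   # epsilon = 0, delta = 3, xi = 10
d$fragments
#>   track_offset start_i start_j end_i end_j length
#> 1            0       1       1     3     3      3
#> 2            0       6       6    10    10      5
similarity_degree(d)
#> [1] 8

sm <- adld_distances(c(Hu = "MTMHTTMTTL", Gor = "MTMYATMTTL"))
sm$distances
#>      Hu Gor
#> Hu  0.0   0
#> Gor 0.2   0
```

The two sequences differ at positions 4 and 5, which splits the main
diagonal into fragments of length 3 and 5; SD = 8, and with a self-degree
of 10 the pair's distance is 1 − 8/10 = 0.2.

A command-line interface mirrors the R API
(`exec/adld scores|encode|pair|matrix|tree|synth`); e.g.
`adld matrix --fasta set.fa --out sm.csv --phylip sm.phy` then
`adld tree --matrix sm.csv --out tree.nwk`.

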