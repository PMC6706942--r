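---
title: "Proteome pI landscapes: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome pI landscapes: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Microbes adapted to marine, brackish, freshwater and hypersaline habitats
differ systematically in the charge of their proteomes: salt-adapted cells
accumulate intracellular cations and favor acidic protein surfaces, which
shows up as an excess of aspartate and glutamate (on the order of 0.6–1.4
Mole%) and a taller acidic peak in the distribution of protein isoelectric
points (pI); freshwater microbes shift the other way, toward neutral and
basic pIs. `piscape` implements the complete analytical chain for studying
this signal: a Henderson–Hasselbalch charge model and pI solver,
localization-stratified pI spectra, Bray–Curtis/PERMANOVA/PCA comparison of
pI profiles across habitats, a nearest-centroid habitat classifier,
reciprocal-best-hit proteome comparison (AAI, POCP, core/flexible
partition), and a seeded synthetic proteome generator that reproduces the
statistical structure of the habitat contrast so the whole pipeline runs,
and is tested, without any downloads.

```{r setup}
library(piscape)
```

## The charge model and the pI solver

Every ionizable group — the two chain termini plus the D, E, C, Y, H, K, R
side chains — contributes its Henderson–Hasselbalch fractional ionization to
the net charge at a given pH:

$$Q(\mathrm{pH}) \;=\; \sum_{g \in \text{basic}} \frac{n_g}{1+10^{\,\mathrm{pH}-pK_a(g)}}
\;-\; \sum_{g \in \text{acidic}} \frac{n_g}{1+10^{\,pK_a(g)-\mathrm{pH}}}.$$

$Q$ is strictly decreasing in pH whenever at least one ionizable group is
present, so the isoelectric point — the unique pH with $Q = 0$ — is found by
bisection on $[0, 14]$. The default tolerance is $10^{-3}$ pH units and
results are displayed to 2 decimals, matching the resolution at which
proteome pI spectra are usually plotted; the test suite checks the solver
against an independent 0.001-step grid search.

```{r}
net_charge("MKKDE", pH = c(4, 7, 10))
isoelectric_point("MKKDE")
```

Three pKa sets ship with the package. The default, `"emboss"`, mirrors the
constants of EMBOSS Pepstats (N-terminus 8.6, C-terminus 3.6, D 3.9, E 4.1,
C 8.5, Y 10.1, H 6.5, K 10.8, R 12.5), the tool classically used for
whole-proteome pI surveys, so that results are comparable with that
literature; `"bjellqvist"` and `"ipc_protein"` are provided because pI is a
pKa-set-dependent quantity and no single set is canonical. Ambiguity codes
(X, B, Z, J, U, O) are retained in sequences but treated as non-ionizable
and excluded from Mole% compositions: assembled-genome protein predictions
routinely contain them, and a deterministic convention matters more than
any particular guess about their chemistry. A peptide with no ionizable
side chains still carries its two termini, so the pI is always defined and
equals the terminal-pKa midpoint (6.10 under the EMBOSS set).

## Spectra, aggregates and peaks

`bin_spectrum()` bins pI values into half-open bins (last bin closed) of
width 0.25 over $[2, 14]$ by default. The width is a package choice: it
resolves the three canonical proteome peaks (near pI 4.5, 6.8 and 9.8) and
nests exactly inside the conventional aggregate windows — acid 3.25–6.25,
neutral 6.75–7.25, basic 7.75–13.75 — used by `acid_neutral_basic()`.
Aggregation is by bin-center membership with inclusive endpoints; since the
three windows deliberately leave gaps, the three fractions sum to at most 1.
At widths where a window boundary falls mid-bin the aggregation stops with
a configuration error rather than silently reapportioning mass; a boundary
that falls exactly on a bin center is included (this is what makes width
0.5, the other plausible plotting width, usable). pI values outside the
binning range — possible for extremely acidic proteins — are counted in the
nearest boundary bin so relative frequencies always sum to 1.

`peak_positions()` smooths with a 3-bin moving average, takes local maxima
(within a plateau of equal smoothed values, the bin with the largest raw
mass wins; ties go to the lowest pH), discards maxima below 10% of the
tallest peak — a noise floor chosen to sit well above the sampling ripples
of finite proteomes and well below any genuine secondary peak — and
suppresses peaks closer than 1 pH unit to a higher one.

## Localization

The analysis stratifies proteomes into secreted, transmembrane and
cytoplasmic/inner-membrane proteins, because the habitat signal differs by
compartment. External predictions from dedicated signal-peptide/TM tools
are the fidelity route and can be imported from a TSV
(`import_localization()`); `heuristic_localization()` is a deterministic,
download-free stand-in built on the Kyte–Doolittle scale (the single
hydropathy scale, hard-coded for determinism). A TM segment is called where
the 19-residue window mean stays at or above 1.6 over at least 19
consecutive window centers; a signal peptide needs at least one K/R in the
first 5 residues plus an 8-residue hydrophobic stretch inside the first 35 —
and that stretch must not itself be a full TM segment (if masking the first
35 residues removes a TM call, the protein is a membrane protein whose
first helix happens to start early, not a secreted one). Proteins with both
a signal peptide and downstream TM segments count as transmembrane: the
three categories are disjoint and membrane anchoring dominates the charge
environment. The heuristic is tuned for recall on clear-cut cases (the test
suite requires at least 0.9 on planted signals); its precision on random
cytoplasmic sequences is modest, which is acceptable for a stand-in whose
role is to keep the pipeline runnable when annotations are absent.

## Habitat statistics

Profiles are compared with the Bray–Curtis dissimilarity
$\sum_i |p_i-q_i| / \sum_i (p_i+q_i)$, which on relative-frequency vectors
is half the L1 distance. `permanova()` implements the one-way permutational
MANOVA decomposition on a distance matrix:
$SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
pseudo-$F = \frac{SS_A/(a-1)}{SS_W/(N-a)}$ and $R^2 = SS_A/SS_T$, with the
p-value from label permutations using the $(1+b)/(1+m)$ estimator — it never
returns exactly 0 and has resolution $1/(m+1)$. Only the one-way design is
implemented, run once per factor (habitat, then taxon), which is how the
two-factor question is usually reported for this kind of panel. Profiles
are relative frequencies that already sum to 1, and no further normalization
is applied by default; the test suite cross-checks pseudo-F and $R^2$
against `vegan::adonis2` and the permutation p against exhaustive
enumeration on a 6-object design.

`pca_profiles()` is an SVD of the column-centered profile matrix with a
fixed sign convention (largest-magnitude loading positive) so scores are
reproducible across eigen-solvers. `classify_habitat()` formalizes the
rule of thumb that the acid/neutral/basic balance identifies the habitat:
nearest centroid in (acid, neutral, basic)-fraction space under Euclidean
distance, ties broken to the lexicographically smaller label. The
3-component space, rather than the full spectrum, is the deliberate feature
choice: it matches how the habitat signature is described and keeps the
classifier interpretable.

## Pairwise genome comparison

`compare_pair()` contrasts two proteomes the way closely related
marine/freshwater neighbor genomes are compared. Candidate homologs are
preselected by a shared-5-mer filter (at least 2 exact 5-mers, which bounds
the all-vs-all cost at desk scale) and aligned with affine-gap local
Smith–Waterman under BLOSUM62 (gap open 11, extend 1; a length-$L$ gap
costs $11+L$). AAI is the unweighted mean identity over reciprocal best
hits, with each pair contributing the average of its two directional
identities so the statistic is symmetric in argument order. POCP follows
the standard definition — the fraction of both genomes' proteins with a
qualifying hit (e-value $< 10^{-5}$, identity $> 40$%, alignable region
$> 50$% of the query) — using an e-value proxy obtained from the raw score
via the Karlin–Altschul formula with fixed gapped-BLOSUM62 parameters
($\lambda = 0.267$, $K = 0.041$) and database size equal to the subject
proteome's residue count; the proxy is a documented package convention that
keeps the pipeline self-contained. For a two-genome comparison the
core/flexible partition is simply RBH membership — multi-genome clustering
adds no testable behavior at $n = 2$. Nucleotide ANI and 16S identity are
out of the protein-centric scope; `run_pair_analysis()` accepts them as
pass-through metadata so reports can carry them verbatim.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code: it defines the study conditions
under which every statistical property of the package is exercised.

* **Composition shifts.** `shift_composition()` moves Mole% onto the acidic
  pool {D, E} (marine signature) or the basic pool {K, R, H} (freshwater
  signature), paid for proportionally by the neutral polar pool
  {N, Q, S, T}. Drawing from the polar pool keeps hydrophobicity roughly
  unchanged, isolating charge — the effect under study — from the
  localization heuristics. The study condition for habitat contrasts is
  $\delta = 1.0$ Mole%, the middle of the 0.6–1.4 Mole% acidic excess
  reported for real marine/freshwater genome pairs. The halophile spec uses
  +3.5$\delta$ acidic combined with −2.5$\delta$ basic: the "salt-in"
  signature, which produces the expected single dominant acid peak.
* **Baseline.** The baseline composition is a documented constant table of
  typical prokaryotic residue frequencies; i.i.d. draws from it, plus the
  two terminal groups, are already enough to produce the characteristic
  bimodal pI spectrum (few proteins are ever near-neutral because a single
  charged residue moves a small protein's pI away from 7).
* **Lengths.** Log-normal with median 250 residues, sigma 0.45, minimum
  30 — plausible prokaryotic protein lengths; these are package constants,
  not claims about any particular dataset.
* **Planted localization signals.** `round(frac * n)` proteins receive an
  N-terminal signal peptide (Met, two K/R, short polar linker, 10-residue
  hydrophobic core) or 1–3 hydrophobic 21-mers over the {L, I, V, F}
  alphabet; ground-truth tables record every planted category so recall can
  be scored without re-derivation.
* **Orthologous pairs.** Shared proteins are generated in the "marine"
  proteome and re-sampled site-by-site with probability `mutation_rate`
  from the "freshwater" composition, biasing homologs toward the partner's
  residue usage while keeping identity recognizable (expected identity
  $\approx 1 - 0.93r$, since a redrawn site can coincide with the original
  residue). Sites inside planted membrane segments are redrawn from the
  hydrophobic alphabet, mimicking purifying selection on membrane spans.
  Secreted proteins can carry an extra habitat shift
  (`secreted_extra_delta`) and transmembrane proteins receive only
  `tm_shift_factor` (default 0.25) of it, reflecting that adaptation
  concentrates on water-exposed surfaces: with these two knobs the
  generated pairs reproduce the secreted > cytoplasmic > membrane ordering
  of the habitat effect. Without the damping factor the ordering inverts
  for membrane proteins, because their few ionizable residues make their pI
  disproportionately volatile under any composition drift — an instructive
  artifact of i.i.d. sequence models.
* **Cohorts.** Each proteome additionally receives a small log-normal
  composition jitter (sd 0.02) emulating genome-to-genome variability, and
  round-robin taxon labels that deliberately carry no compositional signal
  (so taxon acts as a negative-control factor).

What the generator does **not** emulate: phylogenetic correlation between
proteomes, codon/GC-driven composition biases, domain architecture, real
signal-peptide cleavage-site grammar, or any taxon-specific pI signature.
Passing tests therefore demonstrate that the pipeline recovers planted
charge structure of realistic magnitude from sequence data — not that real
habitats are classifiable at any particular accuracy, and not the
taxonomic component of pI variation seen in real panels.

## Numerical choices and degenerate inputs

* Bisection runs $\lceil \log_2(14/\mathrm{tol}) \rceil + 1$ iterations;
  charge curves that never cross zero inside $[0, 14]$ (possible only in
  side-chain-only mode or for extreme compositions) clamp to the boundary.
* Empty pI lists produce an explicit all-zero, zero-count spectrum rather
  than an error, so per-category spectra of proteomes lacking a category
  remain well-defined.
* Permutation p-values are bit-reproducible given (permutations, seed); all
  package randomness flows through a private RNG stream that saves and
  restores the caller's `.Random.seed`.
* RBH ties break by score, then lexicographic subject id; classifier ties
  break to the lexicographically smaller label; plateau peaks resolve to
  the largest raw-mass bin, then lowest pH. Every tie rule is deterministic
  across platforms.
* Single-member groups report SD as `NA` (unbiased $n-1$ estimator);
  PERMANOVA with zero within-group sum of squares reports an infinite
  pseudo-F and computes the p-value normally.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the statistical checks sharp while staying desk-scale:
1,000 random sequences for the pI-solver oracle; 500 replicates at 199
permutations for the PERMANOVA type-I study; 20 pairs of 240-protein
proteomes at per-site divergence 0.3 (the range implied by AAI values near
70% in real neighbor pairs) for the direction-of-effect study; cohorts of
20 proteomes per habitat with 300 proteins each, at 999 permutations, for
the power study; 100 null cohorts for the null study. Real proteomes are an
order of magnitude larger; since every statistic here concentrates with
sample size, the desk-scale results are the conservative case.

## Known limitations

* The pKa model ignores temperature, ionic strength, post-translational
  modifications and disulfide exclusion of cysteines; pI values are
  comparable within a pKa set, not across sets.
* The localization heuristic is not a substitute for trained
  signal-peptide/TM predictors; it has no concept of cleavage sites,
  lipoprotein signals or β-barrels. Import real predictions when available.
* The e-value proxy is calibrated for BLOSUM62 with gap 11/1 only.
* One-way PERMANOVA only: no interactions, strata or dispersion test.
* The two-genome core/flexible partition is not a pan-genome analysis.

## A complete run

```{r, eval = FALSE}
cohort <- generate_cohort(n_per_habitat = 20,
                          habitats = c("freshwater", "brackish",
                                       "marine", "halophile"),
                          delta = 1.0, n_proteins = 300, seed = 42)
res <- run_cohort_analysis(cohort$proteomes, cohort$metadata,
                           n_permutations = 999, seed = 42,
                           out_dir = "cohort_out")
res$permanova$habitat

pair <- generate_pair(n_shared = 200, n_unique_each = 40,
                      secreted_extra_delta = 1, mutation_rate = 0.3,
                      seed = 42)
compare_pair(pair$a, pair$b, pair$loc_a, pair$loc_b)
```
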