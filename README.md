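# piscape

Proteome isoelectric-point landscapes and habitat comparison for
prokaryotic genomes, MAGs and metaproteomes.

## The scientific problem

Aquatic microbes leave a habitat signature in the charge of their
proteomes. Salt-adapted (marine, and extremely so halophilic) cells favor
acidic protein surfaces — an excess of aspartate and glutamate on the order
of 0.6–1.4 Mole% relative to close freshwater relatives — which shifts the
distribution of protein isoelectric points (pI) toward the acidic peak;
freshwater microbes shift toward neutral and basic pIs. The effect is
visible at every level: whole metaproteomes, individual genomes, core and
flexible genes alike, and is sharpest in secreted proteins, intermediate in
cytoplasmic ones, and weakest in membrane proteins. `piscape` is for
microbial ecologists and comparative genomicists who want to compute,
compare and classify these pI landscapes from protein FASTA files.

At its core is the Henderson–Hasselbalch net-charge model. For a protein
with $n_g$ instances of ionizable group $g$ (the two chain termini plus
D, E, C, Y, H, K, R side chains):

$$Q(\mathrm{pH}) = \sum_{g\,\in\,\{\text{Nt},H,K,R\}} \frac{n_g}{1+10^{\mathrm{pH}-pK_a(g)}}
\;-\; \sum_{g\,\in\,\{\text{Ct},D,E,C,Y\}} \frac{n_g}{1+10^{pK_a(g)-\mathrm{pH}}}$$

$Q$ is strictly decreasing in pH, and the pI is its unique zero, found by
bisection to 0.001 pH units (default pKa set mirrors EMBOSS Pepstats).
Around this solver the package provides:

* **Spectra** — binned pI relative-frequency profiles (default 0.25-pH bins
  on [2, 14]), acid/neutral/basic aggregates over the conventional windows
  3.25–6.25 / 6.75–7.25 / 7.75–13.75, and peak detection.
* **Habitat statistics** — Bray–Curtis distances between profiles, one-way
  PERMANOVA (pseudo-F, R², permutation p), PCA, and a nearest-centroid
  habitat classifier in (acid, neutral, basic)-fraction space.
* **Localization stratification** — import of signal-peptide/TM predictions,
  plus a deterministic Kyte–Doolittle heuristic stand-in.
* **Pairwise genome comparison** — reciprocal-best-hit orthology from local
  BLOSUM62 alignments, AAI, POCP, core/flexible partition, per-category
  spectra and amino-acid composition deltas.
* **A synthetic proteome generator** — seeded proteomes, orthologous pairs
  and multi-habitat cohorts with controlled acidic/basic composition
  shifts and planted localization signals; it is the test bed for every
  statistical claim the package makes.

## A worked example

Sixty seconds, no downloads: generate a small two-habitat cohort, test the
habitat effect, and compare one marine/freshwater pair.

```r
library(piscape)

isoelectric_point("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
#> [1] 10.62...

cohort <- generate_cohort(n_per_habitat = 6,
                          habitats = c("freshwater", "marine"),
                          delta = 1.0, n_proteins = 200, seed = 42)
res <- run_cohort_analysis(cohort$proteomes, cohort$metadata,
                           factors = "habitat", n_permutations = 999,
                           seed = 42)
res$permanova$habitat
#> PERMANOVA: pseudo-F = 5.43, R2 = 0.3519, p = 0.002 (999 permutations, seed 42)

res$aggregate_stats
#>        group        component       mean         sd n
#> 1 freshwater    acid_fraction 0.31000000 0.05504544 6
#> ...
#> 4     marine    acid_fraction 0.52916667 0.05093296 6
```

The marine proteomes carry about 22 points more of their pI mass in the
acid window than the freshwater ones — the direction and rough magnitude of
the habitat signature the generator plants (a 1.0 Mole% D+E excess), and
the PERMANOVA confirms habitat structures the Bray–Curtis distances
(R² = 0.35, p = 0.002 here).

```r
pair <- generate_pair(n_shared = 60, n_unique_each = 12,
                      secreted_extra_delta = 1, mutation_rate = 0.3,
                      seed = 42)
cmp <- compare_pair(pair$a, pair$b, pair$loc_a, pair$loc_b)
cmp
#> Pair comparison: AAI 72.4% over 60 RBH pairs, POCP 83.3%
#>   core a/b: 60/60, flexible a/b: 12/12
#>   acid fraction a 0.486 vs b 0.417 (higher: a)
```

AAI ≈ 72% matches the planted per-site divergence of 0.3, all 60 shared
proteins are recovered as core, and the "marine" member (a) is the more
acidic one, as expected.

Real data enters through `read_proteome()` (protein FASTA, optionally
gzipped), `read_metadata()` (proteome/habitat/taxon TSV) and
`import_localization()` (signal-peptide/TM prediction TSV); the same
`run_cohort_analysis()` / `run_pair_analysis()` calls then apply unchanged.
See the vignette (`vignettes/proteome-pi-landscapes.Rmd`) for the model,
the generator's design and its limitations.

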