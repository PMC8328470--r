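# mhcbalance

Neutral forces, human-mediated introgression and balancing selection on MHC
variation in structured populations.

`mhcbalance` is an R package for researchers comparing putatively adaptive
(MHC class II) and neutral (microsatellite) variation across wild
populations — typically salmonids exposed to hatchery introgression, scored
at one multiallelic MHC locus, a panel of STR loci, a diagnostic biallelic
admixture marker (LDH-C1), and measured for weight and standard length. It
covers the full analysis chain:

* **Supertyping** — alleles are collapsed into functional classes by
  K-means clustering of physicochemical profiles (Sandberg z1–z5
  descriptors) at positively selected sites (PSS), with the number of
  clusters chosen by `BIC(K) = n log(WSS_K/n) + K log n`.
* **Diversity & structure** — rarefied allelic richness
  `R = Σᵢ (1 − C(N−nᵢ, g)/C(N, g))`, private variants, Ho/He, Monte-Carlo
  exact Hardy–Weinberg and permutation linkage tests with Holm–Bonferroni
  correction, Nei's G_ST plus the standardized small-k-corrected G″_ST,
  hierarchical AMOVA on allele-identity distances, and Mantel comparisons
  of MHC versus neutral differentiation matrices.
* **Historical selection** — Nei–Gojobori pairwise dN/dS with
  Jukes–Cantor correction, partitioned into PSS / non-PSS codon sets and
  tested one-tailed for dN > dS with a codon-bootstrap Z statistic; plus a
  randomization null (random allele-to-supertype lumping) for
  supertype-based population structure.
* **Contemporary balancing selection** — linear mixed models of Fulton's
  condition factor `K = 100·w/L³` on the within-population frequency of the
  carried MHC variants (rare-allele advantage), residualized zygosity
  (heterozygote advantage) and within-individual sequence dissimilarity
  (divergent-allele advantage), with population as a random intercept;
  AICc-ranked per-supertype carrier models; and across-population models of
  MHC richness on neutral richness and admixture with sequential
  regression.
* **Synthetic data** — a ground-truth generator (Balding–Nichols
  population frequencies, HWE genotypes, codon alignments with
  site-class-specific dN/dS, condition built from known coefficients) so
  the whole pipeline is testable offline.

## Worked example

Simulate a six-population dataset at the package defaults (156 individuals,
58-allele MHC pool, 11 STR loci, planted rare-allele advantage
β_freq = −0.15) and fit the allele-space condition model:

```r
library(mhcbalance)
scen <- sim_scenario(seed = 1)
sim  <- simulate_population_dataset(scen)
rec  <- condition_records(sim$table, catalog = sim$catalog)
fit_condition_model(rec, "1_DAB")
#> <fit_result> 1_DAB (n = 156)
#>             term estimate     SE    df     t       p
#> 1    (Intercept)   1.7000 0.1280  72.4 13.29 4.2e-21
#> 2     freq_index  -0.2260 0.0752  49.6 -3.00 4.2e-03
#> 3 zygosity_resid   0.0842 0.0642 134.6  1.31 1.9e-01
#> 4        str_het  -0.0165 0.1480 147.4 -0.11 9.1e-01
#> 5 ldh_typehybrid  -0.1610 0.0681 140.1 -2.36 2.0e-02
#> 6 ldh_typenative  -0.2100 0.0709 101.1 -2.96 3.8e-03
#> R2m = 0.131, R2c = 0.258, AICc = 42.48
```

The frequency-index estimate (−0.23, SE 0.08) recovers the planted −0.15
within sampling error in this single realization; a negative sign means
carriers of locally *rare* MHC variants are in better condition. Across
200 replicates the estimator is unbiased to within ±0.02 (see the
acceptance suite).

Across-population richness models run directly from a per-population
summary table (the package bundles the published six-population summary it
was designed around):

```r
fit <- fit_richness_models(richness_model_input())
fit$dab$coefficients
#>                  term estimate   SE     t       p
#> 1           intercept    12.43 0.10 118.9 1.3e-06
#> 2        str_richness     4.71 0.11  41.1 3.2e-05
#> 3 ldh_admixture_resid    -1.02 0.11  -8.9 3.0e-03
fit$dab$adj_r_squared   # 0.997
fit$collinearity        # Spearman r_s = 0.77
```

MHC richness rises strongly with neutral STR richness, and the
residualized admixture slope measures what lineage admixture adds once
neutral diversity is accounted for. Differentiation with permutation
significance:

```r
gst(sim$table, "MHC", n_perm = 199, seed = 5)
#> MHC: G_ST 0.276, G″_ST 0.891 (p = 0.005)
```

A thin command-line front end over the same functions ships in
`inst/scripts/mhcbalance.R` with subcommands `simulate`, `supertype`,
`diversity`, `structure`, `selection`, `condition` and `all`.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package: it simulates the default scenario from `--seed`,
clusters supertypes, computes diversity and differentiation, runs the
partitioned dN/dS Z test and the supertype randomization, fits the
condition mixed model, refits the richness models from the bundled
per-population summary, and writes the results manifest to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
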