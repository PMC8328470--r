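---
title: "Methods: functional MHC diversity, neutral forces and balancing selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional MHC diversity, neutral forces and balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcbalance)
```

## The scientific problem

Classical MHC class II genes are among the most polymorphic loci in
vertebrate genomes. Their exon-2-encoded antigen-binding region is shaped by
a mixture of forces: genetic drift and demography, positive selection for
amino-acid replacement at antigen-binding residues over evolutionary time,
and contemporary pathogen-mediated balancing selection. Three balancing
mechanisms are usually contrasted: rare-allele advantage (negative
frequency-dependent selection), heterozygote advantage, and
divergent-allele advantage. In salmonid populations that also receive
hatchery fish, human-mediated introgression adds a further source of (MHC)
variation, traceable with a diagnostic biallelic marker (LDH-C1, allele
\*90 fixed in domestic Atlantic stocks, \*100 native in Mediterranean
populations).

`mhcbalance` implements the full analysis chain for one multiallelic MHC
locus, a panel of neutral microsatellites (STR) and the LDH marker, scored
in several wild populations together with individual weight and standard
length:

1. **Supertyping** — collapse alleles into functional classes by K-means
   clustering of physicochemical profiles at positively selected sites.
2. **Diversity and differentiation** — rarefied allelic richness, private
   variants, heterozygosities, exact Hardy–Weinberg and linkage tests,
   standardized differentiation (G''~ST~), hierarchical AMOVA, Mantel
   comparisons of MHC versus neutral structure.
3. **Historical selection** — Nei–Gojobori dN/dS on codon partitions with a
   codon-bootstrap Z test, and a randomization null for supertype-based
   structure.
4. **Contemporary selection** — linear mixed models of Fulton's condition
   factor on the local frequency, zygosity and sequence dissimilarity of
   the MHC variants an individual carries.
5. **Synthetic data** — a generator with known ground truth so that every
   stage is testable without any external download.

## Supertyping

Alleles are translated (`read_allele_fasta()`), the residues at the
positively selected sites (PSS; an *input*, inferred upstream by codon-model
consensus) are extracted, and each residue is encoded by the five extended
principal-property scales of Sandberg and co-workers (z1–z5), giving a
`|PSS| x 5` feature vector per allele. `select_supertypes()` runs K-means
over a grid of K (best of `n_starts` restarts per K) and scores each K with

$$\mathrm{BIC}(K) = n \,\log(\mathrm{WSS}_K/n) + K \log n,$$

`n` the number of alleles — the convention of the `find.clusters`-style
K-means/BIC selection common in this literature; the formula itself is not
fixed by that literature, so it is stated here explicitly. Ties go to the
smallest K. Features are used raw: the z-scales are already on a common
scale, and skipping per-column standardization or a PCA step makes the
result bit-for-bit reproducible from the inputs. Note a property of this
criterion worth knowing: when the feature cloud has no latent cluster
structure the BIC can decrease over a wide range of K and the selected K
may sit near the grid edge; with genuinely clustered profiles — planted
families in the synthetic catalogs, or low-dimensional blob tests — it
recovers the planted classes (cluster purity 1 in the recovery checks),
though in some realizations it splits a family into subclusters.

## Diversity and differentiation

* **Richness** is rarefied analytically: with allele counts $n_i$ in $N$
  gene copies, the expected allele number in a standardized subsample of
  $g$ copies is $R = \sum_i \left(1 - \binom{N - n_i}{g} / \binom{N}{g}\right)$.
  The default $g$ is twice the smallest per-population sample (46 copies
  for the motivating six-population design with a 23-individual minimum).
* **Heterozygosity** reports observed Ho, Nei's gene diversity
  $He = 1 - \sum p_i^2$ and the unbiased `uHe` with the $2N/(2N-1)$ factor.
* **Hardy–Weinberg** deviations use a Monte-Carlo exact test conditioned on
  allele counts (gene copies shuffled and re-paired; p = fraction of tables
  at most as probable as observed, with the $(b+1)/(m+1)$ correction);
  multiallelic-safe, default 100,000 tables, with Holm–Bonferroni
  adjustment across the population-by-locus family (`hwe_tests()`).
* **Linkage** uses a genotypic G statistic with genotypes at one locus
  permuted among individuals.
* **Differentiation**: `gst()` reports the raw Nei ratio
  $G_{ST} = (H_T - H_S)/H_T$ from uncorrected gene diversities *and* the
  estimators for highly polymorphic markers — Nei–Chesser sample-size
  corrected $H_S$, $H_T$ (harmonic mean sample size), Hedrick's
  standardized $G'_{ST}$, and the $k/(k-1)$-corrected $G''_{ST}$ of
  Meirmans & Hedrick. Which exact dialect the motivating analyses used is
  not formula-cited in that literature, so both raw and corrected values
  are emitted and either is testable. Significance comes from permuting
  individuals across populations.
* **AMOVA** partitions allele-identity (0/1) distances between gene copies
  into among-group, among-population-within-group and within-population
  components with the classical unequal-sample-size coefficients;
  multi-locus markers sum covariance components over loci. Identity rather
  than allele-size distances are used for STR (no stepwise-mutation
  assumption). Permutation schemes are level-appropriate: populations among
  groups, individuals among populations within groups, gene copies among
  populations. A single group degrades to the two-level decomposition.
* **Mantel** correlations of differentiation matrices delegate to
  `vegan::mantel()` (Pearson r on off-diagonals, row/column permutations).

## Historical positive selection

`nei_gojobori_pair()` implements the pairwise counting method: potential
synonymous sites per codon are the per-position fractions of non-stop
single-nucleotide changes that preserve the amino acid (so
$N + S = 3 \times$ codons); observed differences at codons differing at 2–3
positions are averaged over all minimal mutational pathways, excluding
pathways through stop codons (if *every* pathway passes through a stop, the
unweighted average over all pathways is used — a documented fallback for a
genuinely ambiguous convention). Proportions are Jukes–Cantor corrected,
$d = -\tfrac34 \log(1 - \tfrac43 p)$, with $p \ge 0.75$ treated as
saturation (an error, not a number).

`dnds_partition_test()` averages dN and dS over all sequence pairs within a
codon partition (all sites, the PSS set, or its complement) and tests
$d_N > d_S$ one-tailed with $Z = (d_N - d_S)/\mathrm{SE}$, the SE obtained
by bootstrap over codons (default 1,000 seeded replicates) — the bootstrap
variance route of the standard MEGA-style test; no analytic variance is
implemented. $\omega$ is reported as `NA` when $d_S = 0$.

`supertype_gst_randomization()` implements the null for functional
structure: alleles are randomly reassigned to supertype labels (permuting
the observed label vector, so the supertype size spectrum is preserved;
uniform assignment is available behind `preserve_sizes = FALSE`), the
supertype-space differentiation is recomputed each time, and the observed
value is located two-sidedly in the null. With the identity map the null is
degenerate at the observed value and p = 1 exactly.

## Condition models

`condition_records()` assembles, per individual: Fulton's condition factor
$K = 100\,w/L^3$ (w in g, L in cm — units chosen so that typical salmonid
K sits near 1.4–1.5, matching the intercepts the motivating study prints);
the **MHC frequency index** (sum of the within-population frequencies of
the 1–2 carried variants, homozygotes doubling their single variant;
focal individual included by default, a leave-one-out variant behind a
flag); **zygosity** (residualized on the frequency index through a binomial
GLM, response residuals by default, deviance behind a flag — rare variants
concentrate in heterozygotes, and residualization splits those collinear
signals); **sequence dissimilarity** of the carried alleles (Kimura
two-parameter nucleotide and Poisson-corrected amino-acid distances, 0 for
homozygotes); the proportion of heterozygous STR loci; and the LDH type
factor with reference level `domestic` (90/90).

`fit_condition_model()` fits the two model families with a population
random intercept (lme4):

* model 1: `K ~ freq_index + zygosity_resid + str_het + ldh_type` —
  rare-allele advantage (negative frequency-index slope) and heterozygote
  advantage (zygosity), in allele (`1_DAB`) or supertype (`1_ST`) space;
* model 2: `K ~ mhc_dissim + str_het + ldh_type` — divergent-allele
  advantage, nucleotide (`2_NU`) or amino-acid (`2_AA`) distance.

Coefficients come from the REML fit with Satterthwaite denominator degrees
of freedom. Because no Satterthwaite implementation is available in the
pinned dependency set, the package computes it directly for the
single-random-intercept case: the restricted log-likelihood is expressed in
the two variance components, their asymptotic covariance is the inverse
curvature (numerical Hessian) of that surface, and
$\nu = 2 f^2 / \mathrm{Var}(f)$ with $f = c^\top (X^\top V^{-1} X)^{-1} c$
by the delta method. If the random-intercept variance collapses to the
boundary the model falls back to a fixed-intercept linear fit and flags it.
Marginal and conditional $R^2$ use the variance-partition formulation
(fixed-effect variance over total; fixed plus random over total). AICc is
evaluated on an ML refit, $AICc = AIC + 2k(k+1)/(n-k-1)$.

`supertype_scan()` adds one supertype presence/absence indicator at a time
to the `1_ST` baseline, refits by ML, ranks by AICc and flags models more
than 2 AICc points below the baseline; supertypes carried by everyone or
no one are skipped. Carrier effects in the scan are Wald tests on the ML
fit (normal reference) — the scan is a ranking device, not the primary
inference.

`fit_richness_models()` handles the across-population level: MHC richness
(allele and supertype space) on neutral STR richness and LDH admixture
(frequency of the less common LDH allele — percentage or proportion is
immaterial because predictors are z-scored). The two predictors are
collinear by construction, so the admixture predictor is residualized on
STR richness (sequential regression) and then **re-standardized to unit
variance**; this last step is what makes the two slopes directly
comparable, and it is required to reproduce the printed coefficient table
of the motivating study from its own summary statistics.

## Synthetic data: the stated world

`sim_scenario()` defaults mirror the motivating field design: 6 populations
of 28/27/25/26/27/23 diploid individuals; an MHC pool of 58 alleles with a
skewed base frequency spectrum (Dirichlet concentration 0.3, giving a few
common and many rare alleles as in deep-sequenced MHC data); per-population
frequencies drawn Balding–Nichols style around the base (Beta-Dirichlet
with concentration $(1-F)/F$, default $F = 0.2$ — a single parameter
controlling expected differentiation at the magnitude the motivating
populations show); 11 STR loci of 8 alleles; LDH \*90 frequencies
0.143/0.907/0.46/0.058/0.389/0.457 (the printed population values); and
condition built as
$K = \beta_0 + \beta_{freq}\,\mathrm{freq} + \beta_{zyg}\,\mathrm{het} +
\beta_{dissim}\,d + u_{pop} + \varepsilon$ with defaults
$\beta_0 = 1.5, \beta_{freq} = -0.15, \sigma_{pop} = 0.1,
\sigma_e = 0.25$ — the desk-scale recovery benchmark anchored to the
magnitudes the condition models report. Lengths are lognormal
(median 13 cm, sdlog 0.12) and weights are inverted as $w = K L^3/100$, so
the condition factor round-trips exactly. Allele sequences are generated in
latent supertype families: 12 founder sequences diverge deeply from a
stop-free ancestor (`simulate_codon_alignment()`), and each allele evolves
shallowly (one fifth of the founder divergence) from its family founder, so
the PSS physicochemical profiles carry recoverable cluster structure and
the supertype scan has planted signal. Mutations are accepted with
probability $\min(1, \omega)$ for nonsynonymous and $\min(1, 1/\omega)$ for
synonymous changes, with codon-class $\omega$ of 5 at the designated "PSS"
codons and 0.3 elsewhere; stop codons are always rejected.

What the generator does **not** emulate: coalescent ancestry and shared
drift history, linkage, null alleles, genotyping error, and any real
host–parasite dynamics — a green recovery test establishes that the
estimators are consistent in the stated world, not that the biological
conclusions of any particular dataset are right. The star-shaped
within-family genealogy is also simpler than the reticulate,
recombination-marked genealogies of real MHC alleles.

## Numerical choices and edge cases

* Permutation and randomization p-values are always $(b+1)/(n+1)$ — never 0.
* Two-sided randomization p: $2 \min(P_{\le}, P_{\ge})$, capped at 1.
* Monomorphic loci: HWE and linkage tests return `NA` rather than a number.
* K-means tie-breaking on equal BIC: smallest K (parsimony); K above the
  number of distinct profiles is skipped with a warning.
* `gst()` errors when a population has fewer than 2 individuals;
  `fit_richness_models()` errors on constant predictors.
* Seeds are mandatory where results are stochastic (`sim_scenario()`,
  `select_supertypes()`); everything else takes an optional seed.

## Known limitations

* The Satterthwaite machinery covers the single-random-intercept design the
  models use; other random-effect structures fall back to residual df.
* The catalog-level dN/dS test treats sequences as independent pairs, as in
  the counting tradition; it is not a phylogenetic codon model (those are
  deliberately out of scope).
* PSS detection is an input: the package never infers sites itself.
* AMOVA uses identity distances only; an allele-size (stepwise) variant is
  not implemented.

## A minimal end-to-end run

```{r example, eval = FALSE}
scen <- sim_scenario(seed = 1)
sim <- simulate_population_dataset(scen)

pss <- pss_config(scen$pss, attr(sim$catalog, "aln_length"))
feat <- encode_physicochemical(extract_pss_residues(sim$catalog, pss))
sol <- select_supertypes(feat, seed = 2)

diversity_summary(sim$table, "MHC")
gst(sim$table, "MHC", n_perm = 999, seed = 3)
dnds_partition_test(sim$catalog, pss, "PSS", seed = 4)

rec <- condition_records(sim$table, catalog = sim$catalog, solution = sol)
fit_condition_model(rec, "1_DAB")

fit_richness_models(richness_model_input())
```
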