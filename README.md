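# mgxdiff

Seven medical-ecology analyses for asking whether two cohorts of
microbiome samples — typically male and female subjects sampled at the
same body site — host the same community, and if not, where they
differ:

1. **Hill-number diversity** `D(q) = (Σ p_i^q)^{1/(1-q)}` per sample, at
   community, phylum, and core/periphery strata, compared by Wilcoxon
   rank-sum with Cohen's *d* effect sizes;
2. **shared-species analysis** with two permutation nulls — A1
   reshuffles reads between the cohorts, A2 reshuffles whole samples
   (more conservative) — testing for fewer shared taxa than chance;
3. **power-law heterogeneity scaling** `V = a·m^b` (Type I: one point
   per sample; Type III: one point per taxon), with permutation tests
   for cohort differences in the exponent;
4. **diversity–area relationships**: diversity of pooled subjects fitted
   as `D = c·A^z` or with exponential cutoff `D = c·A^z·e^{dA}`, whose
   maximum — the maximal accrual diversity — sits at `A_max = −z/d`
   with `D_max = c·A_max^z·e^{−z}`;
5. **species co-occurrence networks** (Spearman on relative abundances,
   Benjamini–Hochberg FDR ≤ 0.001, singleton prefilter), with basic
   properties, positive/negative edge ratio, and a trio-motif census
   anchored on the most abundant OTU;
6. **core/periphery partitions** maximising the match
   `ρ = Σ a_ij p_ij` to the ideal pattern (fully linked core, periphery
   tied only to the core), with shared-core tests under observed-network
   and permutated-network strategies;
7. **high-salience skeletons**: the backbone of edges lying on shortest
   -path trees from most roots (salience `s_ij = (1/N) Σ_x T_ij(x)`,
   length `1/|ρ|`), thresholded at 0.25/0.5 and compared between
   cohorts by permutated-network tests.

A synthetic two-cohort generator with planted ground truth
(cohort-specific taxa, core/periphery structure, backbones, power-law
points) backs every stage; the test suite checks the implementations
against closed forms and brute-force oracles and measures type-I error
and power of every permutation test.

## Worked example

Simulate two cohorts of 40 subjects from a 400-taxon community in which
30% of taxa are cohort-specific, then run three of the analyses:

```r
library(mgxdiff)

spec <- cohort_spec(n_samples_a = 40, n_samples_b = 40, n_shared_taxa = 280,
                    n_specific_a = 60, n_specific_b = 60, abund_sdlog = 3,
                    depth_mean = 1000, seed = 42)
sim <- generate_cohorts(spec)
cohorts <- split_by_group(sim$table, sim$metadata)

compare_diversity(cohorts$M, cohorts$F)
#>  q   medianA   medianB   wilcoxon_p     cohens_d direction
#>  0 85.500000 91.500000 4.368538e-02 -0.460563650       A<B
#>  1 20.731158 22.921856 5.236674e-12 -1.820442359       A<B
#>  2  8.924689  9.240249 6.516617e-02 -0.472391592       A~B
#>  3  6.403740  6.476628 8.220802e-01 -0.009302873       A~B

shared_species_test(cohorts$M, cohorts$F, algorithm = "A2",
                    n_perm = 1000, seed = 1)
#> Permutation test (shared species, lower tail): observed = 183,
#>   null 249.2 +/- 3.636, p = 0.000999 (n_perm = 1000)

mad <- dar_mad(fit_dar(dar_curve(cohorts$M, q = 0, n_orders = 50, seed = 3),
                       "PLEC", q = 0))
mad
#> Maximal accrual diversity: D_max = 248.3 effective species at A_max = 57.53 subjects
```

Reading the output: the cohorts share 183 taxa where random sample
reshuffling expects ~249, so the A2 test reports significantly fewer
shared species than chance (p at the permutation floor) — the planted
cohort-specific taxa are detected. Diversity differs most strongly at
`q = 1` (Shannon-weighted effective species), while rare-taxon-dominated
richness (`q = 0`) differs only marginally. Accumulating male subjects,
the cutoff model caps accruable richness at ~248 effective species
around 58 subjects.

Networks, cores, and skeletons follow the same pattern
(`build_scn()`, `detect_core()`, `link_salience()`,
`shared_core_permutated()`, `shared_skeleton_analysis()`), and
`run_all()` orchestrates every stage per body site from one config into
tidy TSV reports plus a JSON manifest. The `vignettes/methods.Rmd`
vignette documents the models, parameters, null constructions, and the
design of the validation studies.

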