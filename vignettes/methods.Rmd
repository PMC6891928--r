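---
title: "Methods: comparing two cohorts of microbiome samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two cohorts of microbiome samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgxdiff)
```

`mgxdiff` asks one question seven ways: do two cohorts of microbiome
samples — typically male and female subjects sampled at the same body
site — host the same community? The seven analyses move from diversity
(how many effective species), through composition (which species), to
scaling (how diversity and heterogeneity grow with cohort size), and
finally to species interactions (co-occurrence networks, their
core/periphery organisation, and their high-salience backbones). All
between-cohort contrasts rest on seeded permutation tests with a common
p-value convention, and a synthetic generator with planted ground truth
backs every stage with testable recovery claims.

## Diversity: Hill numbers

Alpha diversity is quantified by Hill numbers,

$$ {}^qD = \Big(\sum_{i=1}^{S} p_i^q\Big)^{1/(1-q)}, $$

where $p_i$ is the relative abundance of taxon $i$ and $q \ge 0$ the
diversity order. $q=0$ is richness, $q \to 1$ the Shannon limit
$\exp(-\sum_i p_i \log p_i)$ (computed analytically, not by numerical
limit; the profile's continuity through $q=1$ is asserted in tests), and
$q=2$ the inverse Simpson concentration. Hill numbers are in units of
effective species, are scale-invariant, and are non-increasing in $q$.
Profiles can be computed per sample at the whole-community level, within
a phylum, or within the core or periphery of a detected core/periphery
partition (`stratified_profiles()` renormalises within the stratum and
skips — and reports — samples with no reads in it).

Cohorts are unpaired, so `compare_groups()` uses the two-sample
rank-sum form of the Wilcoxon test, two-sided (exact for small tie-free
groups, normal approximation with tie correction otherwise), and reports
Cohen's $d$ with the pooled standard deviation alongside. The direction
call (`A>B`, `A<B`, `A~B`) is made by the Wilcoxon p-value at
$\alpha = 0.05$ per comparison, with no multiple-testing correction
across site-by-order comparisons — each comparison is reported
individually, and readers counting significant cells across a table of
sites and orders should bear that in mind. Optional rarefaction to a
common depth (`rarefy_table()`, off by default since no single depth is
canonical) addresses unequal sampling effort.

## Composition: shared species under two nulls

If the two cohorts host the same community, the number of taxa observed
in both (total reads > 0 on each side; no abundance floor) should match
what random sampling effects produce. Two reshuffling nulls formalise
"random":

* **A1 (read reshuffling)** pools every read of both cohorts and
  reallocates reads to the cohorts at random, preserving each cohort's
  total read count. It is implemented per taxon as a sequential
  multivariate hypergeometric split — exactly the distribution obtained
  by labelling each read with its taxon and shuffling, without
  materialising read tokens.
* **A2 (sample reshuffling)** pools whole sample columns and reassigns
  them to two groups of the original sizes. Because it preserves
  within-sample co-occurrence (rare taxa concentrated in a few samples
  move wholesale), its null spreads the shared-species count at least as
  widely as A1's; it is the more conservative and more trustworthy of
  the two. This ordering is asserted in tests on overdispersed synthetic
  data — with no within-sample overdispersion the two nulls nearly
  coincide, which is itself informative.

The test is one-sided for *fewer shared species than chance* (the
direction of interest when cohort-specific taxa are suspected); a
two-sided variant is available. The permutation count defaults to 1000,
matching the network-level tests.

## Scaling: power-law extensions and diversity–area relationships

Community heterogeneity is summarised by Taylor-style power laws
$V = a\,m^b$ fitted on the log10 scale by ordinary least squares.
Type I takes one $(m, V)$ point per sample — the mean and (unbiased,
$n-1$ denominator) variance of taxon abundances within the sample —
and measures interindividual community heterogeneity. Type III takes
one point per taxon across samples, measuring the heterogeneity of the
mixed-species population; the per-taxon construction is one reasonable
reading of that level and is isolated behind the `model_type` switch so
it can be swapped without touching the fitting code. Points with
$m \le 0$ or $V \le 0$ cannot enter a log fit; they are dropped and
counted.

Diversity scaling uses the diversity–area relationship (DAR), with
"area" the number of pooled subjects: samples are accumulated in random
order (100 orderings by default; the mean curve is used), pooling
counts and recomputing ${}^qD$ at each accumulation level. Two models
are fitted in transformed coordinates (reproducible convex least
squares rather than nonlinear iteration):

* power law (PL): $\;{}^qD = c A^z$, OLS of $\ln D$ on $\ln A$;
* power law with exponential cutoff (PLEC):
  $\;{}^qD = c A^z e^{dA}$, OLS of $\ln D$ on $(\ln A, A)$.

With $z > 0$ and $d < 0$ the PLEC curve peaks at the **maximal accrual
diversity**: $A_{\max} = -z/d$ and
$D_{\max} = c\,A_{\max}^{z}\,e^{-z}$ (`dar_mad()`; the closed form is
checked against direct numerical maximisation). With $d \ge 0$ there is
no finite maximum and the function refuses to report one.

Between-cohort differences in any scaling parameter use
`compare_scaling_param()`: the observed statistic is
$|\theta_A - \theta_B|$, the null refits after pooling and re-splitting
samples into the original group sizes, and more than 5% failed refits
abort the test rather than silently biasing it.

## Networks: construction, motifs, core/periphery, salience

**Construction.** `build_scn()` filters taxa with fewer than 80 total
reads (about one read per subject in a typical cohort — approximate
singletons; the threshold is inclusive at the boundary and exposed
per stage), converts to relative abundance, computes all pairwise
Spearman correlations, and applies Benjamini–Hochberg FDR control
across all tested pairs, keeping edges with adjusted $p \le 0.001$.
BH on adjusted p-values is the default reading of "FDR control"; a
raw-p mode is available by flag. Spearman p-values use the
t-approximation at $n \ge 12$ samples and the exact null below.
Edges carry the signed correlation; properties are computed on the
unsigned graph except the positive-to-negative edge ratio (reported as
`Inf` when no negative edges exist). Compositionality-aware estimators
(SparCC and kin) are deliberately out of scope: the pipeline reproduces
the plain Spearman-on-relative-abundance choice.

**Trio motifs.** The most abundant OTU (MAO; read-count ties broken
lexicographically) anchors a census of all $\binom{n-1}{2}$ trios
{MAO, u, v}, classified by the complete edge-configuration-by-sign
taxonomy (which subsumes any fixed list of special trio classes). The
double-link MAO trio (DLM) — exactly two edges, both incident to the
MAO — is named explicitly. The census is validated against exhaustive
enumeration.

**Core/periphery.** The ideal pattern has a fully linked core and a
periphery connected only to the core. For membership vector $\delta$
the objective is $\rho = \sum_{ij} a_{ij} p_{ij}$ over ordered pairs,
where $p_{ij} = 1$ unless both endpoints are periphery. As printed,
the objective rewards any edge touching the core and never penalises,
so the all-but-one-core partition is always optimal in $\rho$; the
implementation therefore constrains $1 \le n_\text{core} < n$ and
breaks ties toward the smaller core (then the lexicographically
smallest membership), making the detected core the smallest vertex
cover reachable by the optimiser — the natural reading of "core" under
this objective. Detection is greedy single-node label switching from
random restarts plus a degree-ranked start; an exhaustive oracle covers
$n \le 12$ in tests. The adjacency is binarised and unsigned, as the
objective is defined on 0/1 entries.

**Link salience.** With edge length $1/|\rho|$ (stronger association =
shorter; the absolute value is required because a negative correlation
would give a negative length, and the sign is kept as edge metadata),
every node $x$ defines a shortest-path tree $T(x)$ containing each edge
that lies on at least one shortest path from $x$. Salience is
$s_{ij} = \frac{1}{N}\sum_x T_{ij}(x)$ over all $N$ nodes, isolated
nodes included (they contribute zero rows, so an edge in a component of
$k$ nodes can reach salience at most $k/N$). The "at least one
shortest path" reading makes the computation deterministic without
tie-break rules; it is implemented by the distance identity
$d(x,i) + w_{ij} = d(x,j)$ (tolerance $10^{-10}$ scaled by the largest
weight) and verified edge-for-edge against exhaustive path enumeration
on small graphs. The high-salience skeleton keeps edges with
$s \ge s^*$ (conventional thresholds 0.25 and 0.5) and all nodes;
skeletons are nested in $s^*$.

**Shared-structure tests.** Core (or periphery) overlap between
cohorts is tested two ways: the *observed-network* strategy permutes
the detected node sets (random subsets of the observed sizes drawn from
the union of the two networks' node sets — checked against the
hypergeometric law), and the *permutated-network* strategy rebuilds
network pairs from pooled-and-resplit samples and re-detects the
partition on each. Shared skeletons exist only under the
permutated-network strategy (a random subset of edges is not a
meaningful skeleton null). Observed and permutated networks use the
same number of detection restarts by default so the null statistic
stays exchangeable with the observed one. All one-sided tests ask for
*less* sharing than chance.

## Permutation machinery

Every test reports $p = (\#\{\text{null at least as extreme}\} + 1) /
(n_\text{perm} + 1)$ — never zero, floored at $1/(n_\text{perm}+1)$,
with the two-sided version $2\min(p_\text{lower}, p_\text{upper})$
capped at 1. One user seed expands into per-test child seeds via a
counter scheme (`child_seed()`), so any single test can be reproduced
in isolation; all RNG use is wrapped so the caller's random stream is
left untouched.

## The synthetic generator and what passing tests show

`generate_cohorts()` draws expected relative abundances from a
lognormal (heavy-tailed rank-abundance, sdlog 1.5 by default), gives
cohort-specific taxa zero expectation in the other cohort, and samples
counts as multinomial draws at negative-binomial depths (mean 5000,
size 10 by default, emulating two cohorts of ~80 subjects). Optional
Dirichlet-style overdispersion concentrates rare taxa into few samples,
as real 16S data does. `generate_planted_network_cohort()` plants
correlation through shared latent Gaussian factors mapped through the
negative-binomial quantile function — a rank-preserving transform, so
Spearman sees the planted structure — with a core factor, periphery
taxa each tied to one core taxon, optional tree-shaped backbone edges,
and independent high-abundance "filler" taxa. The fillers matter:
relative-abundance closure divides by the sample total, and when the
correlated block carries most of the reads that division erases the
planted rank structure, just as a real community's dominant taxa buffer
its rare ones.

Gaussian factor planting is transitive: periphery taxa coupled to the
core at strength $s$ correlate with each other at about $s^2$, which
any usable sample size detects. The realised network therefore always
contains some periphery–periphery edges, and the $\rho$-optimal core of
that network is a superset of the plant. Recovery tests assert what is
actually true of the construction — the planted core is contained in
the detected core and the detected core stays within the planted
core-plus-periphery (spurious singleton edges can add an occasional
extra) — while exact recovery is asserted on ideal core/periphery
graphs, where it holds. None of this mimics the marginal distributions of any real survey; the
generator targets the statistical structure each stage assumes, not
realism, so passing tests certify the machinery, not any biological
claim.

## Validation study design and problem sizes

The calibration and power studies (shared by the test suite and
`scripts/acceptance.R`) fix their conditions in one place:

* **Shared-species / PLE calibration**: two cohorts of 40 samples
  drawn from one 400-taxon lognormal community (sdlog 3, depth 1000).
  The wide lognormal puts a long tail of taxa at cohort-level presence
  probabilities strictly between 0 and 1; a narrower one pins the
  shared-species count at the taxon total and the test, though valid,
  measures nothing.
* **Network calibration**: halves of one 80-sample planted-network
  draw (30 taxa, core 8, periphery 16, couplings 0.85/0.70 plus
  3 fillers). The couplings sit near the FDR detection boundary on
  purpose: edges must flicker across resplits for the overlap
  statistics to vary. Overlap counts are still integers, so these
  permutation tests are discretely conservative — rejection rates at
  $\alpha = 0.05$ land near the bottom of the nominal range rather
  than at 0.05, which the acceptance band [1%, 10%] anticipates.
* **Power, cohort-specific taxa**: 30% specific taxa (60 + 60 of 400)
  at the same marginals.
* **Power, distinct cores**: the same planted-network process with
  cohort B's taxon labels rotated, at 80 samples per cohort — the
  typical per-sex, per-site cohort size in 16S surveys of this kind.
* **Power, distinct backbones**: each cohort carries a hub-and-spoke
  backbone (16 spokes at coupling 0.7) on its own disjoint taxon
  block, 200 samples per cohort. Pooled halves dilute every
  association by about half: the spokes (~0.35) stay detectable while
  the second-order shortcuts (~0.25) drop below the FDR boundary, so
  permutated halves agree on a tree-like consensus backbone that the
  observed pair, by construction, never shares. Smaller cohorts leave
  the diluted spokes undetectable and the test — faithfully — reports
  no difference; distinguishing backbones by salience needs either
  strong backbones or large cohorts.

Detection inside the permutation loops uses 3 greedy restarts
(symmetric between observed and null networks), and the curves use
20–30 accumulation orderings; these sizes keep a full validation run
in the minutes range on one core while leaving every conclusion
comfortably inside its tolerance.

## Degenerate inputs and numerical choices

Zero-total samples abort relative-abundance conversion with the
offending sample names; all-zero abundance vectors abort Hill numbers;
an abundance filter that removes every taxon returns an empty table
that downstream stages reject cleanly; constant taxa carry no rank
signal and are excluded from correlation testing (they remain nodes);
empty graphs yield sentinel property records (density 0, `NaN`
positive/negative ratio) rather than errors; `dar_mad()` refuses
$d \ge 0$; permutation tests abort when more than 5% of null refits or
detections fail. MAO ties break lexicographically; core-partition ties
break toward smaller cores then lexicographic membership; shortest-path
tolerances scale with the largest edge weight.

## Known limitations

Spearman on relative abundances ignores compositional coupling; the
core/periphery objective is the literal unpenalised pattern match, so
cross-size comparisons should use the size-documented outputs rather
than raw $\rho$; Type-III heterogeneity is one interpretation of the
mixed-species level; the DAR mean curve (not per-ordering fits) is
fitted; and the headline empirical findings of any real sex-difference
survey depend on the full survey data — this package certifies the
machinery on synthetic ground truth and leaves biological conclusions
to data its users supply.
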