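---
title: "Kinship and cemetery social structure from low-coverage ancient DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and cemetery social structure from low-coverage ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokin)
```

## The problem

Ancient-DNA cemetery studies typically sequence each skeleton to well below
1X coverage. At such depths diploid genotypes cannot be called confidently
at individual sites, yet questions about the community — who was related to
whom, whether relatives were buried together, whether status tracked
kinship, whether the group was inbred or structured — all hinge on
genome-wide genotype information. The standard response, which this package
implements end to end, is to keep the per-site uncertainty explicit as
*genotype likelihoods* and to push all inference through them, or through
deliberately lossy but unbiased *pseudo-haploid* calls.

`paleokin` covers five stages: (1) a fully synthetic data generator
(pedigree gene dropping, low-coverage read simulation with
deamination-like error, cemetery metadata scenarios); (2) genotype
likelihoods, pseudo-haploid calls, Bayesian allele-frequency estimates and
site filters; (3) pairwise identity-by-descent (IBD) estimation and
relationship classification, with an independent mismatch-based
cross-check; (4) cohort statistics — haplotype diversity, Hudson's
$F_{ST}$, an MCMC inbreeding estimator, molecular sexing, allele-sharing
distances; (5) the cemetery statistics proper — a permutation test for
spatial clustering of relatives (with an exact-enumeration oracle), a
hypergeometric composition test, and kin-dyad status concordance. A small
Early Bronze Age cohort (Mokrin, northern Serbia; 24 individuals, four
burial groups, nine related pairs) ships as plain-text fixtures to
illustrate stage (5).

## Error model and genotype likelihoods

Reads at a biallelic site are modelled as independent draws from the
individual's two alleles, mis-read with probability $\varepsilon$ and, at
*damage-susceptible* sites (a per-site flag emulating the C→T/G→A strand
classes hit by post-mortem deamination), additionally flipped with
probability $\delta$. The per-read alternate-allele probability for
genotype $g \in \{0,1,2\}$ (alternate-allele dosage) at a site with
susceptibility flag $s$ is

$$a(0) = \varepsilon + \delta s, \qquad a(1) = \tfrac12, \qquad
  a(2) = 1 - \varepsilon - \delta s,$$

and the genotype likelihood is binomial,
$L(g) \propto a(g)^{n_\text{alt}} (1-a(g))^{n_\text{ref}}$. Heterozygotes
are left at $a(1) = 1/2$: both alleles are present, so a symmetric flip
leaves the read composition unchanged in expectation. Likelihoods are
stored as natural logs normalized to a per-site maximum of 0; a site with
no reads has three equal likelihoods and drops out of every downstream
sum. Defaults are $\varepsilon = 0.005$ and $\delta = 0.02$; both are
simple scalar stand-ins for what full recalibration pipelines estimate
per position and quality stratum, which is out of scope here. Base
qualities are collapsed into $\varepsilon$.

The *same* model drives `simulate_pileups()`, so simulation and inference
are exactly matched — deliberately: the package's validation questions are
about the estimators, not about model misspecification. Real data pass in
through pileup/GL TSVs or a VCF with `GL`/`PL` fields.

## Pairwise IBD and relationship degrees

For a pair of individuals the genotype-pair probability given IBD
coefficients $k = (k_0, k_1, k_2)$ (probabilities of sharing 0, 1, 2
alleles identical by descent) mixes three joint distributions under
Hardy–Weinberg at the panel frequency $p$: independence ($k_0$), one
shared allele plus one free allele each ($k_1$), and identity ($k_2$).
The pair log-likelihood sums
$\log \sum_{g_i,g_j} L_i(g_i) L_j(g_j) P(g_i,g_j \mid k, p)$ over sites
where both individuals have coverage; `estimate_k()` maximizes it by a
projected grid search on the simplex (step 0.01, then local refinement at
0.001). A grid is deterministic, free of EM convergence ambiguity, and at
these problem sizes costs well under a second per pair via a small C++
kernel. The relatedness summary is $r = k_1/2 + k_2$.

Degrees are binned on $r$ at geometric midpoints between the expected
values of adjacent degrees: identical $> 2^{-1/2}$, first degree
$(2^{-3/2}, 2^{-1/2}]$, second $(2^{-5/2}, 2^{-3/2}]$. Below that,
low-coverage data cannot resolve individual degrees, so a single "third"
bin extends down to $2^{-9/2} \approx 0.044$ and anything weaker is
unrelated. First-degree pairs split into parent–offspring versus siblings
on $\hat k_0 < 0.1$ (a true parent–offspring pair has $k_0 = 0$; siblings
have $k_0 = 1/4$). Pairs with fewer than `n_min = 1000` overlapping
covered sites are reported as *no call*, never as unrelated — at 1000
sites the standard error of $\hat r$ is already a sizeable fraction of a
degree bin, and below that the classification would be noise.

The cross-check classifier is the classical windowed mismatch rate of
pseudo-haploid calls: per pair, the fraction of jointly called sites that
disagree, averaged over non-overlapping windows, normalized by the cohort
baseline (the median of pair means — valid because in a cemetery cohort
the overwhelming majority of pairs are unrelated). Expected normalized
mismatch is 1 (unrelated), 7/8 (second degree), 3/4 (first), 1/2
(identical); the classifier cuts at the midpoints 0.90625, 0.8125 and
0.625 and does not attempt degrees beyond the second, which is this
statistic's realistic resolution.

## Inbreeding, diversity, differentiation, sexing

The cohort inbreeding coefficient $F$ is the shared heterozygote-deficit
parameter in $P(g \mid p, F)$: $q^2 + Fpq$, $2pq(1-F)$, $p^2 + Fpq$. Its
posterior is sampled by a Gaussian random-walk Metropolis chain (step
0.02, reflected at the domain bounds, default $10^5$ iterations with
5,000 burn-in; the heavier published settings remain available through
the arguments). One implementation point is worth stating plainly: each
data entry's likelihood is *linear* in $F$ ($A + FB$ with $A, B$
precomputable), so the full log-likelihood is evaluated once on a
1201-point grid and interpolated by a natural cubic spline inside the
chain. The curvature of the log-likelihood at these data sizes makes the
interpolation error orders of magnitude smaller than Monte-Carlo noise,
and the chain itself then costs microseconds per iteration. In
unrestricted mode the domain is $[-0.2, 1]$ so heterozygote *excess* is
detectable; combinations of strongly negative $F$ with extreme site
frequencies that would drive a genotype probability negative get zero
likelihood, so the effective lower bound adapts to the panel. A
`restrict_nonneg` flag reruns with $F \ge 0$. Chains with acceptance
below 1% or above 99% trigger a diagnostic warning.

Haplotype diversity is the bias-corrected
$\hat h = \frac{n}{n-1}\,(1 - \sum_i x_i^2)$. Note that $\hat h$ is
sensitive to the resolution at which haplotype labels are recorded;
`haplotype_diversity()` takes labels at face value and applies no
collapsing convention.

$F_{ST}$ uses Hudson's estimator with the sample-size correction in the
numerator and is combined across sites as a ratio of sums, the form that
stays consistent when per-site denominators vary. Molecular sex is called
from the Y fraction $R_y = n_Y/(n_X+n_Y)$ with a normal-approximation 95%
interval against the conventional thresholds 0.016 (XX) and 0.075 (XY);
fewer than 100 sex-linked reads is always inconclusive.

## Cemetery statistics

`same_group_pair_count()` counts related pairs buried in one spatial
group. Significance comes from permuting individuals among groups while
preserving group sizes; the one-sided p-value uses the add-one convention
$(1+b)/(1+n)$, which cannot report an exact zero and matches how
Monte-Carlo bounds are usually quoted. Ties count toward the tail
(statistic $\ge$ observed). For small cohorts
`exact_pair_statistic_null()` enumerates every distinct assignment and
serves as the oracle the permutation test is validated against.
Individuals from multiple burials in one grave are distinct individuals
in the same group; no within-grave collapsing is applied.

The composition question — "all nine individuals without a relative are
female; how surprising?" — is the hypergeometric point probability
$\binom{K}{k}/\binom{N}{k}$ of drawing an all-carrier subset, computed
exactly. Status concordance tabulates, per related dyad, whether both
members share the binary grave-good class; dyads with a missing status on
either side are flagged and excluded from totals rather than guessed. In
the bundled cohort the status labels encode only what the source
discussion states individual by individual, which leaves three of the
nine dyads unevaluable and two concordant.

## The synthetic generator, and what passing tests mean

`draw_frequency_panel()` draws alternate-allele frequencies from
Beta(0.8, 0.8) truncated to the minor-allele-frequency filter — a
U-shaped, SFS-like distribution resembling the common-SNP panels used for
low-coverage genotyping (default MAF floor 0.05). `gene_drop()` gives
founders two allele copies (identical by descent with probability
`f_founder`) and transmits one allele per parent per site, tracking
founder-allele labels so the *realized* IBD state of any pair is
available exactly (`ibd_states()`) — this label-tracking is the oracle
behind the kinship-recovery tests. `simulate_pileups()` draws Poisson
depths (per-individual means can mimic a 0.85X ± 0.25 cohort via
`draw_depths()`) and binomial reads under the error model above.
`simulate_cemetery()` lays families into spatial groups with a
kin-clustering probability, appends unrelated in-migrant females with
novel mitochondrial labels (the signature of female exogamy), and labels
mt/Y lineages down maternal/paternal lines.

Simulated sites are *independent* (free recombination, no linkage).
Real genomes are linked, so real-data estimates have larger effective
variance than the simulations suggest; passing recovery tests here
validates correctness of the estimators under their own assumptions, not
their confidence calibration on linked data. Similarly, damage is reduced
to one per-site flip probability rather than a position-in-read profile,
and contamination, reference bias and mapping artefacts are entirely
outside the model.

## Validation scales and numerical choices

The test suite and the acceptance script validate at the study's own
scale: pairwise recovery uses 50 pairs per relationship class at 20,000
panel sites and depth 1X with $\varepsilon = 0.005$ (degree accuracy and
method agreement are measured on classes of degree ≤ 2); inbreeding
recovery uses 20 individuals, 50,000 sites, depth 2X, at $F = 0$ and
$F = 0.1$; panmixia $F_{ST}$ uses 200 random half-splits of a 24-member
cohort; the spatial permutation test runs $10^6$ permutations on the
bundled cohort and is checked against exact enumeration on three small
instances. Grid resolutions (0.01/0.001 simplex steps, 1001-point
frequency grid, 1201-point $F$ grid) were chosen so discretization error
sits well below sampling noise at these sizes. Ties in majority calls are
broken by a seeded fair coin; every stochastic stage derives its seed
deterministically from one master seed via `sub_seed()`, so whole
pipeline runs are exactly reproducible.

## Known limitations

Beyond the independence and damage simplifications above: the IBD model
assumes known, correct panel frequencies (frequency misspecification
biases $\hat k$); no pedigree-feasibility constraint is imposed on
$(k_0,k_1,k_2)$ by default (a flag enables $k_1^2 \ge 4k_0k_2$); the
mismatch classifier's median baseline fails in cohorts where most pairs
are related; credible intervals from the allele-frequency module are
central posterior intervals on a grid and need not match other tools'
conventions; and second-degree relationship types (half-sibling,
avuncular, grandparent–grandchild) are not distinguished — pairwise data
of this depth cannot separate them.
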