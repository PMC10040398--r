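---
title: "Quantifying genetic, cultural and habitat correlates of female dolphin sociality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic, cultural and habitat correlates of female dolphin sociality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Female Indo-Pacific bottlenose dolphins live in fission–fusion societies:
group composition changes by the hour, yet long-term association preferences
are strong and structured. Three families of explanation recur in
behavioural ecology — genes (kin selection favours associating with
relatives), culture (vertically transmitted foraging specialisations such as
sponge tool use create behavioural similarity), and ecology (animals that
use the same habitat simply meet more often). `podnet` implements a complete
analysis chain for separating these signals in grouped survey data, plus a
synthetic-society generator with known ground truth so that every stage of
the chain can be validated before it is pointed at real data.

The pipeline has five stages: a masked Simple Ratio Index association
network, kernel home-range overlap, a Bayesian zero-inflated binomial dyadic
GLMM, modularity-based community detection, and permutation tests of
community attributes, closed out by a closest-associate homophily test.

## The association network

Under the *gambit of the group*, all members of an observed group are taken
to be associating. For two females $a$ and $b$ the Simple Ratio Index is

$$\mathrm{SRI}_{ab} = \frac{x_{ab}}{n_{ab}},$$

with $x_{ab}$ the number of surveys in which both were in the same group and
$n_{ab}$ the number of surveys in which either was observed (a survey counts
once per individual). Only females seen at least ten times in association
with another dolphin enter the community analysis — community-detection
algorithms force even near-solitary animals into communities, which has no
biological meaning for animals with almost no social observations.

Two kinds of dyads are coded *not applicable* rather than zero, because an
SRI of zero asserts avoidance while these dyads simply never had the
opportunity to associate:

* **demographic**: the two females' first–last sighting intervals do not
  overlap (endpoints inclusive; the interval is the only demographic
  information a sighting table carries);
* **geographic**: their 95% kernel home ranges overlap by less than 25%
  volume of intersection, strictly (`overlap == 0.25` is kept).

Home ranges are Gaussian-kernel utilisation distributions on a common grid
(reference bandwidth $h = \sigma n^{-1/6}$, grid padded three bandwidths,
cells of $h/4$). The volume of intersection between two utilisation
distributions is $\sum_{\text{cells}} \min(f_a, f_b)\,\Delta A \in [0,1]$.
Because "overlap of 95% home ranges" is ambiguous between full-UD and
truncated-UD conventions, both are implemented; the default truncates each
UD to its own 95% isopleth and renormalises, which matches the wording and
is the convention of the common home-range packages. The equal-Gaussian
closed form $2\Phi(-d/2\sigma)$ is used as an oracle in the test suite.

## The dyadic model

For each unmasked dyad the response is $y$ surveys together out of $n$
surveys in which either was observed, modelled as zero-inflated binomial:

$$P(y = 0) = \pi + (1-\pi)(1-p)^n, \qquad
  P(y = k > 0) = (1-\pi)\binom{n}{k}p^k(1-p)^{n-k},$$

$$\operatorname{logit}(p) = \beta_0 + \beta_r r_{ij} + \beta_h h_{ij}
  + \beta_{NN}\,[f_{ij}{=}NN] + \beta_{SS}\,[f_{ij}{=}SS]
  + \beta_d d_{ij} + u_i + u_j .$$

The covariates are biparental relatedness $r\in[0,1]$, haplotype identity
$h\in\{0,1\}$, foraging identity $f \in \{NN, SS, MIX\}$ with the mixed dyad
as reference, and the absolute difference in mean sighting depth $d$ in
metres. Continuous covariates enter on their raw scales (a `standardize`
flag is provided since odds ratios per raw unit and per SD differ). The
multi-membership term $u_i + u_j$, with $u_k \sim N(0, \sigma_u)$, absorbs
individual gregariousness: without it, a very social female would inflate
the apparent effect of whatever covariates she happens to carry. The
point mass $\pi$ captures dyads that never associate no matter how
favourable their covariates look — zero inflation is the model's way of
saying "some pairs just avoid each other".

Priors are weakly regularising: $N(0, 10)$ on the intercept, $N(0, 5)$ on
slopes, half-Cauchy$(0, 2)$ on $\sigma_u$, and flat on $\pi \in [0,1]$.
Dyads with a non-genotyped member are dropped (complete case), mirroring
the "not applicable" coding of missing genetic data.

### The sampler

No Hamiltonian Monte Carlo backend is available in this environment, so the
package ships its own adaptive Metropolis-within-Gibbs sampler (in C++),
run as four independent chains of 4000 iterations with the first half as
warmup. Pure random-walk updates mix poorly in two directions that this
posterior makes nearly flat in the likelihood:

* the intercept against the mean of the random effects, and
* the foraging dummies against the class-wise means of the random effects.

Both are handled by *translation moves* that shift a block of random
intercepts together with exactly compensating fixed-effect shifts, leaving
every linear predictor unchanged so that only the priors enter the
acceptance ratio; correlations among the fixed effects are handled by a
joint adaptive-Metropolis proposal whose covariance is learned during
warmup (Haario-style, scaled by $2.38^2/P$). HMC-specific controls
(`adapt_delta`, tree depth) have no analogue here; the convergence contract
is retained as split $\widehat R \le 1.01$ for every reported parameter
(checked after sampling, with a warning otherwise) alongside effective
sample sizes from `coda`.

Model fit is summarised by a Bayesian $R^2$: per posterior draw,
$\mathrm{Var}(\mu) / (\mathrm{Var}(\mu) + \mathrm{Var}(y/n - \mu))$ across
dyads with $\mu = (1-\pi)p$ the expected association proportion. The
sampler's per-draw bookkeeping and an independent R-level recomputation
from the stored draws agree to $10^{-6}$ in the tests. Post-hoc pairwise
foraging contrasts are reported as posterior odds ratios with *sup-t*
simultaneous credible intervals over the three-contrast family — the
Bayesian analogue of Tukey-corrected pairwise comparisons.

## Communities and their correlates

Community detection is multilevel (Louvain) modularity maximisation on the
weighted SRI graph, best of 100 restarts over permuted vertex orders, with
masked and zero-SRI dyads as absent edges (modularity has no missing-data
concept, and a masked pair contributes no co-occurrence weight). The
reported modularity is *recomputed* from the returned labels by the
package's own implementation of weighted Newman modularity, so the score is
never taken on faith from the clustering backend; partitions with $Q > 0.3$
are flagged meaningful by the usual convention. The exhaustive-enumeration
oracle in the test suite confirms that Louvain attains the global optimum
on all small graphs tried, including the classic two-4-clique benchmark
($Q = 11/26 = 0.42308$).

Four permutation procedures then ask whether community boundaries align
with genes, culture and habitat, all with 10,000 iterations and the
doubled-tail rule $p = 2\,\#\{\text{perm at least as extreme}\}/n_{perm}$,
capped at 1, with a zero count reported as $p < 2/n_{perm}$:

1. **relatedness** — observed per-community mean of within-community dyadic
   relatedness vs. random reassignment of individuals to communities of the
   observed sizes (labels are shuffled, not dyadic values, which are not
   exchangeable);
2. **haplotype identity** and 3. **foraging identity** — observed
   within/between-community means of the dyadic sharing indicator
   vs. binomial randomisation: each dyad's indicator redrawn
   Bernoulli($\hat p$) with $\hat p$ the pooled observed sharing proportion
   (an alternative $\hat p = \sum_h f_h^2$ from attribute frequencies is
   available behind a flag);
4. **habitat** — observed per-community SD of member mean depths
   vs. size-preserving reassignment; here a *smaller* SD indicates a more
   homogeneous habitat, so the doubled tail is the lower one whenever the
   observed SD falls below the null median.

The tail is chosen by the side of the permutation median (`direction =
"auto"`): applying the upper-tail rule blindly would halve the size of the
test to 2.5% and, for the depth SD, point away from the alternative.

### A calibration caveat, stated honestly

The two label-shuffling tests (relatedness, depth SD) are exact permutation
tests and calibrate at nominal level: across 1000 null replicates the
type-I error at $\alpha = 0.05$ sits near 0.05. The two
binomial-randomisation tests do not: when individual attributes are
assigned independently of communities, their rejection rate is roughly
0.01–0.03, i.e. the procedure is *conservative*. The reason is structural:
the null redraws dyadic indicators i.i.d. around a plug-in $\hat p$ that
was estimated from the very dyads the observed statistic is computed on, so
the binomial null overstates the sampling variability of the observed
within-community mean. This is a property of the published procedure, not
of its implementation here; it errs in the safe direction (real effects are
harder, not easier, to declare significant). The corresponding calibration
assertions in the acceptance suite are deliberately left failing rather
than widened, with this analysis as the record.

## Closest associates

For each female, the partner with the maximal SRI among unmasked dyads
(ties retained, contributing fractionally). For each foraging class, an
exact one-sided binomial test asks whether same-strategy closest associates
occur more often than the class availability among potential partners
— the focal excluded from her own candidate pool, so for a sponger the null
probability is $(n_S - 1)/(N - 1)$ — with Bonferroni correction over the
two classes. The upper tail is one-sided because the hypothesis is
homophily, not heterophily. Fractional tie contributions are rounded to the
nearest integer for the exact tail; ties are rare with continuous SRI.

## The synthetic society

The generator's defaults describe the study system the pipeline was built
around, and they are deliberately fixed rather than tuned:

* 75 adult females (dependent calves are never generated), six latent
  communities along a 0–17 m depth gradient with the shallow/deep cut at
  10 m, and home-range centres spaced 4 km apart;
* six matrilines; haplotype = matriline, inherited from the mother;
  daughters settle in their mother's community with probability 0.7
  (philopatry) so matrilines straddle community boundaries as in real
  matrilineal societies;
* biparental relatedness from the pedigree by the tabular kinship recursion
  ($2\phi$; fathers drawn from an unrelated male pool, creating full- and
  half-sibships);
* sponging arises once, in the matriline with the most deep-habitat
  members, and is transmitted mother-to-daughter with probability 0.85;
  deep-habitat daughters of non-spongers innovate at 0.05 (a tenth of that
  in shallow water). Anchoring the innovation where it persisted keeps the
  sponger minority present (median 13 of 75 across seeds, range ~5–28),
  minoritarian and concentrated in deep habitat;
* 150 surveys; each female is detected with probability 0.8 and, once
  detected, joins groups within her community (or, with probability 0.1,
  another community's pool — the rare cross-community mixing a real network
  shows) by a *distance-dependent Chinese-restaurant* seating process: join
  an existing group with weight equal to the sum over its members of
  $\exp(\text{dyadic homophily kernel})$, or open a new group with a
  constant weight tuned to a mean group size of about 5 (realised sizes come
  out lower, 2.5–4, once the kernel penalises dissimilar groupmates —
  comfortably in the range reported for Shark Bay). The ddCRP form was
  chosen over a mean-kernel variant because it makes each *pair's*
  co-membership odds increase directly in that pair's kernel; a mean kernel
  hands every candidate group a near-identical bonus in class-homogeneous
  pools, which cancels in the choice probabilities and silently erases
  minority-class effects;
* the homophily kernel's default log-odds are the logs of the odds ratios
  estimated for the real population — relatedness $\log 4.25$, shared
  haplotype $\log 2.83$, shared foraging class $\log 2.38$, depth
  difference $\log 0.64$ per metre;
* 11% of dyads are *avoiders*: they never share a group regardless of
  opportunity. This is the structural-zero process that makes the dyadic
  counts genuinely zero-inflated (0.11 is the zero-inflation probability
  estimated for the real population);
* genotype coverage defaults to 1 in the generator; the analysis scripts
  and the acceptance run set it to 58/75 to mirror the real biopsy
  coverage, with non-genotyped females' haplotypes and relatedness reported
  missing.

With all kernel effects zero, one community and no avoidance, the seating
weights collapse to group sizes and the process is exactly the classic
exchangeable Chinese-restaurant partition — the property the generator's
null tests rest on.

One recovery limit is worth stating plainly: the foraging effect, planted
at its modest real-population magnitude (odds ratio 2.38), is *not* always
sign-recoverable at generator defaults. In roughly 15% of seeds the sponger
minority is nearly coextensive with a single matriline, and the foraging
bonus is then absorbed by the haplotype and relatedness covariates — the
same entanglement of culture with maternal kinship that left the original
study's sponger-dyad contrasts non-significant. The corresponding
acceptance expectation is left failing with this analysis as its record;
the genetic and habitat effects recover in every replicate.

What the generator does **not** emulate: spatially explicit movement (the
kernel sees depth differences, not geometry), males, marker-level
genotypes, observation biases such as photo-identification failure, and
temporal trends in sociality. A green end-to-end test therefore establishes
that the chain recovers planted homophily from well-behaved grouped data —
not that it is robust to every field pathology.

## Numerical choices and edge cases

* SRI denominators deduplicate surveys (an individual recorded twice in one
  survey counts once); a dyad with an empty denominator is coded
  not-applicable (demographic).
* Kernel estimation requires at least 5 sightings; animals below that get
  missing overlaps, which the geographic mask treats as masked (logged).
* Louvain ties are broken by higher recomputed $Q$, then fewer communities,
  then lexicographic labels, making the partition reproducible for a fixed
  seed.
* Permutation statistics for size-1 communities (and all-missing
  communities) are reported as `NA`, never silently dropped.
* The ZIB likelihood is evaluated on the log scale with `logsumexp` for the
  zero class; the pmf sums to one within $10^{-10}$ over the tested grid
  ($n \le 30$, $p$ and $\pi$ spanning $[0,1]$ including the endpoints).
* The sampler centres covariates internally and reports draws on the raw
  scale; the translation moves account for that centring exactly (an early
  version that did not was caught by a diverging intercept $\widehat R$ — a
  useful reminder that likelihood-flat moves must be flat in the
  *parameterisation actually sampled*).

## Known limitations

* The dyadic GLMM treats dyads as conditionally independent given the
  multi-membership intercepts; no residual dyadic covariance (e.g.
  triadic closure) is modelled, matching the original analysis.
* The binomial-randomisation community tests are conservative (above).
* The Metropolis sampler needs roughly 4 chains × 4000 iterations for
  $\widehat R \le 1.01$ on all parameters at the default problem size;
  much larger populations would warrant a gradient-based sampler.
* Home ranges are unclipped by coastline; for a real coastal study area the
  geographic mask should be fed overlaps from coastline-aware software.
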