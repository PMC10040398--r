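# podnet

Association networks, dyadic models and community structure for
fission–fusion animal societies.

`podnet` implements the complete analysis chain used to ask what structures
female bottlenose dolphin society: genes (biparental relatedness, shared
mtDNA haplotype), culture (a vertically transmitted foraging specialisation
— sponge tool use), or habitat (water depth). It works from gambit-of-the-group
survey data — one row per individual per survey, with group membership —
and runs:

1. **Masked SRI network** — the Simple Ratio Index
   `SRI = x / n_either` (surveys together over surveys in which either was
   observed), with dyads that *could not* associate coded "not applicable"
   rather than zero: non-overlapping sighting-date spans (demographic) or
   < 25% volume-of-intersection overlap of 95% kernel home ranges
   (geographic).
2. **Zero-inflated binomial dyadic GLMM** — surveys-together counts with
   logit-linear effects of relatedness, haplotype identity, foraging
   identity (both-non-spongers / both-spongers / mixed) and depth
   difference, multi-membership random intercepts `u_i + u_j`, and a
   zero-inflation mass for structural never-associating pairs. Fitted by an
   adaptive MCMC sampler written for this package (4 chains × 4000
   iterations, weakly regularising priors, split R-hat ≤ 1.01 contract),
   reporting odds ratios, Bayesian R², VIFs and Tukey-style simultaneous
   foraging contrasts.
3. **Louvain community detection** — weighted modularity maximisation with
   restart + refinement, modularity recomputed independently of the
   clustering backend, `Q > 0.3` flagged meaningful.
4. **Community permutation tests** — four procedures (relatedness,
   haplotype identity, foraging identity, depth SD) against 10,000
   size-preserving permutations or binomial randomisations, doubled-tail
   p-values.
5. **Closest-associate homophily** — Bonferroni-corrected exact binomial
   tests of whether females' top associates share their foraging strategy.

A synthetic-society generator (pedigrees with matrilineal haplotypes,
vertically transmitted sponging concentrated in deep habitat, a
distance-dependent Chinese-restaurant grouping process with known homophily
log-odds, structural dyad avoidance) provides ground truth for end-to-end
validation. See `vignettes/female-dolphin-sociality.Rmd` for the model
details and design rationale.

## Worked example

```r
library(podnet)

# a 75-female society at the package's default "stated world"
soc <- simulate_society(population_config(genotype_coverage = 58/75, seed = 1))

res <- run_pipeline(soc$sightings, soc$individuals, soc$relatedness_observed,
                    spec = zib_spec(), n_perm = 10000, seed = 1)
res$partition
res$fit
print(res$perm$haplotype)
```

Output from this exact run:

```
Community partition: 6 communities, Q = 0.8212 (meaningful, Q > 0.3)
community
 1  2  3  4  5  6
15 14 12 12 12 10

Zero-inflated binomial dyadic GLMM ( 322 dyads, 58 individuals )
  Bayesian R2: 0.383 [0.343, 0.422]
  zero-inflation: 0.197 [0.156, 0.244]
  odds ratios:
 term odds_ratio lower upper
    r      1.485 1.227 1.810
    h      2.117 1.940 2.319
  fNN      1.242 0.992 1.548
  fSS      1.715 1.275 2.315
    d      0.838 0.814 0.861
  max split R-hat: 1.006

Permutation test: haplotype identity within/between communities ( 10000 permutations )
    group  observed       p
1  within 0.4941634 < 2e-04
2 between 0.1074499 < 2e-04
```

Reading it: the synthetic society's six planted communities are recovered
with high modularity; in the dyadic model, sharing a haplotype more than
doubles the odds of being seen together (OR 2.12), each metre of depth
difference cuts them by ~16% (OR 0.84), sponger pairs associate most
strongly (OR 1.72 vs mixed pairs), and haplotype sharing is far commoner
within communities (0.49) than between (0.11) against the binomial null —
the same qualitative picture as the real population the defaults emulate.

Each stage is also available piecemeal (`filter_individuals`,
`compute_sri`, `demographic_mask`, `overlap_matrix`, `geographic_mask`,
`build_dyad_table`, `fit_zib_glmm`, `detect_communities`,
`perm_relatedness`, `perm_haplotype`, `perm_foraging`, `perm_depth_sd`,
`closest_associates`, `homophily_binomial_test`), and the numbered scripts
under `analysis/` run the same workflow stage by stage, writing tables and
figures under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_network.R
Rscript analysis/03_dyadic_model.R --seed 1
Rscript analysis/04_communities.R --seed 1
Rscript analysis/05_permutations.R --seed 1
Rscript analysis/06_closest_associates.R
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch on the default synthetic society
— simulation, masked SRI network with kernel home-range overlap, the full
4 × 4000-iteration dyadic model, Louvain communities, all four 10,000-
iteration permutation tests and the closest-associate test — logging a
summary and writing the JSON report to `--out`.
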