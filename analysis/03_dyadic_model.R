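#!/usr/bin/env Rscript

# Stage 3: the Bayesian zero-inflated binomial dyadic GLMM.
#
# For every unmasked dyad, the count of surveys together out of surveys in
# which either female was observed is modelled as zero-inflated binomial with
# logit-linear fixed effects (biparental relatedness, haplotype identity,
# foraging identity with MIX as reference, absolute depth difference) and
# multi-membership random intercepts u_i + u_j. Dyads with a non-genotyped
# member are dropped (complete case), mirroring "not applicable" coding.
# 4 chains x 4000 iterations, half warmup; VIF collinearity diagnostics and
# Tukey-style simultaneous foraging contrasts accompany the fit.
#
# Reads:  results/data/*, results/network/*
# Writes: results/model/{summary.csv, odds_ratios.csv, contrasts.csv,
#         model.json}

suppressPackageStartupMessages(library(podnet))

seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

sightings <- read_sightings("results/data/sightings.csv")
attributes <- read_attributes("results/data/individuals.csv")
relatedness <- read_relatedness("results/data/relatedness.csv")
keep <- filter_individuals(sightings, "in_association", 10)
assoc <- compute_sri(sightings, keep)
assoc <- demographic_mask(assoc, sightings)
overlap <- overlap_matrix(sightings, keep)
assoc <- geographic_mask(assoc, overlap)

dyads <- build_dyad_table(assoc, attributes, relatedness,
                          sightings = sightings)
vif <- vif_check(dyads)
message("VIF: ", paste(names(vif), round(vif, 2), sep = "=", collapse = ", "))

fit <- fit_zib_glmm(dyads, zib_spec(), seed = seed)
print(fit)
ct <- foraging_contrasts(fit)
print(ct)

dir.create("results/model", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(fit$summary, "results/model/summary.csv", row.names = FALSE)
utils::write.csv(fit$odds_ratios, "results/model/odds_ratios.csv",
                 row.names = FALSE)
utils::write.csv(ct, "results/model/contrasts.csv", row.names = FALSE)
grDevices::png("results/model/traceplots.png", 1600, 1200, res = 150)
plot(fit)
grDevices::dev.off()
grDevices::png("results/model/pp_check.png", 1600, 700, res = 150)
pp_check_zib(fit, seed = seed)
grDevices::dev.off()
jsonlite::write_json(
  list(seed = seed, n_dyads = fit$n_dyads, n_dropped = fit$n_dropped,
       vif = as.list(round(vif, 4)),
       bayes_R2 = as.list(fit$bayes_R2),
       zero_inflation = as.list(fit$zero_inflation),
       max_rhat = max(fit$summary$rhat), min_ess = min(fit$summary$ess)),
  "results/model/model.json", auto_unbox = TRUE, digits = NA)
message("written to results/model/")
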