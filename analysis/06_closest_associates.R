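#!/usr/bin/env Rscript

# Stage 6: closest-associate foraging homophily.
#
# Each female's top associate by SRI (ties retained fractionally), the
# proportion of same-strategy closest associates per foraging class, and the
# Bonferroni-corrected exact binomial test against class availability among
# potential partners.
#
# Reads:  results/data/*, results/network implied by recomputation
# Writes: results/closest/{closest_associates.csv, homophily.csv}

suppressPackageStartupMessages(library(podnet))

sightings <- read_sightings("results/data/sightings.csv")
attributes <- read_attributes("results/data/individuals.csv")
keep <- filter_individuals(sightings, "in_association", 10)
assoc <- compute_sri(sightings, keep)
assoc <- demographic_mask(assoc, sightings)
assoc <- geographic_mask(assoc, overlap_matrix(sightings, keep))

ca <- closest_associates(assoc, attributes)
out <- homophily_binomial_test(ca)
print(out)

dir.create("results/closest", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(ca, "results/closest/closest_associates.csv",
                 row.names = FALSE)
utils::write.csv(out, "results/closest/homophily.csv", row.names = FALSE)
message("written to results/closest/")
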