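#!/usr/bin/env Rscript

# Stage 2: from sightings to the masked SRI association network.
#
# Applies the inclusion filter (>= 10 sightings in association with at least
# one other female), computes the Simple Ratio Index for every dyad, then
# codes dyads "not applicable" when the pair could never have associated:
# no overlap of sighting-date spans (demographic) or < 25% volume of
# intersection of 95% kernel home ranges (geographic).
#
# Reads:  results/data/sightings.csv
# Writes: results/network/{sri.csv, sri_mask.csv, sri.graphml, overlap.csv}

suppressPackageStartupMessages(library(podnet))

sightings <- read_sightings("results/data/sightings.csv")
keep <- filter_individuals(sightings, mode = "in_association",
                           min_sightings = 10)
message(length(keep), " females pass the inclusion filter")

assoc <- compute_sri(sightings, keep)
assoc <- demographic_mask(assoc, sightings)
overlap <- overlap_matrix(sightings, keep)
assoc <- geographic_mask(assoc, overlap, threshold = 0.25)
print(assoc)

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
write_association(assoc, "results/network")
utils::write.csv(data.frame(id = rownames(overlap), overlap,
                            check.names = FALSE),
                 "results/network/overlap.csv", row.names = FALSE)
message("written to results/network/")
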