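#!/usr/bin/env Rscript

# Stage 4: community structure of the SRI network.
#
# Multilevel (Louvain) modularity maximisation on the masked SRI graph, best
# of 100 restarts, with the modularity score recomputed independently of the
# clustering backend. A partition is considered meaningful when Q > 0.3.
# Also draws the community-coloured network (squares = shallow females,
# circles = deep, asterisks = spongers).
#
# Reads:  results/data/*, results/network/*
# Writes: results/communities/{communities.csv, partition.json,
#         network.png}

suppressPackageStartupMessages(library(podnet))

seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

sightings <- read_sightings("results/data/sightings.csv")
attributes <- read_attributes("results/data/individuals.csv")
keep <- filter_individuals(sightings, "in_association", 10)
assoc <- compute_sri(sightings, keep)
assoc <- demographic_mask(assoc, sightings)
assoc <- geographic_mask(assoc, overlap_matrix(sightings, keep))

part <- detect_communities(assoc, seed = seed, n_restarts = 100)
print(part)

dir.create("results/communities", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(data.frame(id = names(part$labels),
                            community = unname(part$labels)),
                 "results/communities/communities.csv", row.names = FALSE)
jsonlite::write_json(list(seed = seed, modularity = part$modularity,
                          n_communities = part$n_communities,
                          meaningful = part$meaningful,
                          sizes = as.list(table(part$labels))),
                     "results/communities/partition.json",
                     auto_unbox = TRUE, digits = NA)
grDevices::png("results/communities/network.png", 1400, 1400, res = 150)
set.seed(seed)
plot_network(assoc, part, attributes)
grDevices::dev.off()
message("written to results/communities/")
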