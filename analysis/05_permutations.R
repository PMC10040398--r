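#!/usr/bin/env Rscript

# Stage 5: do genes, culture and habitat follow the community boundaries?
#
# Four permutation procedures against the detected partition, 10,000
# iterations each, doubled-tail p-values:
#   - biparental relatedness: labels shuffled at community sizes, observed
#     per-community within means vs permuted means
#   - haplotype identity and foraging identity: dyadic sharing indicators
#     vs binomial randomisation at the pooled observed sharing rate,
#     within and between communities
#   - habitat: per-community SD of member mean depths vs size-preserving
#     reassignment (smaller SD = more homogeneous habitat, lower tail)
#
# Reads:  results/data/*, results/communities/communities.csv
# Writes: results/permutations/{permutations.json, <test>.png}

suppressPackageStartupMessages(library(podnet))

seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

sightings <- read_sightings("results/data/sightings.csv")
attributes <- read_attributes("results/data/individuals.csv")
relatedness <- read_relatedness("results/data/relatedness.csv")
comm <- utils::read.csv("results/communities/communities.csv")
labels <- stats::setNames(comm$community, comm$id)

keep <- names(labels)
md <- tapply(sightings$depth[sightings$individual_id %in% keep],
             sightings$individual_id[sightings$individual_id %in% keep], mean)
at <- attributes[match(keep, attributes$id), ]
haps <- stats::setNames(as.character(at$haplotype_observed), keep)
sponge <- stats::setNames(at$sponger, keep)

tests <- list(
  relatedness = perm_relatedness(relatedness, labels, 10000, seed = seed + 1),
  haplotype = perm_haplotype(haps, labels, 10000, seed = seed + 2),
  foraging = perm_foraging(sponge, labels, 10000, seed = seed + 3),
  depth_sd = perm_depth_sd(md[keep], labels, 10000, seed = seed + 4)
)

dir.create("results/permutations", recursive = TRUE, showWarnings = FALSE)
for (nm in names(tests)) {
  print(tests[[nm]])
  grDevices::png(sprintf("results/permutations/%s.png", nm), 1200, 800,
                 res = 150)
  plot_permutation(tests[[nm]])
  grDevices::dev.off()
}
jsonlite::write_json(
  lapply(tests, function(pr) list(
    statistic = pr$statistic, n_perm = pr$n_perm, seed = pr$seed,
    observed = as.list(pr$observed),
    p = lapply(pr$p, function(p) list(p = as.numeric(p),
                                      label = attr(p, "label"))))),
  "results/permutations/permutations.json", auto_unbox = TRUE, digits = NA,
  null = "null")
message("written to results/permutations/")
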