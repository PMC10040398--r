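test_that("configuration is validated", {
  expect_error(population_config(detection_prob = 1.4), "probabilities")
  expect_error(population_config(n_females = 3), "n_females")
  expect_error(population_config(n_surveys = 0), "n_surveys")
  expect_error(population_config(homophily_effects = c(relatedness = 1)),
               "homophily_effects")
})

test_that("haplotypes are matrilineal and sponging transmits vertically", {
  # single matriline: every dyad shares the haplotype
  pop1 <- generate_population(population_config(n_females = 20,
                                                n_matrilines = 1, seed = 4))
  expect_length(unique(pop1$individuals$haplotype), 1L)

  # perfect vertical transmission from a sponger founder matriline: every
  # maternal descendant of a sponger is a sponger
  pop <- generate_population(population_config(
    n_females = 40, n_matrilines = 3, vertical_transmission_prob = 1,
    seed = 9))
  ind <- pop$individuals
  moms <- stats::setNames(ind$sponger, ind$id)
  daughters_of_spongers <- ind[!is.na(ind$mother_id) &
                                 moms[ind$mother_id] %in% TRUE, ]
  expect_true(all(daughters_of_spongers$sponger))

  # every daughter carries her mother's haplotype
  hap <- stats::setNames(ind$haplotype, ind$id)
  with_mother <- ind[!is.na(ind$mother_id), ]
  expect_identical(with_mother$haplotype, unname(hap[with_mother$mother_id]))
})

test_that("pedigree relatedness matches textbook identities and the recursive oracle", {
  # hand-built two-generation pedigree: full sisters, half sisters,
  # parent-offspring, unrelated founders
  ped <- data.frame(
    id = c("M1", "M2", "A", "B", "fullS1", "fullS2", "halfS"),
    mother_id = c(NA, NA, NA, NA, "A", "A", "A"),
    father_id = c(NA, NA, NA, NA, "M1", "M1", "M2"),
    stringsAsFactors = FALSE
  )
  A <- pedigree_relatedness(ped)
  expect_equal(A["fullS1", "fullS2"], 0.5)       # full sisters
  expect_equal(A["fullS1", "halfS"], 0.25)       # half sisters
  expect_equal(A["A", "fullS1"], 0.5)            # parent-offspring
  expect_equal(A["M1", "M2"], 0)                 # founders unrelated
  expect_equal(unname(diag(A)), rep(1, 7))       # non-inbred diagonal

  # full agreement with the independent recursive kinship oracle on a
  # generated pedigree
  pop <- generate_population(population_config(n_females = 15, seed = 2))
  A2 <- pedigree_relatedness(pop$pedigree)
  K <- kinship_recursive(pop$pedigree)
  expect_equal(unname(A2[rownames(K), colnames(K)]), unname(2 * K),
               tolerance = 1e-12)

  # cycles are refused
  bad <- data.frame(id = c("a", "b"), mother_id = c("b", "a"),
                    father_id = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(pedigree_relatedness(bad), "cycle")
})

test_that("surveys are reproducible and respect the one-group-per-survey rule", {
  cfg <- population_config(n_females = 15, n_communities = 2,
                           n_surveys = 25, seed = 11)
  s1 <- simulate_society(cfg)
  s2 <- simulate_society(cfg)
  expect_identical(s1$sightings, s2$sightings)
  expect_identical(s1$relatedness, s2$relatedness)
  s3 <- simulate_society(population_config(n_females = 15, n_communities = 2,
                                           n_surveys = 25, seed = 12))
  expect_false(identical(s1$sightings, s3$sightings))

  # (survey, individual) unique; every survey has >= 1 group
  key <- paste(s1$sightings$survey_id, s1$sightings$individual_id)
  expect_false(anyDuplicated(key) > 0)
  expect_gt(length(unique(s1$sightings$survey_id)), 0)

  # per-sighting depth jitters around home depth, so mean depth is recoverable
  md <- tapply(s1$sightings$depth, s1$sightings$individual_id, mean)
  home <- stats::setNames(s1$individuals$mean_depth, s1$individuals$id)
  expect_lt(max(abs(md - home[names(md)])), 1.5)
})

test_that("zero homophily effects in one community make dyads exchangeable", {
  # all dyads should co-occur at the same rate; chi-square goodness of fit on
  # pooled together-counts must not reject at alpha = 0.01
  cfg <- population_config(
    n_females = 8, n_matrilines = 2, n_communities = 1, n_surveys = 400,
    homophily_effects = c(relatedness = 0, haplotype = 0, foraging = 0, depth = 0),
    p_avoid = 0, detection_prob = 1, seed = 21)
  soc <- simulate_society(cfg)
  assoc <- compute_sri(soc$sightings, soc$individuals$id)
  x <- assoc$x[upper.tri(assoc$x)]
  gof <- stats::chisq.test(x, p = rep(1 / length(x), length(x)))
  expect_gt(gof$p.value, 0.01)
})

test_that("a depth-difference penalty induces negative SRI-depth correlation", {
  negs <- vapply(1:30, function(s) {
    cfg <- population_config(n_females = 25, n_communities = 3,
                             n_surveys = 60, seed = 1000 + s)
    soc <- simulate_society(cfg)
    assoc <- compute_sri(soc$sightings, soc$individuals$id)
    dd <- abs(outer(soc$individuals$mean_depth, soc$individuals$mean_depth, "-"))
    ut <- upper.tri(dd)
    stats::cor(assoc$sri[ut], dd[ut], method = "spearman",
               use = "complete.obs") < 0
  }, TRUE)
  expect_gte(mean(negs), 0.95)
})

test_that("a society round-trips losslessly through disk", {
  soc <- simulate_society(population_config(n_females = 10, n_surveys = 15,
                                            genotype_coverage = 0.8, seed = 5))
  dir <- withr::local_tempdir()
  write_society(soc, dir)
  s2 <- read_sightings(file.path(dir, "sightings.csv"))
  expect_equal(nrow(s2), nrow(soc$sightings))
  expect_equal(s2$depth, soc$sightings$depth)
  expect_identical(s2$individual_id, soc$sightings$individual_id)
  R <- read_relatedness(file.path(dir, "relatedness.csv"))
  expect_equal(R, soc$relatedness_observed)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$n_females, 10L)
})
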