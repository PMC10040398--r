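make_small_society <- function(seed = 1, n = 12, surveys = 30) {
  simulate_society(population_config(n_females = n, n_matrilines = 3,
                                     n_communities = 2, n_surveys = surveys,
                                     seed = seed))
}

test_that("dyad table carries counts and the four covariates", {
  soc <- make_small_society()
  assoc <- compute_sri(soc$sightings, soc$individuals$id)
  dy <- build_dyad_table(assoc, soc$individuals, soc$relatedness,
                         sightings = soc$sightings)
  n <- nrow(soc$individuals)
  expect_equal(nrow(dy), n * (n - 1) / 2)   # no masks: all dyads
  expect_true(all(dy$y <= dy$n))
  expect_true(all(dy$d >= 0))
  ind <- soc$individuals
  sp <- stats::setNames(ind$sponger, ind$id)
  expect_equal(unname(dy$f == "SS"), unname(sp[dy$i] & sp[dy$j]))
  # depth difference is plain arithmetic on per-individual mean depths
  md <- tapply(soc$sightings$depth, soc$sightings$individual_id, mean)
  expect_equal(dy$d, as.numeric(abs(md[dy$i] - md[dy$j])), tolerance = 1e-12)
  # unknown individual in the association matrix is an input error
  expect_error(build_dyad_table(assoc, ind[-1, ], soc$relatedness),
               "input error")
})

test_that("missing genetic data propagates as NA covariates", {
  soc <- simulate_society(population_config(n_females = 12, n_surveys = 20,
                                            genotype_coverage = 0.5, seed = 8))
  assoc <- compute_sri(soc$sightings, soc$individuals$id)
  dy <- build_dyad_table(assoc, soc$individuals, soc$relatedness_observed,
                         sightings = soc$sightings)
  miss <- soc$individuals$id[!soc$individuals$genotyped]
  affected <- dy$i %in% miss | dy$j %in% miss
  expect_true(all(is.na(dy$r[affected])))
  expect_true(all(is.na(dy$h[affected])))
  expect_false(anyNA(dy$r[!affected]))
})

test_that("ZIB log-likelihood matches hand enumeration and degenerate cases", {
  # pi = 1: all mass at zero
  expect_equal(zib_loglik(0, 10, 0.3, 1), 0)
  # pi = 0: exactly binomial
  expect_equal(zib_loglik(0:5, 5, 0.37, 0), dbinom(0:5, 5, 0.37, log = TRUE))
  # n = 2, p = 0.5, pi = 0.1: hand-enumerated pmf
  expect_equal(exp(zib_loglik(0:2, 2, 0.5, 0.1)), c(0.325, 0.45, 0.225),
               tolerance = 1e-12)
  # domain violations
  expect_error(zib_loglik(3, 2, 0.5, 0.1), "math error")
  expect_error(zib_loglik(1, 2, 1.5, 0.1), "math error")
})

test_that("ZIB pmf normalises over a parameter grid", {
  for (n in c(1, 5, 17, 30)) for (p in c(0, 1e-6, 0.3, 0.97, 1))
    for (pi in c(0, 0.11, 0.5, 1)) {
      tot <- sum(exp(zib_loglik(0:n, n, p, pi)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
})

test_that("VIF matches closed forms", {
  set.seed(2)
  n <- 4000
  # exactly orthogonal designs via QR
  Z <- qr.Q(qr(matrix(rnorm(n * 5), n)))
  dy <- data.frame(i = "a", j = "b", y = 0, n = 1,
                   r = Z[, 1], h = Z[, 2],
                   f = factor(ifelse(Z[, 3] > 0, "NN", "MIX"),
                              levels = c("MIX", "NN", "SS")),
                   d = Z[, 4])
  v <- vif_check(dy)
  expect_equal(unname(v[c("r", "h", "d")]), rep(1, 3), tolerance = 0.05)

  # a pair with exact correlation 0.8 (others orthogonal): VIF = 1/(1-0.64)
  r_ <- Z[, 1]
  h_ <- 0.8 * Z[, 1] + sqrt(1 - 0.64) * Z[, 2]
  dy2 <- dy
  dy2$r <- r_; dy2$h <- h_; dy2$d <- Z[, 4]
  v2 <- vif_check(dy2)
  expect_equal(unname(v2["r"]), 1 / (1 - 0.64), tolerance = 0.05)
  expect_equal(unname(v2["h"]), 1 / (1 - 0.64), tolerance = 0.05)

  # duplicated covariate: infinite VIF
  dy3 <- dy
  dy3$h <- dy3$r
  expect_true(is.infinite(unname(suppressWarnings(vif_check(dy3))["r"])))
})

test_that("the sampler recovers a planted relatedness effect from model-simulated data", {
  ors <- vapply(1:6, function(s) {
    dy <- simulate_zib_dyads(
      n_ind = 75, n_surveys = 150,
      beta = c(intercept = -3.5, r = log(4), h = 0, fNN = 0, fSS = 0, d = 0),
      seed = 500 + s)
    fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(), seed = s))
    fit$odds_ratios$odds_ratio[fit$odds_ratios$term == "r"]
  }, 0)
  expect_gte(mean(ors >= 2.5 & ors <= 6.5), 0.9)
})

test_that("null data give odds-ratio intervals covering 1", {
  covered <- unlist(lapply(1:8, function(s) {
    dy <- simulate_zib_dyads(
      n_ind = 40, n_surveys = 80,
      beta = c(intercept = -3.5, r = 0, h = 0, fNN = 0, fSS = 0, d = 0),
      seed = 900 + s)
    fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(), seed = s))
    with(fit$odds_ratios, lower <= 1 & upper >= 1)
  }))
  expect_gte(mean(covered), 0.9)
})

test_that("the likelihood is symmetric in dyad member order", {
  dy <- simulate_zib_dyads(n_ind = 20, n_surveys = 40,
                           beta = c(intercept = -3, r = 1, h = 0.5,
                                    fNN = 0.3, fSS = 0.6, d = -0.2),
                           seed = 3)
  swap <- sample(nrow(dy), nrow(dy) %/% 2)
  dy2 <- dy
  dy2$i[swap] <- dy$j[swap]
  dy2$j[swap] <- dy$i[swap]
  f1 <- suppressWarnings(fit_zib_glmm(dy, test_spec(chains = 1, iter = 400),
                                      seed = 5))
  f2 <- suppressWarnings(fit_zib_glmm(dy2, test_spec(chains = 1, iter = 400),
                                      seed = 5))
  # identical multi-membership structure => identical chains under one seed
  expect_equal(f1$draws, f2$draws, tolerance = 1e-12)
})

test_that("Bayesian R2 recomputed in R agrees with the sampler's bookkeeping", {
  dy <- simulate_zib_dyads(n_ind = 25, n_surveys = 60,
                           beta = c(intercept = -3, r = 1.4, h = 0.8,
                                    fNN = 0.4, fSS = 0.9, d = -0.4),
                           seed = 12)
  fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(chains = 2, iter = 800),
                                       seed = 2))
  r2 <- bayes_r2(fit)
  expect_equal(r2$mean, unname(fit$bayes_R2["mean"]), tolerance = 1e-6)
  expect_true(r2$lower <= r2$mean && r2$mean <= r2$upper)
  # informative predictors: R2 clearly positive
  expect_gt(r2$mean, 0.1)
})

test_that("foraging contrasts reconstruct all pairs and respect identities", {
  dy <- simulate_zib_dyads(n_ind = 30, n_surveys = 60,
                           beta = c(intercept = -3, r = 0, h = 0,
                                    fNN = 0.7, fSS = 0.7, d = 0),
                           seed = 21)
  fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(chains = 2, iter = 800),
                                       seed = 4))
  ct <- foraging_contrasts(fit)
  expect_setequal(ct$contrast, c("NN vs MIX", "SS vs MIX", "NN vs SS"))
  # NN vs SS odds ratio = (NN vs MIX) / (SS vs MIX) draw-wise, so the point
  # estimates multiply
  expect_equal(ct$odds_ratio[ct$contrast == "NN vs SS"],
               ct$odds_ratio[ct$contrast == "NN vs MIX"] /
                 ct$odds_ratio[ct$contrast == "SS vs MIX"], tolerance = 1e-9)
  # identical planted class effects: NN vs SS interval covers 1
  row <- ct[ct$contrast == "NN vs SS", ]
  expect_true(row$lower <= 1 && row$upper >= 1)
  # simultaneous intervals are at least as wide as marginal ones
  dr <- fit$draws[, "fNN"]
  marg <- exp(quantile(dr, c(0.025, 0.975)))
  rowNN <- ct[ct$contrast == "NN vs MIX", ]
  expect_lte(rowNN$lower, marg[[1]] + 1e-9)
  expect_gte(rowNN$upper, marg[[2]] - 1e-9)
})

test_that("complete-case handling and convergence reporting work", {
  soc <- simulate_society(population_config(n_females = 20, n_surveys = 40,
                                            genotype_coverage = 0.7, seed = 31))
  assoc <- compute_sri(soc$sightings, soc$individuals$id)
  dy <- build_dyad_table(assoc, soc$individuals, soc$relatedness_observed,
                         sightings = soc$sightings)
  expect_message(
    fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(chains = 2, iter = 600),
                                         seed = 1)),
    "missing genetic")
  expect_equal(fit$n_dyads + fit$n_dropped, nrow(dy))
  expect_true(all(c("rhat", "ess") %in% names(fit$summary)))
  expect_true(all(is.finite(fit$summary$rhat)))
  # the summary table orders mean within its interval
  expect_true(all(fit$summary$lower <= fit$summary$mean &
                    fit$summary$mean <= fit$summary$upper))
})

test_that("diagnostic plots run and the PPC tracks the observed zeros", {
  dy <- simulate_zib_dyads(n_ind = 20, n_surveys = 50,
                           beta = c(intercept = -3, r = 1, h = 0.6,
                                    fNN = 0.3, fSS = 0.5, d = -0.3),
                           zi = 0.15, seed = 44)
  fit <- suppressWarnings(fit_zib_glmm(dy, test_spec(chains = 2, iter = 600),
                                       seed = 6))
  png_file <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_file)
  expect_no_error(plot(fit))
  out <- pp_check_zib(fit, ndraws = 100, seed = 2)
  grDevices::dev.off()
  expect_true(file.exists(png_file))
  # a well-specified model reproduces the observed zero-dyad count
  qs <- stats::quantile(out$replicated_zeros, c(0.005, 0.995))
  expect_gte(out$observed_zeros, qs[[1]])
  expect_lte(out$observed_zeros, qs[[2]])
})
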