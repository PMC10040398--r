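test_that("the doubled-tail p-value rule is applied literally", {
  perm <- 1:10000 / 10000
  # 250 of 10000 permuted >= observed, upper tail -> p = 0.05
  expect_equal(as.numeric(two_sided_p(0.97501, perm, "upper")), 0.05)
  # observed at the median: capped at 1
  expect_equal(as.numeric(two_sided_p(median(perm), perm)), 1)
  # observed above all permuted values: reported as "< 2/n_perm"
  p0 <- two_sided_p(2, perm, "upper")
  expect_equal(as.numeric(p0), 2e-04)
  expect_match(attr(p0, "label"), "^< ")
  # lower tail mirrors the rule
  expect_equal(as.numeric(two_sided_p(0.00059, perm, "lower")),
               2 * 5 / 10000)
  # auto picks the nearer tail
  expect_equal(as.numeric(two_sided_p(0.99, perm, "auto")),
               as.numeric(two_sided_p(0.99, perm, "upper")))
  expect_equal(as.numeric(two_sided_p(0.01, perm, "auto")),
               as.numeric(two_sided_p(0.01, perm, "lower")))
})

test_that("degenerate attribute distributions give p = 1", {
  ids <- sprintf("I%02d", 1:12)
  labels <- stats::setNames(rep(1:3, each = 4), ids)
  # constant relatedness
  R <- matrix(0.2, 12, 12, dimnames = list(ids, ids)); diag(R) <- 1
  pr <- perm_relatedness(R, labels, n_perm = 200, seed = 1)
  expect_true(all(vapply(pr$p, as.numeric, 0) == 1))
  # single haplotype
  hap <- stats::setNames(rep("H1", 12), ids)
  ph <- perm_haplotype(hap, labels, n_perm = 200, seed = 1)
  expect_equal(unname(ph$observed["within"]), 1)
  expect_equal(as.numeric(ph$p$within), 1)
  # all non-spongers
  fl <- stats::setNames(rep(FALSE, 12), ids)
  pf <- perm_foraging(fl, labels, n_perm = 200, seed = 1)
  expect_equal(as.numeric(pf$p$within), 1)
  # constant depths: SD identically zero
  dep <- stats::setNames(rep(5, 12), ids)
  pd <- perm_depth_sd(dep, labels, n_perm = 200, seed = 1)
  expect_true(all(vapply(pd$p, as.numeric, 0) == 1))
})

test_that("permutation tests are seed-reproducible and stable in n_perm", {
  ids <- sprintf("I%02d", 1:20)
  labels <- stats::setNames(rep(1:4, each = 5), ids)
  R <- random_sym_matrix(ids, seed = 3)
  a <- perm_relatedness(R, labels, n_perm = 500, seed = 7)
  b <- perm_relatedness(R, labels, n_perm = 500, seed = 7)
  expect_identical(a$permuted, b$permuted)
  expect_equal(vapply(a$p, as.numeric, 0), vapply(b$p, as.numeric, 0))
  # doubling n_perm moves p by no more than ~2 MC standard errors
  big <- perm_relatedness(R, labels, n_perm = 4000, seed = 8)
  for (k in seq_along(a$p)) {
    pa <- as.numeric(a$p[[k]]); pb <- as.numeric(big$p[[k]])
    se <- 2 * sqrt(pa * (1 - pa) / 500) + 0.02
    expect_lt(abs(pa - pb), 2 * se + 1e-9)
  }
})

test_that("permutation p agrees with exhaustive enumeration on 4 individuals", {
  # 2 communities of 2: all C(4,2) = 6 labelled assignments enumerable
  ids <- c("a", "b", "c", "d")
  labels <- stats::setNames(c(1, 1, 2, 2), ids)
  R <- random_sym_matrix(ids, seed = 5)
  obs1 <- mean(R["a", "b"])   # community 1 within-mean
  combs <- utils::combn(4, 2)
  exact_stats <- apply(combs, 2, function(ii) R[ii[1], ii[2]])
  # exact doubled-tail p for community 1, auto direction
  exact_p <- function(obs, stats_) {
    dirn <- if (obs >= stats::median(stats_)) "upper" else "lower"
    cnt <- if (dirn == "upper") sum(stats_ >= obs) else sum(stats_ <= obs)
    min(1, 2 * cnt / length(stats_))
  }
  pr <- perm_relatedness(R, labels, n_perm = 20000, seed = 2)
  expect_equal(as.numeric(pr$p$community_1),
               exact_p(obs1, exact_stats), tolerance = 0.02)

  dep <- stats::setNames(c(1, 4, 9, 16), ids)
  sds <- apply(combs, 2, function(ii) stats::sd(dep[ii]))
  pd <- perm_depth_sd(dep, labels, n_perm = 20000, seed = 3)
  expect_equal(as.numeric(pd$p$community_1),
               exact_p_lower <- {
                 obs <- stats::sd(dep[c("a", "b")])
                 min(1, 2 * sum(sds <= obs) / length(sds))
               }, tolerance = 0.02)
})

test_that("planted community structure is detected by all four tests", {
  set.seed(42)
  ids <- sprintf("I%02d", 1:36)
  labels <- stats::setNames(rep(1:3, each = 12), ids)
  # relatedness elevated within communities
  R <- matrix(rbeta(36 * 36, 1, 40), 36, dimnames = list(ids, ids))
  within <- outer(labels, labels, "==")
  R[within] <- R[within] + 0.22
  R <- (R + t(R)) / 2; diag(R) <- 1
  pr <- perm_relatedness(R, labels, n_perm = 2000, seed = 1)
  expect_true(all(vapply(pr$p, as.numeric, 0) < 0.01))

  # haplotypes nearly community-specific
  hap <- stats::setNames(paste0("H", labels), ids)
  hap[1] <- "H2"
  ph <- perm_haplotype(hap, labels, n_perm = 2000, seed = 2)
  expect_lt(as.numeric(ph$p$within), 0.01)
  expect_gt(ph$observed["within"], ph$observed["between"])

  # spongers concentrated in community 1
  fl <- stats::setNames(labels == 1, ids)
  fl[c(2, 30)] <- !fl[c(2, 30)]
  pf <- perm_foraging(fl, labels, n_perm = 2000, seed = 3)
  expect_lt(as.numeric(pf$p$within), 0.05)

  # depths homogeneous within communities (3 m vs 13 m with 1 m jitter)
  dep <- stats::setNames(c(3, 8, 13)[labels] + rnorm(36, 0, 1), ids)
  pd <- perm_depth_sd(dep, labels, n_perm = 2000, seed = 4)
  expect_true(all(vapply(pd$p, as.numeric, 0) < 0.05))
})

test_that("size-1 communities report missing statistics", {
  ids <- c("a", "b", "c")
  labels <- stats::setNames(c(1, 1, 2), ids)
  R <- random_sym_matrix(ids, seed = 1)
  pr <- perm_relatedness(R, labels, n_perm = 100, seed = 1)
  expect_true(is.na(pr$observed["community_2"]))
  expect_true(is.na(as.numeric(pr$p$community_2)))
  dep <- stats::setNames(c(2, 7, 4), ids)
  pd <- perm_depth_sd(dep, labels, n_perm = 100, seed = 1)
  expect_true(is.na(pd$observed["community_2"]))
})

test_that("the frequency-based binomial probability option works", {
  ids <- sprintf("I%02d", 1:20)
  labels <- stats::setNames(rep(1:2, each = 10), ids)
  set.seed(6)
  hap <- stats::setNames(sample(c("H1", "H2", "H3"), 20, TRUE), ids)
  p1 <- perm_haplotype(hap, labels, n_perm = 400, seed = 1, p_hat = "pooled")
  p2 <- perm_haplotype(hap, labels, n_perm = 400, seed = 1, p_hat = "frequency")
  f <- table(hap) / 20
  # frequency mode centres the null at sum of squared haplotype frequencies
  expect_equal(mean(p2$permuted[, "within"]), sum(f^2), tolerance = 0.05)
  expect_s3_class(p1, "perm_result")
})
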