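# Independent oracles and fixture builders used across the suite. These
# deliberately use the dumbest correct algorithm (nested loops, exhaustive
# enumeration, closed forms) so they share no code path with the package.

# ---- sighting-table fixtures ------------------------------------------------

# random gambit-of-the-group sighting table: per survey, a random subset of
# individuals split uniformly at random into groups
random_sightings <- function(n_ind, n_surveys, seed, p_present = 0.6) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  rows <- list()
  for (s in seq_len(n_surveys)) {
    present <- ids[runif(n_ind) < p_present]
    if (!length(present)) next
    ngrp <- sample.int(max(1, length(present)), 1)
    grp <- sample.int(ngrp, length(present), replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      survey_id = sprintf("S%03d", s),
      date = as.Date("2010-01-01") + s,
      group_id = sprintf("S%03d_G%02d", s, grp),
      individual_id = present,
      depth = runif(length(present), 0, 17),
      x = rnorm(length(present), 0, 1000),
      y = rnorm(length(present), 0, 1000),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# brute-force SRI by looping over dyads and surveys: for each dyad, count
# surveys in the same group and surveys in which either appears
brute_sri <- function(sightings, ids) {
  n <- length(ids)
  sri <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  x_mat <- matrix(0, n, n, dimnames = list(ids, ids))
  ne_mat <- matrix(0, n, n, dimnames = list(ids, ids))
  by_survey <- split(sightings[, c("individual_id", "group_id")],
                     sightings$survey_id)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    x <- 0L; ne <- 0L
    for (rows in by_survey) {
      ga <- rows$group_id[rows$individual_id == ids[a]]
      gb <- rows$group_id[rows$individual_id == ids[b]]
      if (length(ga) || length(gb)) ne <- ne + 1L
      if (length(ga) && length(gb) && any(ga %in% gb)) x <- x + 1L
    }
    if (ne > 0) sri[a, b] <- sri[b, a] <- x / ne
    x_mat[a, b] <- x_mat[b, a] <- x
    ne_mat[a, b] <- ne_mat[b, a] <- ne
  }
  list(sri = sri, x = x_mat, n_either = ne_mat)
}

# ---- pedigree kinship oracle ------------------------------------------------

# classic recursive kinship coefficient phi(a, b) with memoisation-free
# recursion (fine for tiny pedigrees); founders unrelated
kinship_recursive <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  mo <- ped$mother_id; fa <- ped$father_id
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    ia <- idx[[a]]; ib <- idx[[b]]
    if (ia == ib) {
      return(0.5 * (1 + phi(mo[ia], fa[ia])))
    }
    # recurse on the later-generation individual (the one with parents listed
    # after the other, assuming parents precede offspring in the table)
    if (ia < ib) { tmp <- ia; ia <- ib; ib <- tmp }
    if (is.na(mo[ia]) && is.na(fa[ia])) return(0)
    0.5 * (phi(mo[ia], ped$id[ib]) + phi(fa[ia], ped$id[ib]))
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (a in seq_len(n)) for (b in a:n)
    K[a, b] <- K[b, a] <- phi(ped$id[a], ped$id[b])
  K
}

# ---- exhaustive set partitions / modularity oracle --------------------------

all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  parts <- list()
  rg <- integer(n); rg[1] <- 1L
  recur <- function(i, maxv) {
    if (i > n) { parts[[length(parts) + 1L]] <<- rg[seq_len(n)]; return(invisible()) }
    for (v in seq_len(maxv + 1L)) { rg[i] <<- v; recur(i + 1L, max(maxv, v)) }
  }
  recur(2L, 1L)
  parts
}

brute_best_modularity <- function(W) {
  qs <- vapply(all_partitions(nrow(W)), function(p) modularity_score(W, p), 0)
  max(qs)
}

two_clique_graph <- function() {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  W[4, 5] <- W[5, 4] <- 1
  diag(W) <- 0
  W
}

# ---- misc -------------------------------------------------------------------

# symmetric "relatedness-like" matrix with dimnames
random_sym_matrix <- function(ids, seed, gen = function(m) stats::rbeta(m, 1, 8)) {
  set.seed(seed)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[upper.tri(M)] <- gen(n * (n - 1) / 2)
  M <- M + t(M)
  diag(M) <- 1
  M
}

# analytic bivariate-normal UD on a grid, for volume-intersection oracles
gaussian_ud <- function(mx, my, sd, grid) {
  z <- outer(stats::dnorm(grid$x, mx, sd), stats::dnorm(grid$y, my, sd))
  cell_area <- mean(diff(grid$x)) * mean(diff(grid$y))
  z <- z / (sum(z) * cell_area)
  ud <- list(x = grid$x, y = grid$y, z = z, cell_area = cell_area, h = sd)
  ud$isopleth_95 <- ud_isopleth(ud, 0.95)
  class(ud) <- "ud"
  ud
}

# a fast zib_spec for tests (sign/coverage checks need far fewer draws than
# publication-grade inference)
test_spec <- function(chains = 2, iter = 1200)
  zib_spec(chains = chains, iter = iter)

# simulate a dyad table directly from the ZIB GLMM (the model's own world,
# used for parameter-recovery oracles)
simulate_zib_dyads <- function(n_ind = 40, n_surveys = 100, beta,
                               sigma_u = 0.3, zi = 0.1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  depth <- runif(n_ind, 0, 17)
  hap <- sample(sprintf("H%d", 1:5), n_ind, replace = TRUE)
  sponger <- seq_len(n_ind) %in% sample.int(n_ind, max(3, round(n_ind / 5)))
  r_vals <- c(0, 0.0625, 0.125, 0.25, 0.5)
  u <- rnorm(n_ind, 0, sigma_u)
  pairs <- which(upper.tri(diag(n_ind)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  r <- sample(r_vals, nrow(pairs), replace = TRUE, prob = c(.6, .15, .1, .1, .05))
  h <- as.numeric(hap[i] == hap[j])
  f <- ifelse(sponger[i] & sponger[j], "SS",
              ifelse(!sponger[i] & !sponger[j], "NN", "MIX"))
  d <- abs(depth[i] - depth[j])
  eta <- beta[["intercept"]] + beta[["r"]] * r + beta[["h"]] * h +
    beta[["fNN"]] * (f == "NN") + beta[["fSS"]] * (f == "SS") +
    beta[["d"]] * d + u[i] + u[j]
  n <- rbinom(nrow(pairs), n_surveys, 0.9) + 5L
  y <- ifelse(runif(nrow(pairs)) < zi, 0L, rbinom(nrow(pairs), n, plogis(eta)))
  data.frame(i = ids[i], j = ids[j], y = y, n = n, r = r, h = h,
             f = factor(f, levels = c("MIX", "NN", "SS")), d = d,
             stringsAsFactors = FALSE)
}
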