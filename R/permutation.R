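#' Doubled-tail permutation p-value
#'
#' The two-sided rule: the number of permutation values at least as extreme
#' as the observed value, multiplied by 2 and divided by the number of
#' permutations, capped at 1. `direction = "upper"` counts `perm >= obs`
#' (the rule as classically written), `"lower"` counts `perm <= obs` (needed
#' when the alternative is a *smaller* statistic, e.g. within-community depth
#' SD), and `"auto"` (default) picks the tail on the side of the permutation
#' median, which reproduces the upper rule whenever the observed value sits
#' above the null centre while remaining a valid two-sided test. A zero count
#' is reported as `p < 2/n_perm` (the p-value is set to `2/n_perm` and the
#' `label` attribute records the inequality).
#'
#' @param observed Observed statistic (scalar).
#' @param permuted Numeric vector of permutation statistics.
#' @param direction `"auto"`, `"upper"` or `"lower"`.
#' @return p-value in `(0, 1]`, with attribute `label` (a printable string).
#' @export
two_sided_p <- function(observed, permuted,
                        direction = c("auto", "upper", "lower")) {
  direction <- match.arg(direction)
  permuted <- permuted[!is.na(permuted)]
  n <- length(permuted)
  if (is.na(observed) || n < 1) {
    p <- NA_real_
    attr(p, "label") <- "NA"
    return(p)
  }
  if (direction == "auto")
    direction <- if (observed >= stats::median(permuted)) "upper" else "lower"
  cnt <- if (direction == "upper") sum(permuted >= observed)
         else sum(permuted <= observed)
  if (cnt == 0) {
    p <- 2 / n
    attr(p, "label") <- paste0("< ", format(2 / n))
  } else {
    p <- min(2 * cnt / n, 1)
    attr(p, "label") <- format(p)
  }
  p
}

.perm_result <- function(statistic, observed, permuted, p, n_perm, seed) {
  structure(list(statistic = statistic, observed = observed,
                 permuted = permuted, p = p, n_perm = n_perm, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test:", x$statistic, "(", x$n_perm, "permutations )\n")
  lab <- vapply(seq_along(x$p), function(k) {
    l <- attr(x$p[[k]], "label")
    if (is.null(l)) format(x$p[[k]]) else l
  }, "")
  print(data.frame(group = names(x$observed),
                   observed = unname(x$observed),
                   p = lab, row.names = NULL))
  invisible(x)
}

## per-community mean of within-community dyadic values of a symmetric matrix
.within_means <- function(M, labels) {
  vapply(sort(unique(labels)), function(cc) {
    idx <- which(labels == cc)
    if (length(idx) < 2) return(NA_real_)
    sub <- M[idx, idx]
    v <- sub[upper.tri(sub)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}

#' Community permutation test for biparental relatedness
#'
#' Observed statistic: mean within-community dyadic relatedness, per
#' community. Null: individuals (hence their rows/columns of the relatedness
#' matrix) are randomly reassigned to communities of the observed sizes —
#' labels are shuffled, not dyadic values, since dyadic values are not
#' exchangeable. Communities of size 1 have no within dyad and report `NA`.
#' Individuals without relatedness data contribute nothing (their dyads are
#' NA and excluded from means).
#'
#' @param relatedness Symmetric relatedness matrix (dimnames = ids).
#' @param partition A `community_partition` or named label vector.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param direction Tail rule for [two_sided_p()].
#' @return A `perm_result` with per-community observed means and p-values.
#' @export
perm_relatedness <- function(relatedness, partition, n_perm = 10000,
                             seed = 1L, direction = "auto") {
  labels <- if (inherits(partition, "community_partition")) partition$labels
            else partition
  ids <- names(labels)
  if (!all(ids %in% rownames(relatedness)))
    stop("relatedness matrix does not cover the partition", call. = FALSE)
  M <- relatedness[ids, ids]
  obs <- .within_means(M, labels)
  comms <- sort(unique(labels))
  names(obs) <- paste0("community_", comms)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, length(comms))
  lab <- unname(labels)
  for (b in seq_len(n_perm))
    perm[b, ] <- .within_means(M, sample(lab))
  p <- lapply(seq_along(comms), function(k)
    two_sided_p(obs[k], perm[, k], direction))
  names(p) <- names(obs)
  .perm_result("within-community mean biparental relatedness", obs, perm,
               p, n_perm, seed)
}

## shared-attribute dyadic indicator test with binomial randomisation:
## within/between means compared to Binomial(n_dyads, p_hat)/n_dyads draws
.perm_binomial <- function(indicator_matrix, labels, n_perm, seed, direction,
                           statistic, p_hat_mode = c("pooled", "frequency"),
                           attr_values = NULL) {
  p_hat_mode <- match.arg(p_hat_mode)
  same <- indicator_matrix
  within <- outer(labels, labels, "==")
  ut <- upper.tri(same)
  ok <- !is.na(same[ut])
  ind <- same[ut][ok]
  w <- within[ut][ok]
  if (!length(ind)) stop("no dyads with attribute data", call. = FALSE)
  n_w <- sum(w); n_b <- sum(!w)
  obs <- c(within = if (n_w) mean(ind[w]) else NA_real_,
           between = if (n_b) mean(ind[!w]) else NA_real_)
  p_hat <- if (p_hat_mode == "pooled") mean(ind)
           else sum((table(attr_values) / length(attr_values))^2)
  set.seed(seed)
  perm <- cbind(
    within = if (n_w) stats::rbinom(n_perm, n_w, p_hat) / n_w else rep(NA_real_, n_perm),
    between = if (n_b) stats::rbinom(n_perm, n_b, p_hat) / n_b else rep(NA_real_, n_perm))
  p <- list(within = two_sided_p(obs["within"], perm[, "within"], direction),
            between = two_sided_p(obs["between"], perm[, "between"], direction))
  .perm_result(statistic, obs, perm, p, n_perm, seed)
}

#' Community permutation test for haplotype identity
#'
#' Dyadic indicator: 1 if two females share the mtDNA haplotype, 0 otherwise
#' (dyads with a non-genotyped member are excluded from both observed and
#' permuted statistics). Observed: mean indicator within and between
#' communities. Null: each dyad's indicator is redrawn Bernoulli(p-hat)
#' 10,000 times (binomial randomisation). By default p-hat is the pooled
#' observed proportion of sharing dyads; `p_hat = "frequency"` instead uses
#' the expected sharing under the observed haplotype frequencies,
#' `sum(f_h^2)`.
#'
#' @param haplotypes Named character vector (NA = not genotyped).
#' @param partition A `community_partition` or named label vector.
#' @param n_perm,seed,direction As in [perm_relatedness()].
#' @param p_hat `"pooled"` (default) or `"frequency"`.
#' @return A `perm_result` with `within`/`between` statistics.
#' @export
perm_haplotype <- function(haplotypes, partition, n_perm = 10000, seed = 1L,
                           direction = "auto", p_hat = "pooled") {
  labels <- if (inherits(partition, "community_partition")) partition$labels
            else partition
  ids <- names(labels)
  hap <- haplotypes[ids]
  same <- outer(hap, hap, "==")  # NA propagates for missing genotypes
  .perm_binomial(same, unname(labels), n_perm, seed, direction,
                 "haplotype identity within/between communities",
                 p_hat_mode = p_hat, attr_values = hap[!is.na(hap)])
}

#' Community permutation test for foraging identity
#'
#' As [perm_haplotype()] with the dyadic indicator 1 for sponger--sponger and
#' non-sponger--non-sponger dyads, 0 for mixed dyads; foraging class is known
#' for all individuals.
#'
#' @param spongers Named logical vector of sponger flags.
#' @param partition A `community_partition` or named label vector.
#' @param n_perm,seed,direction,p_hat As in [perm_haplotype()].
#' @return A `perm_result` with `within`/`between` statistics.
#' @export
perm_foraging <- function(spongers, partition, n_perm = 10000, seed = 1L,
                          direction = "auto", p_hat = "pooled") {
  labels <- if (inherits(partition, "community_partition")) partition$labels
            else partition
  ids <- names(labels)
  fl <- spongers[ids]
  same <- outer(fl, fl, "==")
  .perm_binomial(same, unname(labels), n_perm, seed, direction,
                 "foraging identity within/between communities",
                 p_hat_mode = p_hat, attr_values = fl)
}

#' Community permutation test for habitat (depth) homogeneity
#'
#' Observed statistic: standard deviation of member mean depths, per
#' community. Null: individual mean depths are randomly reassigned to
#' communities of the observed sizes. A smaller observed than permuted SD
#' indicates that the community occupies a more homogeneous habitat, so the
#' default tail is `"lower"`. Size-1 communities report `NA`.
#'
#' @param depths Named numeric vector of individual mean depths (m).
#' @param partition A `community_partition` or named label vector.
#' @param n_perm,seed As in [perm_relatedness()].
#' @param direction Tail rule; default `"lower"`.
#' @return A `perm_result` with per-community observed SDs and p-values.
#' @export
perm_depth_sd <- function(depths, partition, n_perm = 10000, seed = 1L,
                          direction = "auto") {
  labels <- if (inherits(partition, "community_partition")) partition$labels
            else partition
  ids <- names(labels)
  dep <- depths[ids]
  if (anyNA(dep)) stop("missing mean depth for some individuals", call. = FALSE)
  lab <- unname(labels)
  comms <- sort(unique(lab))
  comsd <- function(values) vapply(comms, function(cc) {
    v <- values[lab == cc]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, 0)
  obs <- comsd(dep)
  names(obs) <- paste0("community_", comms)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, length(comms))
  for (b in seq_len(n_perm)) perm[b, ] <- comsd(sample(dep))
  p <- lapply(seq_along(comms), function(k)
    two_sided_p(obs[k], perm[, k], direction))
  names(p) <- names(obs)
  .perm_result("within-community SD of mean depth", obs, perm, p, n_perm, seed)
}
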