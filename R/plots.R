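#' Plot the association network coloured by community
#'
#' Nodes are individuals (squares = shallow habitat, circles = deep,
#' asterisk = sponger), colours are communities, edge width is SRI.
#'
#' @param assoc An `assoc_matrix`.
#' @param partition A `community_partition` (optional).
#' @param attributes Data frame with `id`, `sponger`, `habitat` (optional).
#' @param ... Passed to [igraph::plot.igraph()].
#' @return Invisibly, the igraph object plotted.
#' @export
plot_network <- function(assoc, partition = NULL, attributes = NULL, ...) {
  g <- as_igraph(assoc)
  ids <- assoc$individuals
  vcol <- "grey70"
  if (!is.null(partition))
    vcol <- grDevices::hcl.colors(max(partition$labels), "Dark 3")[
      partition$labels[ids]]
  shape <- rep("circle", length(ids))
  lab <- rep("", length(ids))
  if (!is.null(attributes)) {
    at <- attributes[match(ids, attributes$id), ]
    if ("habitat" %in% names(at))
      shape <- ifelse(at$habitat == "shallow", "square", "circle")
    lab <- ifelse(at$sponger, "*", "")
  }
  w <- igraph::E(g)$weight
  igraph::plot.igraph(g, vertex.color = vcol, vertex.shape = shape,
                      vertex.label = lab, vertex.label.cex = 1.4,
                      vertex.size = 7, edge.width = 0.5 + 6 * w / max(w), ...)
  invisible(g)
}

#' Plot a permutation-test null distribution against the observed values
#'
#' One box per statistic (community, or within/between) with the permutation
#' distribution; observed values overlaid as filled points.
#'
#' @param pr A `perm_result`.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, `pr`.
#' @export
plot_permutation <- function(pr, ...) {
  graphics::boxplot(pr$permuted, names = names(pr$observed),
                    main = pr$statistic, ylab = "statistic",
                    las = 2, outline = FALSE, ...)
  graphics::points(seq_along(pr$observed), pr$observed, pch = 19,
                   col = "red3", cex = 1.2)
  invisible(pr)
}

#' Trace plots for a fitted dyadic model
#'
#' One panel per main parameter, chains overlaid — the standard visual check
#' for mixing and stationarity.
#'
#' @param x A `zib_fit`.
#' @param parameters Which parameters (default: all fixed effects plus
#'   `sigma_u` and `zi_prob`).
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.zib_fit <- function(x, parameters = x$summary$parameter, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(parameters)),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(x$chains), "Dark 3")
  for (p in parameters) {
    rng <- range(vapply(x$chains, function(m) range(m[, p]), numeric(2)))
    graphics::plot(x$chains[[1]][, p], type = "l", col = cols[1], ylim = rng,
                   ylab = p, xlab = "")
    if (length(x$chains) > 1)
      for (ch in 2:length(x$chains))
        graphics::lines(x$chains[[ch]][, p], col = cols[ch])
  }
  invisible(x)
}

#' Posterior predictive check for the dyadic model
#'
#' Draws replicated dyad counts from the fitted zero-inflated binomial model
#' and overlays (a) the replicated distribution of the number of zero dyads
#' against the observed count and (b) the observed SRI histogram against the
#' replicated mean histogram — the two features the zero-inflated model must
#' reproduce.
#'
#' @param fit A `zib_fit`.
#' @param ndraws Posterior draws to use (default 200).
#' @param seed RNG seed for the replicates.
#' @return Invisibly, a list with the observed and replicated zero counts.
#' @export
pp_check_zib <- function(fit, ndraws = 200, seed = 1L) {
  set.seed(seed)
  d <- fit$data
  ids <- fit$individuals
  par_names <- intersect(colnames(fit$draws),
                         c("intercept", "r", "h", "fNN", "fSS", "d"))
  X <- cbind(intercept = 1, r = d$r / fit$scales["r"], h = d$h,
             fNN = as.numeric(d$f == "NN"), fSS = as.numeric(d$f == "SS"),
             d = d$d / fit$scales["d"])[, par_names, drop = FALSE]
  take <- sample.int(nrow(fit$draws), min(ndraws, nrow(fit$draws)))
  i1 <- match(d$i, ids); i2 <- match(d$j, ids)
  U <- fit$draws[, paste0("u[", ids, "]"), drop = FALSE]
  zeros <- vapply(take, function(s) {
    eta <- as.vector(X %*% fit$draws[s, par_names]) + U[s, i1] + U[s, i2]
    pi_s <- fit$draws[s, "zi_prob"]
    yrep <- ifelse(stats::runif(nrow(d)) < pi_s, 0L,
                   stats::rbinom(nrow(d), d$n, stats::plogis(eta)))
    sum(yrep == 0)
  }, 0)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::hist(zeros, breaks = 20, main = "zero dyads", col = "grey80",
                 xlab = "replicated count",
                 xlim = range(c(zeros, sum(d$y == 0))))
  graphics::abline(v = sum(d$y == 0), col = "red3", lwd = 2)
  s1 <- take[1]
  eta1 <- as.vector(X %*% fit$draws[s1, par_names]) + U[s1, i1] + U[s1, i2]
  pi1 <- fit$draws[s1, "zi_prob"]
  yrep1 <- ifelse(stats::runif(nrow(d)) < pi1, 0L,
                  stats::rbinom(nrow(d), d$n, stats::plogis(eta1)))
  br <- seq(0, max(d$y / d$n, yrep1 / d$n) + 0.02, by = 0.02)
  graphics::hist(d$y / d$n, breaks = br, col = grDevices::adjustcolor("grey40", 0.6),
                 main = "SRI distribution", xlab = "SRI")
  graphics::hist(yrep1 / d$n, breaks = br,
                 col = grDevices::adjustcolor("red3", 0.35), add = TRUE)
  invisible(list(observed_zeros = sum(d$y == 0), replicated_zeros = zeros))
}
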