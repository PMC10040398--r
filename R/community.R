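#' Weighted Newman modularity of a labelled partition
#'
#' `Q = (1 / 2m) * sum_ij (w_ij - k_i k_j / 2m) * delta(c_i, c_j)` with
#' `k_i` the weighted degree and `2m` the total weight. Self-loops are
#' ignored. This is deliberately an independent reimplementation of the
#' quantity the Louvain algorithm maximises, so partitions found by
#' [detect_communities()] can be re-scored without circularity.
#'
#' @param weights Symmetric non-negative weight matrix (masked/absent dyads
#'   as 0).
#' @param labels Community labels, one per node (any atomic type).
#' @return Modularity Q.
#' @export
modularity_score <- function(weights, labels) {
  W <- as.matrix(weights)
  if (length(labels) != nrow(W))
    stop("label error: need one label per node", call. = FALSE)
  if (anyNA(labels)) stop("label error: NA label", call. = FALSE)
  diag(W) <- 0
  two_m <- sum(W)
  if (two_m <= 0) return(0)
  k <- rowSums(W)
  S <- outer(labels, labels, "==")
  sum((W - outer(k, k) / two_m) * S) / two_m
}

## Greedy single-node refinement: repeatedly move the node whose best
## reassignment (to any other community or a fresh singleton) most increases
## modularity, until no move helps. Louvain only ever aggregates, so on small
## graphs it can land in optima that one node-move would escape; this pass
## (the local-move half of Leiden-style refinement) closes that gap.
.refine_partition <- function(W, labels) {
  m2 <- sum(W)                 # 2m
  if (m2 <= 0) return(labels)
  k <- rowSums(W)
  repeat {
    improved <- FALSE
    for (v in seq_along(labels)) {
      cur <- labels[v]
      cand <- unique(c(cur, labels[-v], max(labels) + 1L))
      w_vc <- vapply(cand, function(cc)
        sum(W[v, labels == cc & seq_along(labels) != v]), 0)
      tot <- vapply(cand, function(cc)
        sum(k[labels == cc & seq_along(labels) != v]), 0)
      cur_i <- match(cur, cand)
      # delta Q of moving v from its community (without v) to candidate cc
      dq <- (w_vc - w_vc[cur_i]) / (m2 / 2) -
        k[v] * (tot - tot[cur_i]) / (2 * (m2 / 2)^2)
      best <- which.max(dq)
      if (dq[best] > 1e-12 && cand[best] != cur) {
        labels[v] <- cand[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  labels
}

#' Multilevel (Louvain) community detection on an association matrix
#'
#' Runs the weighted Louvain algorithm `n_restarts` times under permuted
#' vertex orders, follows each run with a greedy single-node refinement pass
#' (Louvain only aggregates, so small graphs can need one node-move to reach
#' the optimum), and keeps the partition with the highest modularity,
#' recomputed independently by [modularity_score()]. Ties are broken by fewer
#' communities, then by lexicographic canonical labels. Masked ("not
#' applicable") and zero-SRI dyads contribute no edge; individuals with no
#' usable edges end up in singleton communities (reported). A partition is
#' flagged `meaningful` when Q exceeds the conventional 0.3 threshold.
#'
#' @param assoc An `assoc_matrix`, or a symmetric weight matrix.
#' @param seed Integer seed.
#' @param n_restarts Louvain restarts (default 100).
#' @return Object of class `community_partition`: named integer `labels`
#'   (community ids numbered by decreasing size), `modularity`,
#'   `n_communities`, `meaningful`.
#' @export
detect_communities <- function(assoc, seed = 1L, n_restarts = 100) {
  if (inherits(assoc, "assoc_matrix")) {
    W <- assoc$sri
    W[assoc$mask != "value"] <- 0
    W[is.na(W)] <- 0
  } else {
    W <- as.matrix(assoc)
    W[is.na(W)] <- 0
  }
  if (is.null(rownames(W))) dimnames(W) <- list(seq_len(nrow(W)), seq_len(nrow(W)))
  ids <- rownames(W)
  if (sum(W) == 0) stop("empty graph: no usable associations", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  iso <- igraph::degree(g) == 0
  if (any(iso))
    message(sum(iso), " isolated individuals become singleton communities")
  set.seed(seed)
  best <- NULL
  consider <- function(memb, best) {
    Q <- modularity_score(W, memb)
    canon <- match(memb, unique(memb))
    cand <- list(Q = Q, labels = canon, k = length(unique(canon)))
    if (is.null(best) ||
        cand$Q > best$Q + 1e-12 ||
        (abs(cand$Q - best$Q) <= 1e-12 &&
         (cand$k < best$k ||
          (cand$k == best$k &&
           paste(cand$labels, collapse = ",") < paste(best$labels, collapse = ","))))) {
      cand
    } else best
  }
  n <- nrow(W)
  for (r in seq_len(n_restarts)) {
    perm <- sample(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    ## vertex i of g is vertex perm[i] of gp, so map memberships back
    memb <- as.integer(igraph::membership(cl))[perm]
    best <- consider(.refine_partition(W, memb), best)
    ## modularity maximisation is NP-hard and Louvain only aggregates, so a
    ## few greedy descents from random labellings guard against the (small)
    ## local optima the aggregation path cannot escape
    rand0 <- sample.int(min(n, max(2L, best$k + 1L)), n, replace = TRUE)
    best <- consider(.refine_partition(W, rand0), best)
  }
  ## zero-degree nodes carry no modularity weight, so their labels are
  ## arbitrary ties; pin them to singletons as documented
  if (any(iso))
    best$labels[iso] <- max(best$labels) + seq_len(sum(iso))
  ## relabel by decreasing community size for stable presentation
  sizes <- table(best$labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- match(best$labels, as.integer(names(sizes))[ord])
  labels <- stats::setNames(relab, ids)
  out <- list(labels = labels, modularity = best$Q,
              n_communities = length(unique(relab)),
              meaningful = best$Q > 0.3)
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, Q =",
      format(x$modularity, digits = 4),
      if (x$meaningful) "(meaningful, Q > 0.3)" else "(Q <= 0.3)", "\n")
  print(table(community = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert-Arabie ARI: 1 for identical partitions, ~0 for independent
#' labellings.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
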