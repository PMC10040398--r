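#' Apply sighting-based inclusion filters
#'
#' Two filters are in common use for gambit-of-the-group data: keep females
#' seen at least `min_sightings` times *in association* with at least one
#' other individual (group size >= 2), the filter required before community
#' detection so that near-solitary animals are not forced into communities; or
#' keep individuals seen at least `min_sightings` times irrespective of
#' association.
#'
#' @param sightings Sighting table (`survey_id`, `group_id`, `individual_id`,
#'   ...).
#' @param mode `"in_association"` or `"any"`.
#' @param min_sightings Minimum number of qualifying surveys (default 10).
#' @return Character vector of retained individual ids (sorted).
#' @export
filter_individuals <- function(sightings, mode = c("in_association", "any"),
                               min_sightings = 10) {
  mode <- match.arg(mode)
  if (!nrow(sightings)) stop("empty sighting table", call. = FALSE)
  if (mode == "any") {
    n <- tapply(sightings$survey_id, sightings$individual_id,
                function(s) length(unique(s)))
  } else {
    gsize <- stats::ave(seq_len(nrow(sightings)), sightings$group_id,
                        FUN = length)
    soc <- sightings[gsize >= 2, ]
    if (!nrow(soc)) {
      warning("no individuals ever seen in association; empty network")
      return(character(0))
    }
    n <- tapply(soc$survey_id, soc$individual_id,
                function(s) length(unique(s)))
  }
  keep <- sort(names(n)[n >= min_sightings])
  if (!length(keep)) warning("inclusion filter removed every individual")
  keep
}

## internal: per-individual-by-survey presence and per-survey group membership
.incidence <- function(sightings, ids) {
  surveys <- sort(unique(sightings$survey_id))
  sub <- sightings[sightings$individual_id %in% ids, , drop = FALSE]
  S <- matrix(0L, length(ids), length(surveys), dimnames = list(ids, surveys))
  S[cbind(match(sub$individual_id, ids), match(sub$survey_id, surveys))] <- 1L
  groups <- sort(unique(sub$group_id))
  B <- matrix(0L, length(ids), length(groups), dimnames = list(ids, groups))
  B[cbind(match(sub$individual_id, ids), match(sub$group_id, groups))] <- 1L
  list(seen = S, grouped = B)
}

#' Simple Ratio Index association matrix
#'
#' For each dyad, SRI = x / n_either: the number of surveys in which the two
#' were observed in the same group over the number of surveys in which either
#' was observed. A survey counts once per individual even if she was recorded
#' in several groups within it (which the input format forbids anyway). Dyads
#' with `n_either = 0` are coded not-applicable (demographic).
#'
#' @param sightings Sighting table.
#' @param individuals Character vector of individual ids to include (e.g. from
#'   [filter_individuals()]).
#' @return An `assoc_matrix`: list with symmetric matrices `sri`, `x`
#'   (surveys together), `n_either`, and `mask` (character,
#'   `"value"`/`"demographic"`/`"geographic"`; diagonal `"diagonal"`).
#' @export
compute_sri <- function(sightings, individuals) {
  ids <- sort(unique(individuals))
  if (length(ids) < 2) stop("need at least two individuals", call. = FALSE)
  inc <- .incidence(sightings, ids)
  together <- inc$grouped %*% t(inc$grouped)
  both <- inc$seen %*% t(inc$seen)
  n_i <- diag(both)
  n_either <- outer(n_i, n_i, "+") - both
  sri <- ifelse(n_either > 0, together / n_either, NA_real_)
  mask <- matrix("value", length(ids), length(ids), dimnames = list(ids, ids))
  mask[n_either == 0] <- "demographic"
  diag(mask) <- "diagonal"
  diag(sri) <- NA_real_
  storage.mode(together) <- "double"
  out <- list(sri = sri, x = together, n_either = n_either, mask = mask,
              individuals = ids)
  class(out) <- "assoc_matrix"
  out
}

#' Mask dyads without demographic overlap
#'
#' Two individuals whose sighting-date intervals (first seen to last seen) do
#' not overlap could never have associated; their SRI is coded
#' "not applicable" (demographic). Interval endpoints are inclusive: sharing a
#' single day counts as overlap.
#'
#' @param assoc An `assoc_matrix`.
#' @param sightings Sighting table with a `date` column (used to derive
#'   first/last sighting per individual).
#' @return The `assoc_matrix` with its mask updated.
#' @export
demographic_mask <- function(assoc, sightings) {
  ids <- assoc$individuals
  d <- sightings[sightings$individual_id %in% ids, ]
  d$date <- as.Date(d$date)
  first <- tapply(d$date, d$individual_id, min)
  last <- tapply(d$date, d$individual_id, max)
  first <- first[ids]; last <- last[ids]
  disjoint <- outer(last, first, "<") | t(outer(last, first, "<"))
  diag(disjoint) <- FALSE
  assoc$mask[disjoint & assoc$mask == "value"] <- "demographic"
  assoc$sri[assoc$mask == "demographic"] <- NA_real_
  assoc
}

#' Mask dyads without geographic overlap
#'
#' Dyads whose 95% home-range volume-of-intersection overlap is *strictly*
#' below the threshold (default 25%) are coded "not applicable" (geographic).
#' Missing overlap values (e.g. too few sightings for a kernel estimate) are
#' masked and reported.
#'
#' @param assoc An `assoc_matrix`.
#' @param overlap Symmetric overlap matrix in `[0, 1]` covering the
#'   individuals of `assoc` (dimnames used for alignment).
#' @param threshold Strict lower cut-off (default 0.25).
#' @return The `assoc_matrix` with its mask updated.
#' @export
geographic_mask <- function(assoc, overlap, threshold = 0.25) {
  ids <- assoc$individuals
  if (!all(ids %in% rownames(overlap)))
    stop("overlap matrix does not cover all individuals", call. = FALSE)
  ov <- overlap[ids, ids]
  missing_ov <- is.na(ov)
  if (any(missing_ov[upper.tri(missing_ov)]))
    message(sum(missing_ov[upper.tri(missing_ov)]),
            " dyads lack an overlap estimate; masked as geographic")
  drop <- (missing_ov | ov < threshold)
  diag(drop) <- FALSE
  assoc$mask[drop & assoc$mask == "value"] <- "geographic"
  assoc$sri[assoc$mask == "geographic"] <- NA_real_
  assoc
}

#' @export
print.assoc_matrix <- function(x, ...) {
  ut <- upper.tri(x$sri)
  cat("Simple Ratio Index association matrix\n")
  cat("  individuals:", length(x$individuals), "\n")
  cat("  dyads:", sum(ut), " (", sum(x$mask[ut] == "value"), "usable,",
      sum(x$mask[ut] == "demographic"), "demographic NA,",
      sum(x$mask[ut] == "geographic"), "geographic NA )\n")
  v <- x$sri[ut][x$mask[ut] == "value"]
  if (length(v))
    cat(sprintf("  SRI: mean %.3f, max %.3f, %.0f%% zero\n",
                mean(v), max(v), 100 * mean(v == 0)))
  invisible(x)
}

#' Convert an association matrix to an igraph graph
#'
#' Masked dyads and zero-SRI dyads contribute no edge; all individuals remain
#' as vertices (isolates become singleton communities downstream).
#'
#' @param assoc An `assoc_matrix`.
#' @return An undirected weighted [igraph::graph].
#' @export
as_igraph <- function(assoc) {
  W <- assoc$sri
  W[assoc$mask != "value"] <- 0
  W[is.na(W)] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}
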