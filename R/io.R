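#' Read a sighting table
#'
#' Validates the long survey format: one row per individual per survey with
#' columns `survey_id`, `date`, `group_id`, `individual_id`, `depth`, `x`,
#' `y`. Duplicate (survey, individual) rows — an individual cannot be in two
#' groups in one survey — and malformed rows raise errors with row numbers.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_sightings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty input: ", path, call. = FALSE)
  need <- c("survey_id", "date", "group_id", "individual_id", "depth", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(d[, c("survey_id", "individual_id")])
  if (any(dup))
    stop("duplicate (survey, individual) rows at lines: ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$depth) | d$depth < 0)
  if (length(bad))
    stop("malformed depth at lines: ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable dates in ", path, call. = FALSE)
  d
}

#' Read an individual attribute table
#'
#' @param path CSV with at least `id` and `sponger`; haplotype and depth
#'   columns are kept when present.
#' @return Data frame.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty input: ", path, call. = FALSE)
  if (!all(c("id", "sponger") %in% names(d)))
    stop("attribute table needs columns id, sponger", call. = FALSE)
  if (anyDuplicated(d$id)) stop("duplicate individual ids", call. = FALSE)
  d$sponger <- as.logical(d$sponger)
  d
}

#' Read a pairwise relatedness matrix
#'
#' First column = ids, remaining columns the matrix. Symmetry is enforced to
#' 1e-8; NA rows/columns mark non-genotyped individuals.
#'
#' @param path CSV file.
#' @return Symmetric numeric matrix.
#' @export
read_relatedness <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty input: ", path, call. = FALSE)
  ids <- as.character(d[[1]])
  M <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  dimnames(M) <- list(ids, colnames(M))
  if (!identical(rownames(M), colnames(M)))
    stop("relatedness matrix rows/columns disagree", call. = FALSE)
  asym <- max(abs(M - t(M)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-8)
    stop("validation error: relatedness matrix asymmetric beyond 1e-8",
         call. = FALSE)
  M
}

#' Write an association matrix
#'
#' SRI and mask as CSV plus a weighted edge list in GraphML for external
#' network tools.
#'
#' @param assoc An `assoc_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_association <- function(assoc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data.frame(id = assoc$individuals, assoc$sri,
                              check.names = FALSE),
                   file.path(dir, "sri.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = assoc$individuals, assoc$mask,
                              check.names = FALSE),
                   file.path(dir, "sri_mask.csv"), row.names = FALSE)
  igraph::write_graph(as_igraph(assoc), file.path(dir, "sri.graphml"),
                      format = "graphml")
  invisible(dir)
}

## p-value with its "< 2/n" label, for JSON reports
.p_entry <- function(p) {
  lab <- attr(p, "label")
  list(p = as.numeric(p), label = if (is.null(lab)) format(p) else lab)
}

#' Run the full sociality analysis pipeline
#'
#' Sequences the whole workflow over one dataset: inclusion filter, SRI
#' association matrix, demographic and geographic masking (kernel home-range
#' volume-of-intersection overlap), dyad table + VIF diagnostics, the
#' zero-inflated binomial dyadic GLMM, Louvain community detection, the four
#' community-attribute permutation tests, and the closest-associate homophily
#' test. Every stochastic stage is seeded deterministically from `seed`.
#'
#' @param sightings Sighting table (see [read_sightings()]).
#' @param attributes Attribute table (`id`, `sponger`, optional
#'   `haplotype_observed`/`haplotype`).
#' @param relatedness Symmetric relatedness matrix or NULL.
#' @param mode Inclusion filter mode (default `"in_association"`).
#' @param min_sightings Inclusion threshold (default 10).
#' @param overlap_threshold Geographic-mask cut (default 0.25).
#' @param bandwidth Kernel bandwidth for home ranges (`"reference"` or
#'   metres).
#' @param spec [zib_spec()] for the dyadic model (NULL skips the model, for
#'   fast partial runs).
#' @param n_perm Permutations per community test (default 10000).
#' @param n_restarts Louvain restarts.
#' @param seed Master seed.
#' @param out_dir Optional directory: results are written as CSV/GraphML/JSON.
#' @return List with `individuals`, `assoc`, `overlap`, `dyads`, `vif`,
#'   `fit`, `partition`, `perm` (4 tests), `closest`, `homophily`, `seed`.
#' @export
run_pipeline <- function(sightings, attributes, relatedness = NULL,
                         mode = "in_association", min_sightings = 10,
                         overlap_threshold = 0.25, bandwidth = "reference",
                         spec = zib_spec(), n_perm = 10000, n_restarts = 100,
                         seed = 1L, out_dir = NULL) {
  keep <- filter_individuals(sightings, mode = mode,
                             min_sightings = min_sightings)
  if (length(keep) < 4) stop("fewer than 4 individuals pass the filter",
                             call. = FALSE)
  assoc <- compute_sri(sightings, keep)
  assoc <- demographic_mask(assoc, sightings)
  overlap <- overlap_matrix(sightings, keep, bandwidth = bandwidth)
  assoc <- geographic_mask(assoc, overlap, threshold = overlap_threshold)

  dyads <- build_dyad_table(assoc, attributes, relatedness,
                            sightings = sightings)
  vif <- vif_check(dyads)
  fit <- if (!is.null(spec)) fit_zib_glmm(dyads, spec, seed = seed) else NULL

  partition <- detect_communities(assoc, seed = seed + 100L,
                                  n_restarts = n_restarts)

  sub <- sightings[sightings$individual_id %in% keep, ]
  mean_depth <- tapply(sub$depth, sub$individual_id, mean)[keep]
  at <- attributes[match(keep, attributes$id), ]
  hap_col <- if ("haplotype_observed" %in% names(at)) "haplotype_observed"
             else "haplotype"
  haps <- stats::setNames(as.character(at[[hap_col]]), keep)
  sponge <- stats::setNames(at$sponger, keep)

  perm <- list(
    relatedness = if (!is.null(relatedness))
      perm_relatedness(relatedness, partition, n_perm, seed = seed + 201L)
      else NULL,
    haplotype = perm_haplotype(haps, partition, n_perm, seed = seed + 202L),
    foraging = perm_foraging(sponge, partition, n_perm, seed = seed + 203L),
    depth_sd = perm_depth_sd(mean_depth, partition, n_perm, seed = seed + 204L)
  )

  closest <- closest_associates(assoc, attributes)
  homophily <- homophily_binomial_test(closest)

  res <- list(individuals = keep, assoc = assoc, overlap = overlap,
              dyads = dyads, vif = vif, fit = fit, partition = partition,
              perm = perm, closest = closest, homophily = homophily,
              seed = seed)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline results to disk
#'
#' @param res Result bundle from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_association(res$assoc, dir)
  utils::write.csv(res$dyads, file.path(dir, "dyads.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = names(res$partition$labels),
                              community = unname(res$partition$labels)),
                   file.path(dir, "communities.csv"), row.names = FALSE)
  utils::write.csv(res$closest, file.path(dir, "closest_associates.csv"),
                   row.names = FALSE)
  json <- list(
    seed = res$seed,
    n_individuals = length(res$individuals),
    vif = as.list(res$vif),
    modularity = res$partition$modularity,
    n_communities = res$partition$n_communities,
    meaningful = res$partition$meaningful,
    permutation = lapply(res$perm, function(pr) {
      if (is.null(pr)) return(NULL)
      list(statistic = pr$statistic, n_perm = pr$n_perm, seed = pr$seed,
           observed = as.list(pr$observed),
           p = lapply(pr$p, .p_entry))
    }),
    homophily = res$homophily
  )
  if (!is.null(res$fit)) {
    json$model <- list(
      n_dyads = res$fit$n_dyads, n_dropped = res$fit$n_dropped,
      odds_ratios = res$fit$odds_ratios,
      bayes_R2 = as.list(res$fit$bayes_R2),
      zero_inflation = as.list(res$fit$zero_inflation),
      max_rhat = max(res$fit$summary$rhat),
      min_ess = min(res$fit$summary$ess))
    utils::write.csv(res$fit$summary, file.path(dir, "model_summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
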