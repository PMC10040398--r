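#' Build the per-dyad modelling table
#'
#' One row per *unmasked* dyad of the association matrix, carrying the
#' response counts (`y` = surveys together, `n` = surveys in which either was
#' observed) and the four dyadic covariates: biparental relatedness `r` (NA
#' when either female lacks genetic data), haplotype identity `h` (1 same / 0
#' different, NA without genotypes), foraging identity `f` (factor `MIX` /
#' `NN` / `SS` with `MIX` the reference level), and absolute difference in
#' mean sighting depth `d` (metres).
#'
#' @param assoc An `assoc_matrix` (masks already applied).
#' @param attributes Data frame with `id`, `sponger`, and either `mean_depth`
#'   or haplotype columns (`haplotype_observed` preferred, else `haplotype`).
#' @param relatedness Symmetric relatedness matrix (dimnames = ids); NA
#'   rows/columns mark non-genotyped individuals.
#' @param sightings Optional sighting table; when given, `mean_depth` is
#'   recomputed as the mean depth over each female's sightings (the field
#'   definition) instead of taken from `attributes`.
#' @return Data frame with columns `i`, `j`, `y`, `n`, `r`, `h`, `f`, `d`.
#' @export
build_dyad_table <- function(assoc, attributes, relatedness = NULL,
                             sightings = NULL) {
  ids <- assoc$individuals
  if (!all(ids %in% attributes$id))
    stop("input error: individuals missing from attribute table: ",
         paste(setdiff(ids, attributes$id), collapse = ", "), call. = FALSE)
  at <- attributes[match(ids, attributes$id), ]
  hap_col <- if ("haplotype_observed" %in% names(at)) "haplotype_observed"
             else "haplotype"
  hap <- as.character(at[[hap_col]])
  sponger <- at$sponger
  if (!is.null(sightings)) {
    sub <- sightings[sightings$individual_id %in% ids, ]
    md <- tapply(sub$depth, sub$individual_id, mean)
    depth <- as.numeric(md[ids])
  } else depth <- at$mean_depth

  ut <- which(upper.tri(assoc$sri) & assoc$mask == "value", arr.ind = TRUE)
  i <- ids[ut[, 1]]; j <- ids[ut[, 2]]
  r <- if (is.null(relatedness)) rep(NA_real_, nrow(ut))
       else relatedness[cbind(match(i, rownames(relatedness)),
                              match(j, colnames(relatedness)))]
  h_i <- hap[ut[, 1]]; h_j <- hap[ut[, 2]]
  h <- ifelse(is.na(h_i) | is.na(h_j), NA_real_, as.numeric(h_i == h_j))
  f <- ifelse(sponger[ut[, 1]] & sponger[ut[, 2]], "SS",
              ifelse(!sponger[ut[, 1]] & !sponger[ut[, 2]], "NN", "MIX"))
  d <- abs(depth[ut[, 1]] - depth[ut[, 2]])
  out <- data.frame(
    i = i, j = j,
    y = assoc$x[ut], n = assoc$n_either[ut],
    r = as.numeric(r), h = h,
    f = factor(f, levels = c("MIX", "NN", "SS")),
    d = d,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Variance inflation factors for the dyadic covariates
#'
#' Classical VIF: each covariate (foraging expanded to its two dummies) is
#' regressed on the others; VIF = 1 / (1 - R^2). Computed on complete cases.
#' A singular regression yields `Inf`.
#'
#' @param dyads Data frame from [build_dyad_table()].
#' @return Named numeric vector of VIFs.
#' @export
vif_check <- function(dyads) {
  cc <- stats::complete.cases(dyads[, c("r", "h", "f", "d")])
  X <- data.frame(r = dyads$r[cc], h = dyads$h[cc],
                  fNN = as.numeric(dyads$f[cc] == "NN"),
                  fSS = as.numeric(dyads$f[cc] == "SS"),
                  d = dyads$d[cc])
  varying <- vapply(X, function(v) stats::var(v) > 0, TRUE)
  vapply(names(X), function(k) {
    if (!varying[[k]]) return(NA_real_)  # constant covariate: VIF undefined
    fit <- stats::lm(stats::reformulate(names(X)[varying & names(X) != k],
                                        response = k), data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}
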