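#' Closest associate of each individual
#'
#' For every individual, the partner(s) with the maximal SRI among unmasked
#' dyads. Ties retain all tied partners; a tied individual later contributes
#' fractionally to same-strategy proportions. Individuals whose entire row is
#' masked (or who have no unmasked partner) are excluded and reported.
#'
#' @param assoc An `assoc_matrix`.
#' @param attributes Data frame with `id` and `sponger` (used for the
#'   same-strategy indicator).
#' @return Data frame: `id`, `sponger`, `closest` (comma-separated ids),
#'   `n_tied`, `top_sri`, `same_strategy` (fraction of tied closest
#'   associates sharing the focal's class).
#' @export
closest_associates <- function(assoc, attributes) {
  ids <- assoc$individuals
  sp <- stats::setNames(attributes$sponger[match(ids, attributes$id)], ids)
  if (anyNA(sp)) stop("sponger flag missing for some individuals", call. = FALSE)
  rows <- lapply(ids, function(a) {
    v <- assoc$sri[a, ]
    v[assoc$mask[a, ] != "value"] <- NA
    v <- v[names(v) != a]
    if (all(is.na(v))) return(NULL)
    top <- max(v, na.rm = TRUE)
    tied <- names(v)[!is.na(v) & v == top]
    data.frame(id = a, sponger = sp[[a]],
               closest = paste(tied, collapse = ","),
               n_tied = length(tied), top_sri = top,
               same_strategy = mean(sp[tied] == sp[[a]]),
               stringsAsFactors = FALSE)
  })
  dropped <- ids[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    message(length(dropped), " individuals with no unmasked partner excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Closest-associate foraging homophily test
#'
#' For each strategy class, an exact one-sided (upper) binomial test of
#' whether individuals have a same-strategy closest associate more often than
#' expected from class availability: for a focal of class c, the null
#' probability is the proportion of class-c animals among her potential
#' partners (the focal herself excluded). The two tests (spongers,
#' non-spongers) are Bonferroni-corrected. Fractional tie contributions are
#' rounded to the nearest integer count for the exact tail.
#'
#' @param closest Data frame from [closest_associates()].
#' @param n_spongers,n_nonspongers Class counts in the analysed population
#'   (defaults: counted from `closest`, appropriate when no individual was
#'   excluded).
#' @return Data frame, one row per class: `class`, `n`, `prop_same`, `p0`
#'   (null probability), `k` (integer same count used), `p_raw`,
#'   `p_bonferroni`.
#' @export
homophily_binomial_test <- function(closest,
                                    n_spongers = sum(closest$sponger),
                                    n_nonspongers = sum(!closest$sponger)) {
  N <- n_spongers + n_nonspongers
  if (n_spongers == 0 || n_nonspongers == 0) {
    warning("one foraging class is empty; homophily test skipped for it")
  }
  one_class <- function(flag, n_class) {
    sub <- closest[closest$sponger == flag, ]
    if (!nrow(sub) || n_class == 0) return(NULL)
    p0 <- (n_class - 1) / (N - 1)  # focal excluded from her own candidate pool
    k_frac <- sum(sub$same_strategy)
    k <- round(k_frac)
    n <- nrow(sub)
    p_raw <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    data.frame(class = if (flag) "sponger" else "non-sponger",
               n = n, prop_same = k_frac / n, p0 = p0, k = k,
               p_raw = p_raw, p_bonferroni = min(1, 2 * p_raw),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(TRUE, n_spongers), one_class(FALSE, n_nonspongers))
  rownames(out) <- NULL
  out
}
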