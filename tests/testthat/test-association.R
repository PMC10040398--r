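# helper to build a sighting table from a list of surveys, each a list of
# groups, each a character vector of individuals
sightings_from_groups <- function(surveys, start = as.Date("2010-01-01")) {
  rows <- list()
  for (s in seq_along(surveys)) {
    for (g in seq_along(surveys[[s]])) {
      ind <- surveys[[s]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        survey_id = sprintf("S%03d", s), date = start + s,
        group_id = sprintf("S%03d_G%02d", s, g), individual_id = ind,
        depth = 5, x = 0, y = 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("inclusion filters follow their definitions", {
  # 'a' solitary in 10 surveys; 'b','c' together in 10; 'd' social in 9 only
  surveys <- lapply(1:10, function(s) {
    gs <- list("a", c("b", "c"))
    if (s <= 9) gs <- c(gs, list(c("d", "e")))
    gs
  })
  tab <- sightings_from_groups(surveys)
  expect_setequal(filter_individuals(tab, "in_association", 10), c("b", "c"))
  expect_true("a" %in% filter_individuals(tab, "any", 10))
  expect_false("d" %in% filter_individuals(tab, "in_association", 10))
  expect_false("d" %in% filter_individuals(tab, "any", 10))   # 9 surveys
  expect_error(filter_individuals(tab[0, ], "any"), "empty")
})

test_that("SRI matches hand-computed and degenerate cases", {
  # a in 10 surveys, b in 8, together in 3 -> union 15, SRI 0.2
  surveys <- c(
    lapply(1:3, function(s) list(c("a", "b"), "z")),     # together
    lapply(4:10, function(s) list("a", "z")),            # a alone
    lapply(11:15, function(s) list("b", "z"))            # b alone
  )
  tab <- sightings_from_groups(surveys)
  assoc <- compute_sri(tab, c("a", "b", "z"))
  expect_equal(assoc$sri["a", "b"], 3 / 15)
  expect_equal(assoc$x["a", "b"], 3)
  expect_equal(assoc$n_either["a", "b"], 15)

  # always together -> 1; never co-sighted -> 0
  tab2 <- sightings_from_groups(lapply(1:12, function(s)
    list(c("p", "q"), if (s %% 2) "r" else "s")))
  a2 <- compute_sri(tab2, c("p", "q", "r", "s"))
  expect_equal(a2$sri["p", "q"], 1)
  expect_equal(a2$sri["r", "s"], 0)
  # r and s never share a survey either -> n_either = 12, SRI 0
  expect_equal(a2$n_either["r", "s"], 12)
})

test_that("SRI equals the brute-force recount on random sighting tables", {
  for (seed in 1:6) {
    tab <- random_sightings(n_ind = sample(4:12, 1), n_surveys = 20,
                            seed = 100 + seed)
    ids <- sort(unique(tab$individual_id))
    assoc <- compute_sri(tab, ids)
    oracle <- brute_sri(tab, ids)
    ut <- upper.tri(oracle$sri)
    expect_equal(assoc$sri[ids, ids][ut], oracle$sri[ut], tolerance = 1e-12)
    expect_equal(unname(assoc$x[ids, ids][ut]), unname(oracle$x[ut]))
    expect_equal(unname(assoc$n_either[ids, ids][ut]),
                 unname(oracle$n_either[ut]))
  }
})

test_that("removing a survey never increases n_either", {
  tab <- random_sightings(10, 25, seed = 42)
  ids <- sort(unique(tab$individual_id))
  full <- compute_sri(tab, ids)$n_either
  for (s in unique(tab$survey_id)[1:5]) {
    red <- compute_sri(tab[tab$survey_id != s, ], ids)$n_either
    expect_true(all(red <= full))
  }
})

test_that("demographic mask uses inclusive first-last sighting overlap", {
  # surveys are daily: a spans days 1-10, b days 11-20, c days 20-29 (c and b
  # share day 20, in different groups); x spans everything
  surveys <- lapply(1:29, function(s) {
    gs <- list("x")
    if (s <= 10) gs <- c(gs, list("a"))
    if (s >= 11 && s <= 20) gs <- c(gs, list("b"))
    if (s >= 20) gs <- c(gs, list("c"))
    gs
  })
  tab <- sightings_from_groups(surveys)
  assoc <- demographic_mask(compute_sri(tab, c("a", "b", "c", "x")), tab)
  expect_equal(assoc$mask["a", "b"], "demographic")   # disjoint intervals
  expect_equal(assoc$mask["b", "c"], "value")         # share day 20
  expect_true(is.na(assoc$sri["a", "b"]))
  # all-spanning individuals are never masked
  expect_equal(assoc$mask["a", "x"], "value")
})

test_that("geographic mask is strict at the 25% threshold", {
  tab <- sightings_from_groups(lapply(1:10, function(s) list(c("a", "b", "c"))))
  assoc <- compute_sri(tab, c("a", "b", "c"))
  ov <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ov["a", "b"] <- ov["b", "a"] <- 0.25   # exactly at threshold: kept
  ov["a", "c"] <- ov["c", "a"] <- 0.10   # below: masked
  ov["b", "c"] <- ov["c", "b"] <- NA     # missing: masked, logged
  expect_message(m <- geographic_mask(assoc, ov), "lack an overlap")
  expect_equal(m$mask["a", "b"], "value")
  expect_equal(m$mask["a", "c"], "geographic")
  expect_equal(m$mask["b", "c"], "geographic")

  # mask is symmetric and idempotent under recomputation
  expect_identical(m$mask, t(m$mask))
  m2 <- geographic_mask(m, ov)
  expect_identical(m$mask, m2$mask)
  expect_equal(m$sri, m2$sri)
})
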