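test_that("intensity scoring applies the threshold and ambiguity band", {
  rec <- data.frame(marker = rep("M1", 3), clone = c("H1", "H2", "H3"),
                    x = 0, y = c(0.55, 0.30, 0.10))
  m <- score_intensities(rec, threshold = 0.3, ambiguous_halfwidth = 0.05)
  expect_equal(as.vector(m[, "M1"]), c(1L, 2L, 0L))

  # zero halfwidth: no ambiguous calls from in-band values
  m0 <- score_intensities(rec, threshold = 0.3, ambiguous_halfwidth = 0)
  expect_true(all(m0 %in% c(0L, 1L)))

  # per-marker override switches axis and threshold
  rec2 <- data.frame(marker = c("M1", "M2"), clone = "H1",
                     x = c(0.25, 0.25), y = c(0.1, 0.1))
  ov <- data.frame(marker = "M2", axis = "x", threshold = 0.20)
  m2 <- score_intensities(rec2, overrides = ov, ambiguous_halfwidth = 0.01)
  expect_equal(as.vector(m2["H1", c("M1", "M2")]), c(0L, 1L))

  # missing (marker, clone) pair scored ambiguous with a warning
  rec3 <- data.frame(marker = c("M1", "M1", "M2"),
                     clone = c("H1", "H2", "H1"),
                     x = 0, y = c(0.5, 0.5, 0.5))
  expect_warning(m3 <- score_intensities(rec3), class = "rhmap_warning")
  expect_equal(as.vector(m3["H2", "M2"]), 2L)
})

test_that("retention frequency excludes ambiguous calls", {
  calls <- rh_call_matrix(matrix(
    c(rep(1L, 12), rep(0L, 36),
      rep(1L, 12), rep(0L, 30), rep(2L, 6)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("H1", "H2"), sprintf("M%02d", 1:48))))
  st <- retention_frequency(calls)
  expect_equal(st$retention[st$clone == "H1"], 0.25)
  expect_equal(st$retention[st$clone == "H2"], 12 / 42)

  # invariant to marker permutation
  perm <- sample(ncol(calls))
  expect_equal(retention_frequency(calls[, perm])$retention, st$retention)

  all_amb <- rh_call_matrix(matrix(2L, 1, 3, dimnames = list("H1", c("A", "B", "C"))))
  expect_error(retention_frequency(all_amb), class = "rhmap_retention_error")
})

test_that("panel-wide retention matches the simulated rate", {
  cfg <- clean_config(n_chromosomes = 3, markers_per_chromosome = 15,
                      seed = 17)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  st <- retention_frequency(p$calls)
  se <- stats::sd(st$retention) / sqrt(nrow(st))
  expect_lt(abs(mean(st$retention) - 0.117), 3 * se)
})

test_that("clone selection keeps the band and rescues sole carriers", {
  calls <- rh_call_matrix(matrix(
    c(1L, 1L, 0L, 0L,
      0L, 1L, 1L, 0L,
      1L, 0L, 0L, 0L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("H1", "H2", "H3"), c("A", "B", "C", "D"))))
  st <- data.frame(clone = c("H1", "H2", "H3"),
                   retention = c(0.30, 0.30, 0.02))
  # H3 is below the band and carries no unique marker (A also in H1)
  expect_equal(select_clones(st, calls, 0.05, 0.40), c("H1", "H2"))
  # make H3 the sole carrier of D: rescued despite low retention
  calls2 <- calls; calls2["H3", "D"] <- 1L
  calls2 <- rh_call_matrix(unclass(calls2))
  expect_equal(select_clones(st, calls2, 0.05, 0.40), c("H1", "H2", "H3"))
  # all in band: everything kept, order preserved, deterministic subset
  st2 <- st; st2$retention <- c(0.2, 0.3, 0.25)
  expect_equal(select_clones(st2, calls, 0.05, 0.40), c("H1", "H2", "H3"))
  # no clone in band and no sole carrier anywhere: selection fails loudly
  shared <- rh_call_matrix(matrix(1L, 2, 2,
    dimnames = list(c("H1", "H2"), c("A", "B"))))
  st3 <- data.frame(clone = c("H1", "H2"), retention = c(0.3, 0.3))
  expect_error(select_clones(st3, shared, 0.9, 0.95),
               class = "rhmap_selection_error")
})

test_that("non-separating markers are flagged", {
  set.seed(5)
  good <- data.frame(marker = "G", clone = sprintf("H%02d", 1:40),
                     x = 0, y = c(runif(20, 0, 0.08), runif(20, 0.5, 0.7)))
  bad <- data.frame(marker = "B", clone = sprintf("H%02d", 1:40),
                    x = 0, y = runif(40, 0.1, 0.5))
  fl <- flag_nonseparating(rbind(good, bad))
  expect_false(fl$flagged[fl$marker == "G"])
  expect_true(fl$flagged[fl$marker == "B"])
})
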