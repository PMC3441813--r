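test_that("multipoint likelihood has its closed forms and symmetries", {
  # single marker, call 1, no error: log(r)
  m <- rh_call_matrix(matrix(1L, 1, 1, dimnames = list("H1", "A")))
  mod <- multipoint_model("A", numeric(0), r = 0.117)
  expect_equal(multipoint_loglik("A", m, mod), log(0.117))

  # reversal invariance on simulated data
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 6,
                      seed = 3, ambiguous_rate = 0.05)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  ord <- colnames(p$calls)
  fit <- fit_adjacent_thetas(ord, p$calls)
  ll <- multipoint_loglik(ord, p$calls, fit)
  rev_mod <- multipoint_model(rev(ord), rev(fit$thetas), fit$r)
  expect_equal(multipoint_loglik(rev(ord), p$calls, rev_mod), ll,
               tolerance = 1e-10)

  # ambiguous call equals the sum over its completions
  mm <- matrix(c(1L, 2L, 0L,
                 1L, 1L, 0L,
                 0L, 0L, 1L), nrow = 3, byrow = TRUE,
               dimnames = list(c("H1", "H2", "H3"), c("A", "B", "C")))
  mod3 <- multipoint_model(c("A", "B", "C"), c(0.3, 0.2), 0.25)
  ll_all <- multipoint_loglik(c("A", "B", "C"), rh_call_matrix(mm), mod3)
  others <- multipoint_loglik(c("A", "B", "C"),
                              rh_call_matrix(mm[2:3, ]), mod3)
  comp <- vapply(c(0L, 1L), function(v) {
    m1 <- mm[1, , drop = FALSE]; m1[1, 2] <- v
    multipoint_loglik(c("A", "B", "C"), rh_call_matrix(m1), mod3)
  }, numeric(1))
  expect_equal(ll_all - others, log(sum(exp(comp))), tolerance = 1e-10)
})

test_that("fitted adjacent thetas recover pairwise and duplicate structure", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 2,
                      seed = 3)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  est <- estimate_two_point(p$calls[, 1], p$calls[, 2])
  fit <- fit_adjacent_thetas(colnames(p$calls), p$calls)
  expect_lt(abs(fit$thetas - est$theta), 1e-3)

  # duplicated marker: fitted theta exactly zero
  m <- unclass(p$calls)
  m <- cbind(m, DUP = as.vector(m[, 1]))
  fit2 <- fit_adjacent_thetas(c(colnames(p$calls)[1], "DUP",
                                colnames(p$calls)[2]), rh_call_matrix(m))
  expect_equal(fit2$thetas[1], 0)
})

test_that("search_order finds the exhaustive optimum on small groups", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 6,
                      seed = 37)
  ds <- simulate_rh_dataset(cfg)
  mk <- sort(colnames(ds$calls))
  mp <- search_order(mk, ds$calls, seed = 1, n_restarts = 3)
  best <- exhaustive_best_loglik(mk, ds$calls, r = mp$r)
  expect_equal(mp$loglik, best, tolerance = 1e-4)
  truth <- unname(ds$truth_order[[1]])
  expect_true(identical(mp$markers, truth) ||
                identical(mp$markers, rev(truth)))
  # canonical orientation: lexicographically smaller end first
  expect_true(mp$markers[1] < mp$markers[length(mp$markers)])
  # coordinates start at 0, non-decreasing, total = last
  expect_equal(mp$cr[1], 0)
  expect_true(all(diff(mp$cr) >= 0))
  expect_equal(mp$length_cr, mp$cr[length(mp$cr)])
})

test_that("two-marker groups reduce to the two-point distance", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 2,
                      seed = 41)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  mp <- search_order(colnames(p$calls), p$calls, seed = 1, n_restarts = 1)
  est <- estimate_two_point(p$calls[, 1], p$calls[, 2])
  expect_equal(mp$length_cr, round(theta_to_cr(est$theta), 1),
               tolerance = 0.2)
})

test_that("a duplicated marker never changes the group length", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 5,
                      seed = 43)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  ord <- colnames(p$calls)
  mp <- map_from_order("G", ord, p$calls, r = 0.117)
  m2 <- cbind(unclass(p$calls), ZDUP = as.vector(p$calls[, 3]))
  ord2 <- append(ord, "ZDUP", after = 3)
  mp2 <- map_from_order("G", ord2, rh_call_matrix(m2), r = 0.117)
  expect_equal(mp2$thetas[3], 0)
  expect_equal(mp2$length_cr, mp$length_cr, tolerance = 0.11)
})

test_that("co-localized markers merge into shared positions", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 4,
                      seed = 47)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  mp <- search_order(colnames(p$calls), p$calls, seed = 1, n_restarts = 2)
  mp <- colocalize(mp, p$calls)
  expect_equal(nrow(mp$positions), 4)  # all vectors distinct here

  # six identical vectors collapse to one position of six
  base <- as.vector(p$calls[, 1])
  m6 <- matrix(rep(base, 6), ncol = 6,
               dimnames = list(rownames(p$calls), paste0("Q", 1:6)))
  mp6 <- search_order(colnames(m6), rh_call_matrix(m6), seed = 1,
                      n_restarts = 1)
  mp6 <- colocalize(mp6, rh_call_matrix(m6))
  expect_equal(nrow(mp6$positions), 1)
  expect_equal(mp6$positions$n_markers, 6L)
  expect_equal(mp6$length_cr, 0)
})
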