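test_that("simulated genomes respect positions, classes and determinism", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 5, seed = 11)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g), 5)
  expect_true(all(diff(g$pos_kb) > 0))
  expect_false(anyDuplicated(g$marker) > 0)

  cfg0 <- sim_config(n_chromosomes = 2, markers_per_chromosome = 10,
                     microsatellite_fraction = 0, seed = 2)
  expect_false(any(simulate_genome(cfg0)$class == "microsatellite"))

  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  ds1 <- simulate_rh_dataset(clean_config(seed = 5))
  ds2 <- simulate_rh_dataset(clean_config(seed = 5))
  expect_identical(serialize(ds1, NULL), serialize(ds2, NULL))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_chromosomes = 0), class = "rhmap_config_error")
  expect_error(sim_config(markers_per_chromosome = 0),
               class = "rhmap_config_error")
  expect_error(sim_config(retention_rate = 1.2), class = "rhmap_config_error")
  expect_error(sim_config(kb_per_cr = 0), class = "rhmap_config_error")
})

test_that("markers with negligible separation are always co-retained", {
  g <- structure(data.frame(marker = c("A", "B"), chrom = "chr1",
                            pos_kb = c(5000, 5000.001), class = "gene",
                            stringsAsFactors = FALSE),
                 class = c("rh_genome", "data.frame"))
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 2,
                    chromosome_length_kb = 10000, n_clones = 500,
                    false_positive_rate = 0, false_negative_rate = 0,
                    ambiguous_rate = 0, seed = 3)
  p <- simulate_panel(g, cfg)
  expect_equal(unname(p$truth_calls[, "A"]), unname(p$truth_calls[, "B"]))
})

test_that("breakage and retention converge to their closed forms", {
  # two markers one expected break apart: theta = 1 - exp(-1)
  d_kb <- 2750
  g <- structure(data.frame(marker = c("A", "B"), chrom = "chr1",
                            pos_kb = c(1000, 1000 + d_kb), class = "gene",
                            stringsAsFactors = FALSE),
                 class = c("rh_genome", "data.frame"))
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 2,
                    chromosome_length_kb = 6000, n_clones = 10000,
                    retention_rate = 0.117, kb_per_cr = 27.5,
                    false_positive_rate = 0, false_negative_rate = 0,
                    ambiguous_rate = 0, seed = 8)
  p <- simulate_panel(g, cfg)
  theta <- 1 - exp(-1)
  r <- 0.117
  p_disc <- 2 * r * theta * (1 - r)   # P(1,0) + P(0,1)
  emp <- mean(p$truth_calls[, "A"] != p$truth_calls[, "B"])
  se <- sqrt(p_disc * (1 - p_disc) / cfg$n_clones)
  expect_lt(abs(emp - p_disc), 3 * se)

  # presence fraction over 50,000 clone-marker cells
  cfg2 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 100,
                     chromosome_length_kb = 50000, n_clones = 500,
                     retention_rate = 0.117, false_positive_rate = 0,
                     false_negative_rate = 0, ambiguous_rate = 0, seed = 9)
  p2 <- simulate_panel(simulate_genome(cfg2), cfg2)
  emp2 <- mean(p2$truth_calls == 1L)
  # markers on one chromosome are correlated; use a generous SE bound from
  # the per-clone retention variance
  per_clone <- rowMeans(p2$truth_calls == 1L)
  se2 <- stats::sd(per_clone) / sqrt(cfg2$n_clones)
  expect_lt(abs(emp2 - 0.117), 3 * se2)
})

test_that("retained fragments are disjoint and inside chromosome bounds", {
  cfg <- clean_config(seed = 13, n_chromosomes = 2)
  p <- simulate_panel(simulate_genome(cfg), cfg)
  fr <- p$fragments
  expect_true(all(fr$start_kb >= 0))
  expect_true(all(fr$end_kb <= max(cfg$chromosome_length_kb)))
  for (key in unique(paste(fr$clone, fr$chrom))) {
    sub <- fr[paste(fr$clone, fr$chrom) == key, ]
    sub <- sub[order(sub$start_kb), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start_kb[-1] >= sub$end_kb[-nrow(sub)]))
  }
})

test_that("genetic map positions follow the kb-to-cM scale", {
  g <- structure(data.frame(marker = c("MS1", "MS2"), chrom = "chr1",
                            pos_kb = c(840, 1680), class = "microsatellite",
                            stringsAsFactors = FALSE),
                 class = c("rh_genome", "data.frame"))
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 2,
                    kb_per_cm = 840, map_jitter_cm = 0, seed = 4)
  gm <- simulate_genetic_map(g, cfg)
  expect_equal(gm$cm[gm$marker == "MS1"], 1.0)
  expect_equal(gm$cm[gm$marker == "MS2"], 2.0)
  # no jitter: cM order is kb order
  expect_identical(gm$marker[order(gm$cm)], c("MS1", "MS2"))
})

test_that("splitting a chromosome yields two linkage-group labels", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 12,
                    microsatellite_fraction = 0.6, split_chromosome = 1,
                    seed = 21)
  g <- simulate_genome(cfg)
  gm <- simulate_genetic_map(g, cfg)
  ms1 <- g$marker[g$chrom == "chr1" & g$class == "microsatellite"]
  lgs <- unique(gm$lg[gm$marker %in% ms1])
  expect_length(lgs, 2)
  expect_warning(
    simulate_genetic_map(
      simulate_genome(sim_config(microsatellite_fraction = 0, seed = 1)),
      sim_config(microsatellite_fraction = 0, seed = 1)),
    class = "rhmap_warning")
})

test_that("model species rearrangements produce the expected truth", {
  base <- function(specs) sim_config(
    n_chromosomes = 3, markers_per_chromosome = 10, seed = 31,
    species_specs = specs)
  cfg <- base(list(species_spec("plain")))
  g <- simulate_genome(cfg)
  sp <- simulate_model_species(g, cfg)
  expect_equal(nrow(sp$truth), 0)
  orders <- split(g$marker, g$chrom)
  dec <- synteny_decompose(orders, sp$anchors, "plain")
  expect_true(all(vapply(dec, function(x) nrow(x$segments), 0L) == 1L))

  # fusion: two donor chromosomes end up on one model chromosome
  cfg_f <- base(list(species_spec("fused", fusions = 1)))
  g_f <- simulate_genome(cfg_f)
  sp_f <- simulate_model_species(g_f, cfg_f)
  dec_f <- synteny_decompose(split(g_f$marker, g_f$chrom), sp_f$anchors, "fused")
  ox <- oxford_grid(dec_f)
  expect_true(any(colSums(ox$cs_counts > 0) == 2))

  # inversion: CS count unchanged, CSO count goes up
  cfg_i <- base(list(species_spec("inv", inversions = 1)))
  g_i <- simulate_genome(cfg_i)
  sp_i <- simulate_model_species(g_i, cfg_i)
  dec_i <- synteny_decompose(split(g_i$marker, g_i$chrom), sp_i$anchors, "inv")
  expect_true(all(vapply(dec_i, function(x) nrow(x$segments), 0L) == 1L))
  s <- summarize_cs_cso(list(inv = dec_i))
  expect_equal(sum(s$n_cso), 3 + 1)  # one extra ordered run on one chromosome

  # infeasible rearrangement counts error out
  cfg_bad <- sim_config(n_chromosomes = 1, markers_per_chromosome = 4,
                        seed = 1, species_specs = list(
                          species_spec("bad", inversions = 5)))
  g_bad <- simulate_genome(cfg_bad)
  expect_error(simulate_model_species(g_bad, cfg_bad),
               class = "rhmap_config_error")
})
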