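test_that("hit filtering applies score/length windows and best-hit choice", {
  h <- data.frame(
    marker  = c("C1",   "C1",   "C2",   "C3",   "C4",   "C5"),
    species = "stickleback",
    chrom   = c("GAC01", "GAC02", "GAC03", "GAC04", "chrUn", "GAC05"),
    start   = c(100, 900, 10, 40, 0, 7),
    end     = c(250, 1100, 160, 340, 200, 207),
    score   = c(300, 280, 249, 400, 260, 300),
    length  = c(150, 200, 150, 300, 200, 200))
  # C2 fails the score floor (249 < 250); C3 passes (length 300 allowed);
  # C1 keeps its best hit (300 > 280); C4 survives but sits on chrUn
  an <- filter_hits(h, min_score = 250, min_len = 80, max_len = 300)
  expect_equal(sort(unique(an$marker)), c("C1", "C3", "C4", "C5"))
  expect_equal(an$chrom[an$marker == "C1"], "GAC01")
  expect_true(an$unknown_chrom[an$marker == "C4"])
  expect_equal(an$pos[an$marker == "C1"], 175)

  # boundary: score exactly at the floor is kept; length above window is not
  h2 <- data.frame(marker = c("A", "B"), species = "s", chrom = "c1",
                   start = 0, end = 100, score = c(250, 500),
                   length = c(100, 301))
  an2 <- filter_hits(h2)
  expect_equal(an2$marker, "A")
})

test_that("the cross-species partition counts subsets and percentages", {
  # 2475 markers with at least one hit; 1920 hit stickleback
  mk <- sprintf("M%04d", 1:2475)
  rows <- data.frame(marker = mk[1:1920], species = "stickleback")
  rows <- rbind(rows, data.frame(marker = mk[1921:2475], species = "medaka"))
  vp <- venn_partition(rows)
  expect_equal(vp$n_markers, 2475)
  st <- vp$totals[vp$totals$species == "stickleback", ]
  expect_equal(st$count, 1920)
  expect_equal(st$percent, 77.6)
  # subset counts always sum to the grand total
  expect_equal(sum(vp$subsets$count), vp$n_markers)
})

test_that("conserved segments and singletons follow the run definition", {
  an <- data.frame(marker = paste0("m", 1:5), species = "s",
                   chrom = c("A", "A", "B", "A", "A"),
                   pos = c(10, 20, 5, 30, 40))
  cs <- detect_cs(paste0("m", 1:5), an, "s")
  expect_equal(nrow(cs$segments), 2)
  expect_true(all(cs$segments$model_chrom == "A"))
  expect_equal(cs$singletons$marker, "m3")

  # non-anchored markers do not break runs
  cs2 <- detect_cs(c("m1", "zz", "m2"), an, "s")
  expect_equal(nrow(cs2$segments), 1)
  expect_equal(cs2$segments$n_markers, 2L)

  # a single anchored marker is a singleton
  cs3 <- detect_cs("m1", an, "s")
  expect_equal(nrow(cs3$segments), 0)
  expect_equal(cs3$singletons$marker, "m1")
})

test_that("ordered-run decomposition is greedy, directional and tie-safe", {
  r1 <- detect_cso(paste0("m", 1:3), c(10, 20, 30))
  expect_equal(unique(r1$run), 1L)
  expect_equal(unique(r1$direction), "+")

  r2 <- detect_cso(paste0("m", 1:5), c(10, 20, 30, 25, 35))
  expect_equal(r2$run, c(1L, 1L, 1L, 2L, 2L))

  r3 <- detect_cso(paste0("m", 1:3), c(30, 20, 10))
  expect_equal(unique(r3$run), 1L)
  expect_equal(unique(r3$direction), "-")

  expect_error(detect_cso(c("a", "b"), c(5, 5)), class = "rhmap_tie_error")
})

test_that("oxford grids conserve anchor counts; reversal flips direction", {
  cfg <- sim_config(n_chromosomes = 3, markers_per_chromosome = 10, seed = 67,
                    species_specs = list(
                      species_spec("spA", translocations = 1),
                      species_spec("spB", inversions = 2)))
  g <- simulate_genome(cfg)
  sp <- simulate_model_species(g, cfg)
  orders <- split(g$marker, g$chrom)
  for (s in c("spA", "spB")) {
    dec <- synteny_decompose(orders, sp$anchors, s)
    ox <- oxford_grid(dec)
    expect_equal(ox$n_anchors, sum(sp$anchors$species == s))
    expect_equal(sum(ox$row_totals), ox$n_anchors)
    expect_equal(sum(ox$col_totals), ox$n_anchors)
    # every anchored marker lies in exactly one CS or the singleton list
    for (chr in names(dec)) {
      a <- dec[[chr]]$assignment
      expect_equal(sum(!is.na(a$segment)) + nrow(dec[[chr]]$singletons),
                   nrow(a))
    }
  }
  # a translocated donor chromosome shows two nonzero CS cells
  decA <- synteny_decompose(orders, sp$anchors, "spA")
  oxA <- oxford_grid(decA)
  cut_chroms <- unique(sp$truth$chrom[sp$truth$species == "spA"])
  for (chr in cut_chroms)
    expect_equal(sum(oxA$cs_counts[chr, ] > 0), 2)

  # reversing the map order keeps CS counts, flips CSO directions
  dec_f <- synteny_decompose(orders, sp$anchors, "spB")
  dec_r <- synteny_decompose(lapply(orders, rev), sp$anchors, "spB")
  for (chr in names(orders)) {
    expect_equal(nrow(dec_r[[chr]]$segments), nrow(dec_f[[chr]]$segments))
    dirs_f <- unlist(lapply(dec_f[[chr]]$cso, function(x) x$direction))
    dirs_r <- unlist(lapply(dec_r[[chr]]$cso, function(x) x$direction))
    expect_equal(sum(dirs_f == "+", na.rm = TRUE),
                 sum(dirs_r == "-", na.rm = TRUE))
  }
})

test_that("summary table reports CS/CSO per chromosome with 'un' gaps", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 8, seed = 71,
                    species_specs = list(species_spec("plain")))
  g <- simulate_genome(cfg)
  sp <- simulate_model_species(g, cfg)
  orders <- split(g$marker, g$chrom)
  dec <- synteny_decompose(orders, sp$anchors, "plain")
  s <- summarize_cs_cso(list(plain = dec))
  expect_true(all(s$n_cs == 1))
  expect_true(all(s$n_cso == 1))

  # drop one chromosome's anchors entirely: rendered "un"
  an2 <- sp$anchors[!sp$anchors$marker %in% orders$chr2, ]
  dec2 <- synteny_decompose(orders, an2, "plain")
  f <- format_cs_cso(summarize_cs_cso(list(plain = dec2)))
  expect_equal(f$plain_CS[f$chromosome == "chr2"], "un")
})
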