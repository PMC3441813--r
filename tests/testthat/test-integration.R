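fake_map <- function(group, markers, cr = NULL) {
  structure(list(group = group, markers = markers,
                 cr = cr %||% seq(0, by = 30, length.out = length(markers)),
                 length_cr = max(cr %||% (30 * (length(markers) - 1)))),
            class = "rh_map")
}

test_that("groups are anchored to the majority linkage group", {
  gmap <- data.frame(
    lg = c(rep("LG7", 3), rep("LG2", 1), rep("LG8", 2), rep("LG24", 2)),
    marker = c("MS1", "MS2", "MS3", "MS4", "GM027", "UNH129", "GM104", "GM173"),
    cm = c(0, 5, 10, 3, 0, 4, 1, 6))
  maps <- list(
    fake_map("RH1", c("MS1", "X1", "MS2", "MS3")),        # 3 anchors on LG7
    fake_map("RH2", c("Y1", "Y2")),                        # orphan
    fake_map("RH3", c("GM027", "UNH129", "GM104", "GM173")))  # 2 + 2 conflict
  an <- anchor_groups(maps, gmap)
  expect_equal(an$assignments$lg[an$assignments$group == "RH1"], "LG7")
  expect_equal(an$orphans, "RH2")
  cf <- an$conflicts[an$conflicts$group == "RH3", ]
  expect_setequal(cf$lg, c("LG8", "LG24"))
  expect_true(all(cf$n_anchors == 2))
  # assignments + orphans partition the groups
  expect_setequal(c(an$assignments$group, an$orphans),
                  c("RH1", "RH2", "RH3"))

  mg <- detect_lg_merges(an)
  expect_equal(mg$merged, list(c("LG24", "LG8")))
  expect_equal(unname(mg$chromosome["LG8"]), "LG24-LG8")

  # no conflicts: no merges, chromosomes = LGs
  an2 <- anchor_groups(maps[1:2], gmap)
  mg2 <- detect_lg_merges(an2)
  expect_length(mg2$merged, 0)

  # chained merges are transitive
  an3 <- structure(list(
    assignments = data.frame(group = c("RH1", "RH2"), lg = c("A", "B"),
                             n_anchors = c(2L, 2L)),
    conflicts = data.frame(group = c("RH1", "RH1", "RH2", "RH2"),
                           lg = c("A", "B", "B", "C"),
                           n_anchors = c(2L, 2L, 2L, 2L)),
    orphans = character()), class = "rh_anchoring")
  mg3 <- detect_lg_merges(an3)
  expect_equal(mg3$merged, list(c("A", "B", "C")))
})

test_that("group orientation follows anchor rank correlation", {
  gmap <- data.frame(lg = "LG1",
                     marker = c("MS1", "MS2", "MS3", "MS4"),
                     cm = c(10, 30, 50, 70))
  fwd <- fake_map("RH1", c("MS1", "A", "MS2"), cr = c(0, 20, 40))
  rev_ <- fake_map("RH2", c("MS4", "B", "MS3"), cr = c(0, 20, 40))
  asm <- assemble_chromosome("LG1", list(fwd, rev_), gmap)
  ord <- asm$order
  expect_equal(ord$group, c("RH1", "RH2"))  # by mean anchor cM
  expect_false(ord$flip[ord$group == "RH1"])
  expect_true(ord$flip[ord$group == "RH2"])
  expect_true(all(ord$evidence == "anchor_rank_correlation"))
})

test_that("assembly recovers simulated group order and orientation", {
  cfg <- clean_config(n_chromosomes = 1, markers_per_chromosome = 18,
                      seed = 53, microsatellite_fraction = 0.5)
  ds <- simulate_rh_dataset(cfg)
  truth <- unname(ds$truth_order[[1]])
  # three RH groups = three consecutive slices of the chromosome, the middle
  # one deliberately reversed before mapping (orientation is unknown to the
  # assembler)
  slices <- list(truth[1:6], rev(truth[7:12]), truth[13:18])
  maps <- lapply(seq_along(slices), function(i)
    map_from_order(paste0("RH", i), slices[[i]], ds$calls))
  asm <- assemble_chromosome("LG1", maps, ds$genetic_map)
  expect_equal(asm$order$group, c("RH1", "RH2", "RH3"))
  expect_equal(asm$order$flip, c(FALSE, TRUE, FALSE))
})

test_that("FISH constraints override anchor order and report conflicts", {
  gmap <- data.frame(lg = "LG1", marker = c("MS1", "MS2", "MS3", "MS4"),
                     cm = c(0, 10, 40, 50))
  g1 <- fake_map("RH1", c("MS1", "MS2", "B1", "B2"), cr = c(0, 10, 20, 30))
  g2 <- fake_map("RH2", c("MS3", "MS4", "B3"), cr = c(0, 10, 20))
  fish <- data.frame(marker = c("B1", "B2", "B3"), chromosome = "LG1",
                     arm = c("long", "long", "short"), rank = c(1, 2, 1))
  asm <- assemble_chromosome("LG1", list(g1, g2), gmap, constraints = fish)
  # FISH puts RH2 (short arm) before RH1 (long arm), reversing anchor order
  expect_equal(asm$order$group, c("RH2", "RH1"))
  expect_true(length(asm$conflicts) > 0)
})

test_that("order comparison reports LCS and local inversions", {
  gmap <- data.frame(lg = "LG1", marker = paste0("MS", 1:5),
                     cm = c(0, 10, 20, 30, 40))
  same <- fake_map("RH1", paste0("MS", 1:5))
  asm <- assemble_chromosome("LG1", list(same), gmap)
  cmp <- compare_orders(asm, list(same), gmap)
  expect_equal(cmp$lcs, 5L)
  expect_equal(nrow(cmp$inverted_pairs), 0)

  swapped <- fake_map("RH1", paste0("MS", c(1, 3, 2, 4, 5)))
  asm2 <- assemble_chromosome("LG1", list(swapped), gmap)
  cmp2 <- compare_orders(asm2, list(swapped), gmap)
  expect_equal(cmp2$lcs, 4L)
  expect_equal(nrow(cmp2$inverted_pairs), 1)
  expect_setequal(unlist(cmp2$inverted_pairs[1, ]), c("MS3", "MS2"))

  # random permutations agree with a brute-force LCS oracle
  set.seed(61)
  gmap8 <- data.frame(lg = "LG1", marker = paste0("MS", 1:8),
                      cm = seq(0, 70, by = 10))
  for (k in 1:5) {
    perm <- sample(8)
    mp <- fake_map("RH1", paste0("MS", perm))
    asm3 <- assemble_chromosome("LG1", list(mp), gmap8)
    cmp3 <- compare_orders(asm3, list(mp), gmap8)
    oracle <- max(brute_lcs(cmp3$rh_order, cmp3$genetic_order),
                  brute_lcs(rev(cmp3$rh_order), cmp3$genetic_order))
    expect_equal(cmp3$lcs, oracle)
  }
})
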