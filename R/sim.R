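#' Simulation configuration for a radiation hybrid panel
#'
#' Bundles every parameter of the synthetic RH study: the donor genome layout,
#' the irradiation/retention model, genotyping noise, the genetic map scale and
#' the model-species rearrangement specs.  Defaults reproduce the conditions of
#' a 3500-rad tilapia-style panel: 190 hybrid clones, fragment retention 0.117,
#' 27.5 kb per centiray and 840 kb per centimorgan.
#'
#' @param n_chromosomes number of donor chromosomes.
#' @param markers_per_chromosome marker count per chromosome; scalar or a
#'   vector of length `n_chromosomes`.
#' @param chromosome_length_kb chromosome length(s) in kb; scalar or vector.
#' @param retention_rate probability that a fragment is retained in a clone.
#' @param kb_per_cr physical distance corresponding to one centiray; the
#'   Poisson breakage rate is `1 / (100 * kb_per_cr)` per kb.
#' @param kb_per_cm physical distance per centimorgan on the genetic map.
#' @param n_clones number of hybrid cell lines in the panel.
#' @param false_positive_rate probability an absent marker is called present.
#' @param false_negative_rate probability a present marker is called absent.
#' @param ambiguous_rate probability a call is blanked to ambiguous (code 2).
#' @param microsatellite_fraction fraction of markers that are microsatellites
#'   (the subset carried by the genetic map).
#' @param species_specs list of [species_spec()] records describing model
#'   genomes derived from the donor genome by rearrangement.
#' @param spacing `"random"` places markers uniformly at random; `"even"`
#'   places them at equal gaps jittered by `spacing_jitter` of one gap, which
#'   bounds every inter-marker distance (useful when gaps must stay within the
#'   linkable range).
#' @param spacing_jitter jitter fraction for `spacing = "even"`.
#' @param split_chromosome optional chromosome index whose microsatellites are
#'   emitted under two linkage-group labels, creating a ground-truth LG merge.
#' @param map_jitter_cm standard deviation of Gaussian jitter added to genetic
#'   map positions (cM).
#' @param inversion_span number of consecutive markers reversed by one
#'   simulated inversion.
#' @param seed master seed; all stages draw from substreams derived from it.
#' @return an object of class `rh_sim_config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 8, seed = 7)
#' @export
sim_config <- function(n_chromosomes = 3,
                       markers_per_chromosome = 20,
                       chromosome_length_kb = 15000,
                       retention_rate = 0.117,
                       kb_per_cr = 27.5,
                       kb_per_cm = 840,
                       n_clones = 190,
                       false_positive_rate = 0.01,
                       false_negative_rate = 0.01,
                       ambiguous_rate = 0.02,
                       microsatellite_fraction = 0.11,
                       species_specs = list(),
                       spacing = c("random", "even"),
                       spacing_jitter = 0.25,
                       split_chromosome = NULL,
                       map_jitter_cm = 0,
                       inversion_span = 2L,
                       seed = 1L) {
  spacing <- match.arg(spacing)
  if (!is_count(n_chromosomes))
    stop_rhmap("n_chromosomes must be a positive integer", "rhmap_config_error")
  m <- rep_len(as.integer(markers_per_chromosome), n_chromosomes)
  if (any(!is.finite(m)) || any(m < 1))
    stop_rhmap("markers_per_chromosome must be >= 1", "rhmap_config_error")
  len <- rep_len(as.numeric(chromosome_length_kb), n_chromosomes)
  if (any(len <= 0))
    stop_rhmap("chromosome_length_kb must be positive", "rhmap_config_error")
  probs <- c(retention_rate, false_positive_rate, false_negative_rate,
             ambiguous_rate, microsatellite_fraction)
  if (!is_prob(probs))
    stop_rhmap("rates and fractions must lie in [0, 1]", "rhmap_config_error")
  if (kb_per_cr <= 0 || kb_per_cm <= 0)
    stop_rhmap("kb_per_cr and kb_per_cm must be positive", "rhmap_config_error")
  if (!is_count(n_clones))
    stop_rhmap("n_clones must be >= 1", "rhmap_config_error")
  if (!is.null(split_chromosome) &&
      (!is_count(split_chromosome) || split_chromosome > n_chromosomes))
    stop_rhmap("split_chromosome out of range", "rhmap_config_error")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = m,
    chromosome_length_kb = len,
    retention_rate = retention_rate,
    kb_per_cr = kb_per_cr,
    kb_per_cm = kb_per_cm,
    n_clones = as.integer(n_clones),
    false_positive_rate = false_positive_rate,
    false_negative_rate = false_negative_rate,
    ambiguous_rate = ambiguous_rate,
    microsatellite_fraction = microsatellite_fraction,
    species_specs = species_specs,
    spacing = spacing,
    spacing_jitter = spacing_jitter,
    split_chromosome = split_chromosome,
    map_jitter_cm = map_jitter_cm,
    inversion_span = as.integer(inversion_span),
    seed = as.integer(seed)
  ), class = "rh_sim_config")
}

#' Model-species rearrangement specification
#'
#' @param name species name used in anchor tables.
#' @param fusions,fissions,translocations,inversions number of rearrangements
#'   of each kind applied to the donor genome.
#' @param missing_rate probability a marker has no located ortholog in this
#'   species.
#' @return a `species_spec` list.
#' @examples
#' species_spec("stickleback", fusions = 1)
#' @export
species_spec <- function(name, fusions = 0L, fissions = 0L,
                         translocations = 0L, inversions = 0L,
                         missing_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L, is_prob(missing_rate))
  structure(list(name = name, fusions = as.integer(fusions),
                 fissions = as.integer(fissions),
                 translocations = as.integer(translocations),
                 inversions = as.integer(inversions),
                 missing_rate = missing_rate),
            class = "species_spec")
}

marker_ids <- function(classes) {
  ids <- character(length(classes))
  fmt <- c(microsatellite = "MS%03d", gene = "C%04d",
           `BAC-end` = "WG%03d", SNP = "SNP%03d")
  for (cl in names(fmt)) {
    sel <- classes == cl
    ids[sel] <- sprintf(fmt[[cl]], seq_len(sum(sel)))
  }
  ids
}

#' Simulate a donor genome with classed, positioned markers
#'
#' Places markers along each chromosome (uniformly at random by default, or at
#' jittered even gaps), assigns the configured fraction of them the
#' microsatellite class and splits the remainder across gene, BAC-end and SNP
#' classes.
#'
#' @param config an [sim_config()] object.
#' @return data frame of class `rh_genome` with columns `marker`, `chrom`,
#'   `pos_kb`, `class`; positions strictly increase within a chromosome and
#'   marker ids are unique genome-wide.
#' @examples
#' g <- simulate_genome(sim_config(n_chromosomes = 1, markers_per_chromosome = 5))
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "rh_sim_config"))
  set.seed(config$seed)
  chrom <- pos <- list()
  for (i in seq_len(config$n_chromosomes)) {
    m <- config$markers_per_chromosome[i]
    L <- config$chromosome_length_kb[i]
    if (config$spacing == "random") {
      p <- sort(runif(m, 0, L))
      while (anyDuplicated(p)) p <- sort(runif(m, 0, L))
    } else {
      gap <- L / (m + 1)
      p <- seq_len(m) * gap +
        runif(m, -config$spacing_jitter * gap, config$spacing_jitter * gap)
      p <- sort(p)
    }
    chrom[[i]] <- rep(paste0("chr", i), m)
    pos[[i]] <- p
  }
  n <- sum(config$markers_per_chromosome)
  n_ms <- round(config$microsatellite_fraction * n)
  classes <- rep("gene", n)
  if (n_ms > 0) classes[sample.int(n, n_ms)] <- "microsatellite"
  other <- which(classes == "gene")
  if (length(other))
    classes[other] <- sample(c("gene", "BAC-end", "SNP"), length(other),
                             replace = TRUE, prob = c(0.70, 0.07, 0.23))
  out <- data.frame(marker = marker_ids(classes),
                    chrom = unlist(chrom),
                    pos_kb = unlist(pos),
                    class = classes,
                    stringsAsFactors = FALSE)
  structure(out, class = c("rh_genome", "data.frame"), config = config)
}

#' Simulate a radiation hybrid panel from a donor genome
#'
#' Per clone and chromosome, breakpoints are drawn from a homogeneous Poisson
#' process with rate `1 / (100 * kb_per_cr)` per kb, so the breakage
#' probability between markers `d` kb apart is `1 - exp(-d / (100 * kb_per_cr))`.
#' Each fragment is retained independently with probability `retention_rate`;
#' a marker is present iff it lies on a retained fragment.  Genotyping noise is
#' then applied: false negatives to true presents, false positives to true
#' absents, then uniform ambiguity blanking, each stage on its own seeded
#' substream.
#'
#' @param genome an [simulate_genome()] result.
#' @param config the [sim_config()] used to build `genome`.
#' @return list of class `rh_sim` with elements `calls` (an `rh_calls`
#'   clone-by-marker matrix), `truth_calls` (pre-noise), `fragments` (retained
#'   fragments: `clone`, `chrom`, `start_kb`, `end_kb`) and `genome`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 5, n_clones = 10)
#' panel <- simulate_panel(simulate_genome(cfg), cfg)
#' @export
simulate_panel <- function(genome, config) {
  stopifnot(inherits(genome, "rh_genome"), inherits(config, "rh_sim_config"))
  if (nrow(genome) == 0) stop_rhmap("empty genome", "rhmap_config_error")
  set.seed(config$seed + 1L)
  n <- config$n_clones
  clones <- sprintf("H%03d", seq_len(n))
  calls <- matrix(0L, n, nrow(genome),
                  dimnames = list(clones, genome$marker))
  rate <- 1 / (100 * config$kb_per_cr)
  frag <- vector("list", n)
  chroms <- unique(genome$chrom)
  pos_by <- split(seq_len(nrow(genome)), factor(genome$chrom, levels = chroms))
  for (j in seq_len(n)) {
    keep <- list()
    for (ci in seq_along(chroms)) {
      idx <- pos_by[[ci]]
      L <- config$chromosome_length_kb[ci]
      nb <- rpois(1, L * rate)
      bounds <- c(0, sort(runif(nb, 0, L)), L)
      retained <- runif(length(bounds) - 1L) < config$retention_rate
      fi <- findInterval(genome$pos_kb[idx], bounds,
                         rightmost.closed = TRUE, all.inside = TRUE)
      calls[j, idx] <- as.integer(retained[fi])
      if (any(retained))
        keep[[length(keep) + 1L]] <- data.frame(
          clone = clones[j], chrom = chroms[ci],
          start_kb = bounds[which(retained)],
          end_kb = bounds[which(retained) + 1L],
          stringsAsFactors = FALSE)
    }
    frag[[j]] <- if (length(keep)) do.call(rbind, keep) else NULL
  }
  truth <- calls
  set.seed(config$seed + 2L)
  pres <- which(calls == 1L)
  if (config$false_negative_rate > 0 && length(pres))
    calls[pres[runif(length(pres)) < config$false_negative_rate]] <- 0L
  set.seed(config$seed + 3L)
  abs_ <- which(truth == 0L)
  if (config$false_positive_rate > 0 && length(abs_))
    calls[abs_[runif(length(abs_)) < config$false_positive_rate]] <- 1L
  set.seed(config$seed + 4L)
  if (config$ambiguous_rate > 0)
    calls[runif(length(calls)) < config$ambiguous_rate] <- 2L
  structure(list(calls = rh_call_matrix(calls),
                 truth_calls = rh_call_matrix(truth),
                 fragments = do.call(rbind, frag),
                 genome = genome, config = config),
            class = "rh_sim")
}

#' Simulate the genetic (meiotic) map over the microsatellite subset
#'
#' Each microsatellite receives a cM position proportional to its physical
#' position (`pos_kb / kb_per_cm`), optionally jittered.  One linkage group is
#' emitted per chromosome; `split_chromosome` in the config splits that
#' chromosome's microsatellites into two LG labels, creating a ground-truth
#' LG-merge case.
#'
#' @inheritParams simulate_panel
#' @return data frame with columns `lg`, `marker`, `cm`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 10,
#'                   microsatellite_fraction = 0.5)
#' gm <- simulate_genetic_map(simulate_genome(cfg), cfg)
#' @export
simulate_genetic_map <- function(genome, config) {
  stopifnot(inherits(genome, "rh_genome"), inherits(config, "rh_sim_config"))
  ms <- genome[genome$class == "microsatellite", , drop = FALSE]
  if (nrow(ms) == 0) {
    warn_rhmap("genome has no microsatellites; genetic map is empty")
    return(data.frame(lg = character(), marker = character(), cm = numeric()))
  }
  set.seed(config$seed + 5L)
  cm <- ms$pos_kb / config$kb_per_cm
  if (config$map_jitter_cm > 0)
    cm <- pmax(0, cm + rnorm(nrow(ms), 0, config$map_jitter_cm))
  chrom_idx <- match(ms$chrom, unique(genome$chrom))
  lg <- paste0("LG", chrom_idx)
  if (!is.null(config$split_chromosome)) {
    i <- config$split_chromosome
    mid <- config$chromosome_length_kb[i] / 2
    sel <- chrom_idx == i & ms$pos_kb > mid
    lg[sel] <- paste0("LG", config$n_chromosomes + 1L)
    cm[sel] <- cm[sel] - min(cm[sel])
  }
  out <- data.frame(lg = lg, marker = ms$marker, cm = cm,
                    stringsAsFactors = FALSE)
  out[order(out$lg, out$cm, out$marker), , drop = FALSE]
}

## -- model species rearrangement machinery -----------------------------------

# pick an interior cut in `v` (a marker index vector) leaving >= 2 markers per
# side and avoiding positions inside recorded inversion spans (tilapia indices)
feasible_cuts <- function(v, blocked) {
  cuts <- seq(2L, length(v) - 2L)
  if (length(blocked))
    cuts <- cuts[!(cuts %in% blocked) & !((cuts + 1L) %in% blocked)]
  cuts
}

#' Simulate a rearranged model-species genome and its anchor table
#'
#' Derives each model species from the donor genome by seeded inversions (of
#' `inversion_span` consecutive markers, interior and non-overlapping), then
#' fissions, fusions and reciprocal translocations, each cut leaving at least
#' two markers per side.  Model coordinates are rank-based along each model
#' chromosome.  Orthologs are dropped at the species' `missing_rate`.  Every
#' within-chromosome junction the rearrangements create is recorded as a
#' ground-truth breakpoint (kind `"interchromosomal"` or `"inversion"`).
#'
#' @inheritParams simulate_panel
#' @return list with `anchors` (data frame: `marker`, `species`, `chrom`,
#'   `start`, `end`, `pos`) and `truth` (data frame: `species`, `chrom` --
#'   donor chromosome, `left_marker`, `right_marker`, `kind`).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 8,
#'                   species_specs = list(species_spec("medaka", inversions = 1)))
#' sp <- simulate_model_species(simulate_genome(cfg), cfg)
#' @export
simulate_model_species <- function(genome, config) {
  stopifnot(inherits(genome, "rh_genome"), inherits(config, "rh_sim_config"))
  specs <- config$species_specs
  if (!length(specs))
    stop_rhmap("species_specs is empty", "rhmap_config_error")
  anchors <- list()
  truth <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    set.seed(config$seed + 10L + si)
    res <- rearrange_one_species(genome, spec, config$inversion_span)
    tag <- toupper(substr(spec$name, 1, 3))
    rows <- list()
    for (k in seq_along(res$chrs)) {
      mk <- res$chrs[[k]]
      pos <- seq_along(mk) * 50000
      rows[[k]] <- data.frame(marker = mk, species = spec$name,
                              chrom = sprintf("%s%02d", tag, k),
                              start = pos - 250, end = pos + 250, pos = pos,
                              stringsAsFactors = FALSE)
    }
    an <- do.call(rbind, rows)
    if (spec$missing_rate > 0)
      an <- an[runif(nrow(an)) >= spec$missing_rate, , drop = FALSE]
    anchors[[si]] <- an
    if (nrow(res$truth)) {
      res$truth$species <- spec$name
      truth[[length(truth) + 1L]] <- res$truth
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), left_marker = character(),
               right_marker = character(), kind = character(),
               species = character())
  list(anchors = do.call(rbind, anchors),
       truth = truth[, c("species", "chrom", "left_marker", "right_marker",
                         "kind"), drop = FALSE])
}

rearrange_one_species <- function(genome, spec, span) {
  chrom_names <- unique(genome$chrom)
  chrs <- lapply(chrom_names, function(cn) genome$marker[genome$chrom == cn])
  origin <- rep(chrom_names, lengths(chrs))
  names(origin) <- unlist(chrs)
  tilapia_order <- chrs  # pre-rearrangement order, for truth lookups
  blocked <- lapply(chrs, function(x) integer())  # inverted spans per donor chr
  truth <- list()
  note <- function(chr, left, right, kind)
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chr, left_marker = left, right_marker = right, kind = kind,
      stringsAsFactors = FALSE)
  ## inversions first, on the untouched donor chromosomes
  for (k in seq_len(spec$inversions)) {
    ok <- FALSE
    for (attempt in 1:200) {
      ci <- sample.int(length(chrs), 1)
      len <- length(chrs[[ci]])
      if (len < span + 2L) next
      starts <- seq(2L, len - span)
      bad <- blocked[[ci]]
      if (length(bad))
        starts <- starts[vapply(starts, function(s)
          !any(seq(s - 1L, s + span) %in% bad), logical(1))]
      if (!length(starts)) next
      s <- if (length(starts) == 1L) starts else sample(starts, 1)
      seg <- seq(s, s + span - 1L)
      v <- chrs[[ci]]
      note(chrom_names[ci], v[s - 1L], v[s], "inversion")
      note(chrom_names[ci], v[s + span - 1L], v[s + span], "inversion")
      chrs[[ci]][seg] <- rev(v[seg])
      blocked[[ci]] <- c(blocked[[ci]], seg)
      ok <- TRUE
      break
    }
    if (!ok)
      stop_rhmap("cannot place the requested inversions", "rhmap_config_error")
  }
  donor_of <- seq_along(chrs)  # index into `blocked` while chrs are still donor
  ## fissions
  for (k in seq_len(spec$fissions)) {
    cand <- which(lengths(chrs) >= 4L & !is.na(donor_of))
    feas <- lapply(cand, function(ci)
      feasible_cuts(chrs[[ci]], blocked[[donor_of[ci]]]))
    cand <- cand[lengths(feas) > 0]
    if (!length(cand))
      stop_rhmap("cannot place the requested fissions", "rhmap_config_error")
    ci <- if (length(cand) == 1L) cand else sample(cand, 1)
    cuts <- feasible_cuts(chrs[[ci]], blocked[[donor_of[ci]]])
    cut <- if (length(cuts) == 1L) cuts else sample(cuts, 1)
    v <- chrs[[ci]]
    note(origin[[v[cut]]], v[cut], v[cut + 1L], "interchromosomal")
    chrs[[ci]] <- v[seq_len(cut)]
    chrs[[length(chrs) + 1L]] <- v[seq(cut + 1L, length(v))]
    donor_of <- c(donor_of, NA_integer_)  # split pieces: no further cuts needed
  }
  ## fusions
  for (k in seq_len(spec$fusions)) {
    if (length(chrs) < 2L)
      stop_rhmap("cannot place the requested fusions", "rhmap_config_error")
    pick <- sample.int(length(chrs), 2)
    chrs[[pick[1]]] <- c(chrs[[pick[1]]], chrs[[pick[2]]])
    chrs[[pick[2]]] <- NULL
    donor_of <- donor_of[-pick[2]]
    donor_of[pick[1]] <- NA_integer_
  }
  ## reciprocal translocations
  for (k in seq_len(spec$translocations)) {
    cand <- which(lengths(chrs) >= 4L)
    ok_cut <- function(ci) {
      v <- chrs[[ci]]
      cuts <- seq(2L, length(v) - 2L)
      # both flanks must come from one donor chromosome, outside inversions
      keep <- vapply(cuts, function(cu) {
        a <- v[cu]; b <- v[cu + 1L]
        if (origin[[a]] != origin[[b]]) return(FALSE)
        di <- match(origin[[a]], chrom_names)
        ia <- match(a, tilapia_order[[di]]); ib <- match(b, tilapia_order[[di]])
        !any(c(ia, ib) %in% blocked[[di]])
      }, logical(1))
      cuts[keep]
    }
    feas <- lapply(cand, ok_cut)
    cand <- cand[lengths(feas) > 0]
    if (length(cand) < 2L)
      stop_rhmap("cannot place the requested translocations",
                 "rhmap_config_error")
    pick <- sample(cand, 2)
    for (ci in pick) {
      cuts <- ok_cut(ci)
      cut <- if (length(cuts) == 1L) cuts else sample(cuts, 1)
      v <- chrs[[ci]]
      note(origin[[v[cut]]], v[cut], v[cut + 1L], "interchromosomal")
      attr(chrs[[ci]], "cut") <- cut
    }
    v1 <- chrs[[pick[1]]]; v2 <- chrs[[pick[2]]]
    c1 <- attr(v1, "cut"); c2 <- attr(v2, "cut")
    chrs[[pick[1]]] <- c(v1[seq_len(c1)], v2[seq(c2 + 1L, length(v2))])
    chrs[[pick[2]]] <- c(v2[seq_len(c2)], v1[seq(c1 + 1L, length(v1))])
    donor_of[pick] <- NA_integer_
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), left_marker = character(),
               right_marker = character(), kind = character(),
               stringsAsFactors = FALSE)
  list(chrs = chrs, truth = truth)
}

#' Simulate a complete RH dataset with ground truth
#'
#' Convenience wrapper running [simulate_genome()], [simulate_panel()],
#' [simulate_genetic_map()] and (when species are configured)
#' [simulate_model_species()].
#'
#' @param config an [sim_config()] object.
#' @return list of class `rh_sim_dataset` with `genome`, `calls`,
#'   `truth_calls`, `fragments`, `genetic_map`, `anchors`, `truth_synteny`,
#'   `truth_order` (list of marker vectors per chromosome) and `config`.
#' @examples
#' ds <- simulate_rh_dataset(sim_config(n_chromosomes = 2,
#'                                      markers_per_chromosome = 6,
#'                                      n_clones = 20))
#' @export
simulate_rh_dataset <- function(config) {
  genome <- simulate_genome(config)
  panel <- simulate_panel(genome, config)
  gmap <- suppressWarnings(simulate_genetic_map(genome, config))
  sp <- if (length(config$species_specs))
    simulate_model_species(genome, config) else NULL
  structure(list(genome = genome,
                 calls = panel$calls,
                 truth_calls = panel$truth_calls,
                 fragments = panel$fragments,
                 genetic_map = gmap,
                 anchors = sp$anchors,
                 truth_synteny = sp$truth,
                 truth_order = split(genome$marker,
                                     factor(genome$chrom,
                                            levels = unique(genome$chrom))),
                 config = config),
            class = "rh_sim_dataset")
}
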