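#' Filter ortholog hits into a best-hit anchor table
#'
#' Keeps alignments with score at least `min_score` and alignment length in
#' `[min_len, max_len]` (guarding against retrogene-length hits), then retains
#' the highest-scoring survivor per (marker, species); ties break by
#' (chromosome, start) ascending.  Hits on an unresolved "chromosome unknown"
#' sequence are kept for cross-species tallies ([venn_partition()]) but
#' flagged so positional analyses exclude them.
#'
#' @param hits data frame with columns `marker`, `species`, `chrom`, `start`,
#'   `end` (0-based half-open bp), `score`, `length`; `strand` optional and
#'   ignored (orientation is inferred from coordinate monotonicity).
#' @param min_score minimum alignment score.
#' @param min_len,max_len alignment-length window in nt.
#' @param unknown_pattern regular expression identifying unknown-chromosome
#'   names.
#' @return data frame of class `rh_anchor_table`: `marker`, `species`,
#'   `chrom`, `start`, `end`, `score`, `length`, `pos` (interval midpoint),
#'   `unknown_chrom`.
#' @examples
#' h <- data.frame(marker = "C1", species = "stickleback", chrom = "GAC01",
#'                 start = 100, end = 250, score = 300, length = 150)
#' filter_hits(h)
#' @export
filter_hits <- function(hits, min_score = 250, min_len = 80, max_len = 300,
                        unknown_pattern = "^(chr)?un") {
  need <- c("marker", "species", "chrom", "start", "end", "score", "length")
  stopifnot(is.data.frame(hits), all(need %in% names(hits)))
  if (any(hits$end <= hits$start)) stop_rhmap("hit intervals must have end > start")
  if (any(hits$score < 0)) stop_rhmap("scores must be non-negative")
  keep <- hits$score >= min_score & hits$length >= min_len &
    hits$length <= max_len
  sv <- hits[keep, need, drop = FALSE]
  if (nrow(sv)) {
    ord <- order(sv$marker, sv$species, -sv$score, sv$chrom, sv$start)
    sv <- sv[ord, , drop = FALSE]
    sv <- sv[!duplicated(sv[, c("marker", "species")]), , drop = FALSE]
  }
  sv$pos <- (sv$start + sv$end) / 2
  sv$unknown_chrom <- grepl(unknown_pattern, sv$chrom, ignore.case = TRUE)
  rownames(sv) <- NULL
  structure(sv, class = c("rh_anchor_table", "data.frame"))
}

#' Cross-species partition of markers by where they have retained hits
#'
#' Assigns every marker with at least one retained best hit to the subset of
#' species in which it hit (unknown-chromosome hits count), and reports subset
#' counts, per-species totals and percentages of the grand total (1 decimal).
#'
#' @param anchors an [filter_hits()] table (or any data frame with `marker`
#'   and `species`).
#' @param species optional species order for the report.
#' @return list of class `rh_venn`: `subsets` (data frame `species_set`,
#'   `count`), `totals` (data frame `species`, `count`, `percent`),
#'   `n_markers` (grand total).
#' @examples
#' a <- data.frame(marker = c("C1", "C1", "C2"),
#'                 species = c("stickleback", "medaka", "stickleback"))
#' venn_partition(a)
#' @export
venn_partition <- function(anchors, species = NULL) {
  stopifnot(all(c("marker", "species") %in% names(anchors)))
  species <- species %||% sort(unique(anchors$species))
  sets <- lapply(split(anchors$species, anchors$marker),
                 function(s) paste(sort(unique(s)), collapse = "+"))
  key <- unlist(sets)
  n <- length(key)
  subsets <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(subsets) <- c("species_set", "count")
  subsets <- subsets[order(-subsets$count, subsets$species_set), ]
  rownames(subsets) <- NULL
  totals <- data.frame(
    species = species,
    count = vapply(species, function(s)
      sum(vapply(strsplit(key, "\\+"), function(k) s %in% k, logical(1))),
      integer(1)),
    stringsAsFactors = FALSE)
  totals$percent <- round(100 * totals$count / n, 1)
  rownames(totals) <- NULL
  structure(list(subsets = subsets, totals = totals, n_markers = n),
            class = "rh_venn")
}

#' Decompose a chromosome map into conserved segments and singletons
#'
#' Walks the map-ordered markers restricted to those anchored (on a known
#' chromosome) in the given species.  Maximal runs of two or more consecutive
#' anchored markers on the same model chromosome form conserved segments
#' (CS); runs of one are singletons.  Markers without an anchor are skipped
#' and do not break runs.
#'
#' @param order marker ids in map order (one donor chromosome).
#' @param anchors an [filter_hits()] table or simulator anchor table
#'   (`marker`, `species`, `chrom`, `pos`).
#' @param species species to analyse.
#' @return list of class `rh_cs`: `assignment` (data frame `marker`,
#'   `model_chrom`, `pos`, `segment` -- CS id or NA for singletons),
#'   `segments` (data frame `segment`, `model_chrom`, `n_markers`),
#'   `singletons` (data frame `marker`, `model_chrom`).
#' @examples
#' a <- data.frame(marker = c("m1", "m2", "m3"), species = "medaka",
#'                 chrom = c("OLA1", "OLA1", "OLA2"), pos = c(10, 20, 5))
#' detect_cs(c("m1", "m2", "m3"), a, "medaka")
#' @export
detect_cs <- function(order, anchors, species) {
  an <- anchors[anchors$species == species, , drop = FALSE]
  if (!is.null(an$unknown_chrom)) an <- an[!an$unknown_chrom, , drop = FALSE]
  an <- an[match(order, an$marker), , drop = FALSE]
  keep <- !is.na(an$marker)
  an <- an[keep, c("marker", "chrom", "pos"), drop = FALSE]
  names(an) <- c("marker", "model_chrom", "pos")
  rownames(an) <- NULL
  if (!nrow(an)) {
    return(structure(list(
      assignment = cbind(an, segment = integer(0)),
      segments = data.frame(segment = integer(), model_chrom = character(),
                            n_markers = integer()),
      singletons = data.frame(marker = character(), model_chrom = character())),
      class = "rh_cs"))
  }
  run <- cumsum(c(TRUE, an$model_chrom[-1] != an$model_chrom[-nrow(an)]))
  run_len <- ave(run, run, FUN = length)
  seg_id <- integer(nrow(an))
  seg_id[run_len >= 2L] <- match(run[run_len >= 2L],
                                 unique(run[run_len >= 2L]))
  an$segment <- ifelse(run_len >= 2L, seg_id, NA_integer_)
  segs <- unique(run[run_len >= 2L])
  segments <- data.frame(
    segment = seq_along(segs),
    model_chrom = vapply(segs, function(s) an$model_chrom[run == s][1], ""),
    n_markers = vapply(segs, function(s) sum(run == s), integer(1)),
    stringsAsFactors = FALSE)
  singles <- an[is.na(an$segment), c("marker", "model_chrom"), drop = FALSE]
  rownames(singles) <- NULL
  structure(list(assignment = an, segments = segments, singletons = singles),
            class = "rh_cs")
}

#' Decompose a conserved segment into ordered runs (CSO)
#'
#' Greedy left-to-right decomposition of the segment's ortholog coordinate
#' sequence into maximal strictly monotone runs; the direction (increasing or
#' decreasing) is fixed by each run's first two members.  Runs of two or more
#' markers are conserved segments ordered (CSO); isolated members stay
#' unassigned.
#'
#' @param cs_markers markers of one CS, in map order.
#' @param coords their ortholog coordinates on the model chromosome; must be
#'   unique.
#' @return data frame `marker`, `coord`, `run` (NA for isolated members),
#'   `direction` (`"+"`, `"-"` or NA).
#' @examples
#' detect_cso(paste0("m", 1:5), c(10, 20, 30, 25, 35))
#' @export
detect_cso <- function(cs_markers, coords) {
  stopifnot(length(cs_markers) == length(coords), length(cs_markers) >= 2L)
  if (anyDuplicated(coords))
    stop_rhmap("ortholog coordinates must be unique within a chromosome",
               "rhmap_tie_error")
  n <- length(coords)
  run <- integer(n)
  dirs <- character(n)
  cur <- 1L; run[1] <- 1L
  dir <- 0L  # unset until the run has two members
  for (k in seq(2L, n)) {
    step <- sign(coords[k] - coords[k - 1L])
    if (dir == 0L || step == dir) {
      if (dir == 0L) dir <- step
      run[k] <- cur
    } else {
      cur <- cur + 1L
      run[k] <- cur
      dir <- 0L
    }
  }
  len <- ave(run, run, FUN = length)
  out <- data.frame(marker = cs_markers, coord = coords,
                    run = ifelse(len >= 2L, run, NA_integer_),
                    stringsAsFactors = FALSE)
  out$run <- ifelse(is.na(out$run), NA_integer_,
                    match(out$run, unique(out$run[!is.na(out$run)])))
  dir_of <- tapply(out$coord, out$run, function(x) if (x[2] > x[1]) "+" else "-")
  out$direction <- ifelse(is.na(out$run), NA_character_,
                          unname(dir_of[as.character(out$run)]))
  out
}

#' Synteny decomposition of a full map against one species
#'
#' Runs [detect_cs()] per chromosome and [detect_cso()] within each CS.
#'
#' @param orders named list: chromosome -> marker ids in map order.
#' @param anchors anchor table (see [detect_cs()]).
#' @param species species to analyse.
#' @return list of class `rh_synteny`: per chromosome, the `rh_cs` object
#'   with a `cso` list (one decomposition per CS) attached.
#' @export
synteny_decompose <- function(orders, anchors, species) {
  out <- lapply(orders, function(ord) {
    cs <- detect_cs(ord, anchors, species)
    cs$cso <- lapply(seq_len(nrow(cs$segments)), function(s) {
      sel <- !is.na(cs$assignment$segment) & cs$assignment$segment == s
      detect_cso(cs$assignment$marker[sel], cs$assignment$pos[sel])
    })
    cs
  })
  structure(out, class = "rh_synteny", species = species)
}

#' Oxford grid of a synteny decomposition
#'
#' Cross-tabulates donor chromosomes against model chromosomes; each cell
#' holds the number of CS markers and of singletons.  Margins and the grand
#' total (which equals the species' anchor count) are attached.
#'
#' @param synteny an [synteny_decompose()] result.
#' @return list of class `rh_oxford`: `cs_counts` and `singleton_counts`
#'   (matrices donor x model chromosome), `row_totals`, `col_totals`,
#'   `n_anchors`.
#' @export
oxford_grid <- function(synteny) {
  stopifnot(inherits(synteny, "rh_synteny"))
  donors <- names(synteny)
  models <- sort(unique(unlist(lapply(synteny, function(cs)
    cs$assignment$model_chrom))))
  cs_m <- sg_m <- matrix(0L, length(donors), length(models),
                         dimnames = list(donors, models))
  for (d in donors) {
    a <- synteny[[d]]$assignment
    if (!nrow(a)) next
    in_cs <- !is.na(a$segment)
    if (any(in_cs)) {
      t1 <- table(a$model_chrom[in_cs])
      cs_m[d, names(t1)] <- cs_m[d, names(t1)] + as.integer(t1)
    }
    if (any(!in_cs)) {
      t2 <- table(a$model_chrom[!in_cs])
      sg_m[d, names(t2)] <- sg_m[d, names(t2)] + as.integer(t2)
    }
  }
  tot <- cs_m + sg_m
  structure(list(cs_counts = cs_m, singleton_counts = sg_m,
                 row_totals = rowSums(tot), col_totals = colSums(tot),
                 n_anchors = sum(tot)), class = "rh_oxford")
}

#' Per-chromosome CS and CSO counts across species
#'
#' @param decompositions named list: species -> [synteny_decompose()] result.
#' @return data frame `chromosome`, `species`, `n_cs`, `n_cso`; chromosomes
#'   with no anchors in a species carry NA counts (rendered `"un"` by
#'   [format_cs_cso()]).
#' @export
summarize_cs_cso <- function(decompositions) {
  rows <- list()
  for (sp in names(decompositions)) {
    dec <- decompositions[[sp]]
    for (chr in names(dec)) {
      a <- dec[[chr]]$assignment
      if (!nrow(a)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chr, species = sp, n_cs = NA_integer_,
          n_cso = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      n_cso <- sum(vapply(dec[[chr]]$cso, function(x)
        length(unique(x$run[!is.na(x$run)])), integer(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, species = sp,
        n_cs = nrow(dec[[chr]]$segments), n_cso = n_cso,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Render a CS/CSO summary with "un" for unanchored chromosomes
#'
#' @param summary a [summarize_cs_cso()] data frame.
#' @return wide character data frame, one row per chromosome, `CS`/`CSO`
#'   columns per species.
#' @export
format_cs_cso <- function(summary) {
  chrs <- unique(summary$chromosome)
  out <- data.frame(chromosome = chrs, stringsAsFactors = FALSE)
  for (sp in unique(summary$species)) {
    sub <- summary[summary$species == sp, ]
    cs <- sub$n_cs[match(chrs, sub$chromosome)]
    cso <- sub$n_cso[match(chrs, sub$chromosome)]
    out[[paste0(sp, "_CS")]] <- ifelse(is.na(cs), "un", as.character(cs))
    out[[paste0(sp, "_CSO")]] <- ifelse(is.na(cso), "un", as.character(cso))
  }
  out
}
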