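#' Anchor RH groups to genetic linkage groups via shared microsatellites
#'
#' Each ordered RH group is assigned to the linkage group (LG) holding the
#' majority of its microsatellites shared with the genetic map.  Ties are
#' broken toward the LG whose shared anchors span the smaller cM range, then
#' lexicographically.  Groups with anchors on more than one LG emit conflict
#' records (the raw material for LG-merge detection); groups with no anchors
#' are orphans.
#'
#' @param maps list of `rh_map` objects.
#' @param gmap genetic map data frame with columns `lg`, `marker`, `cm`.
#' @return list of class `rh_anchoring`: `assignments` (data frame `group`,
#'   `lg`, `n_anchors`), `conflicts` (data frame `group`, `lg`, `n_anchors`,
#'   one row per (group, LG) with anchors), `orphans` (character vector).
#' @examples
#' gmap <- data.frame(lg = "LG1", marker = c("MS001", "MS002"), cm = c(0, 5))
#' mp <- structure(list(group = "RH1", markers = c("MS001", "MS002"),
#'                      cr = c(0, 50)), class = "rh_map")
#' anchor_groups(list(mp), gmap)
#' @export
anchor_groups <- function(maps, gmap) {
  stopifnot(is.list(maps), all(c("lg", "marker", "cm") %in% names(gmap)))
  assignments <- conflicts <- list()
  orphans <- character()
  for (mp in maps) {
    hit <- gmap[gmap$marker %in% mp$markers, , drop = FALSE]
    if (!nrow(hit)) {
      orphans <- c(orphans, mp$group)
      next
    }
    tab <- table(hit$lg)
    lgs <- names(tab)
    if (length(lgs) > 1L)
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        group = mp$group, lg = lgs, n_anchors = as.integer(tab),
        stringsAsFactors = FALSE)
    top <- lgs[tab == max(tab)]
    if (length(top) > 1L) {
      span <- vapply(top, function(l) {
        cm <- hit$cm[hit$lg == l]
        diff(range(cm))
      }, numeric(1))
      top <- top[order(span, top)][1]
    }
    assignments[[length(assignments) + 1L]] <- data.frame(
      group = mp$group, lg = top, n_anchors = as.integer(max(tab)),
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(group = character(), lg = character(),
                      n_anchors = integer(), stringsAsFactors = FALSE)
  structure(list(
    assignments = if (length(assignments)) do.call(rbind, assignments) else empty,
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else empty,
    orphans = orphans), class = "rh_anchoring")
}

#' Detect linkage groups joined by a single RH group
#'
#' Two LGs are merged into one chromosome when some RH group carries at least
#' `min_anchors_per_lg` shared microsatellites from each; merges are closed
#' transitively.  The classical signature is a group with two anchors on each
#' of two small LGs, which joins them into a single chromosome.
#'
#' @param anchoring an [anchor_groups()] result.
#' @param min_anchors_per_lg anchors required from each LG inside one group.
#' @return list of class `rh_merges`: `merged` (list of LG character vectors,
#'   one per merged chromosome), `chromosome` (named character: LG ->
#'   chromosome name, merged sets joined by `-`), `evidence` (data frame
#'   `group`, `lg_a`, `lg_b`).
#' @examples
#' a <- structure(list(
#'   assignments = data.frame(group = "RH1", lg = "LG8", n_anchors = 2L),
#'   conflicts = data.frame(group = "RH1", lg = c("LG8", "LG24"),
#'                          n_anchors = c(2L, 2L)),
#'   orphans = character()), class = "rh_anchoring")
#' detect_lg_merges(a)
#' @export
detect_lg_merges <- function(anchoring, min_anchors_per_lg = 2L) {
  stopifnot(inherits(anchoring, "rh_anchoring"))
  lgs <- unique(c(anchoring$assignments$lg, anchoring$conflicts$lg))
  evidence <- list()
  cf <- anchoring$conflicts
  for (g in unique(cf$group)) {
    sub <- cf[cf$group == g & cf$n_anchors >= min_anchors_per_lg, ]
    if (nrow(sub) >= 2L) {
      prs <- combn(sort(sub$lg), 2)
      evidence[[length(evidence) + 1L]] <- data.frame(
        group = g, lg_a = prs[1, ], lg_b = prs[2, ], stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(group = character(), lg_a = character(), lg_b = character(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(evidence[, c("lg_a", "lg_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = lgs))
  comp <- igraph::components(g)
  sets <- split(lgs, comp$membership[lgs])
  sets <- lapply(sets, sort)
  chromosome <- character()
  for (s in sets) {
    nm <- paste(s, collapse = "-")
    chromosome[s] <- nm
  }
  structure(list(merged = unname(sets[lengths(sets) > 1L]),
                 chromosome = chromosome, evidence = evidence),
            class = "rh_merges")
}

fish_signed_rank <- function(constraints) {
  sgn <- ifelse(constraints$arm == "short", -1, 1)
  sgn * constraints$rank
}

#' Order and orient the RH groups of one chromosome
#'
#' Groups are ordered by the mean cM of their genetic-map anchors.  Each
#' group's orientation (flip flag) comes from the sign of the rank correlation
#' between its internal cR order and the anchor cM order when it has two or
#' more anchors; otherwise from the strongest end-marker two-point LOD toward
#' the neighbouring group; otherwise the group is flagged unoriented.  FISH
#' constraints (BAC marker, arm, rank from the centromere) are authoritative:
#' they override the anchor-based order/orientation and any contradiction is
#' reported, never silently resolved.
#'
#' @param chromosome chromosome name.
#' @param maps list of `rh_map` objects assigned to this chromosome.
#' @param gmap genetic map (`lg`, `marker`, `cm`).
#' @param pairs optional [all_pairs()] table for end-marker orientation.
#' @param constraints optional FISH table: `marker`, `chromosome`, `arm`
#'   (`"long"`, `"short"` or `"unknown"`), `rank` (>= 1 from the centromere).
#' @return list of class `rh_assembly`: `chromosome`, `order` (data frame
#'   `index`, `group`, `flip`, `evidence`, `mean_cm`), `conflicts` (character
#'   vector of reports).
#' @export
assemble_chromosome <- function(chromosome, maps, gmap, pairs = NULL,
                                constraints = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  info <- lapply(maps, function(mp) {
    hit <- gmap[gmap$marker %in% mp$markers, , drop = FALSE]
    list(map = mp, anchors = hit,
         mean_cm = if (nrow(hit)) mean(hit$cm) else NA_real_)
  })
  mean_cm <- vapply(info, `[[`, numeric(1), "mean_cm")
  ord <- order(mean_cm, na.last = TRUE)
  conflicts <- character()
  flips <- rep(NA, length(maps))
  evid <- rep("unoriented", length(maps))
  for (i in seq_along(info)) {
    mp <- info[[i]]$map
    an <- info[[i]]$anchors
    an <- an[!duplicated(an$marker), , drop = FALSE]
    if (nrow(an) >= 2L) {
      cr <- mp$cr[match(an$marker, mp$markers)]
      if (length(unique(cr)) > 1L && length(unique(an$cm)) > 1L) {
        rho <- suppressWarnings(cor(cr, an$cm, method = "spearman"))
        if (is.finite(rho) && rho != 0) {
          flips[i] <- rho < 0
          evid[i] <- "anchor_rank_correlation"
          next
        }
      }
    }
    # fall back to end-marker two-point LOD toward the neighbouring group
    if (!is.null(pairs)) {
      pos <- which(ord == i)
      nb_after <- pos < length(ord)
      nb <- if (nb_after) info[[ord[pos + 1L]]]$map else
        if (pos > 1L) info[[ord[pos - 1L]]]$map else NULL
      if (!is.null(nb)) {
        ends <- c(mp$markers[1], mp$markers[length(mp$markers)])
        sub <- pairs[(pairs$marker_a %in% ends & pairs$marker_b %in% nb$markers) |
                       (pairs$marker_b %in% ends & pairs$marker_a %in% nb$markers), ]
        sub <- sub[sub$usable & !is.na(sub$lod), , drop = FALSE]
        if (nrow(sub)) {
          top <- sub[which.max(sub$lod), ]
          end_mk <- if (top$marker_a %in% ends) top$marker_a else top$marker_b
          # the linked end should face the neighbouring group
          end_is_last <- end_mk == mp$markers[length(mp$markers)]
          flips[i] <- xor(end_is_last, nb_after)
          evid[i] <- "end_marker_lod"
          next
        }
      }
    }
  }
  out <- data.frame(index = seq_along(ord),
                    group = vapply(info[ord], function(z) z$map$group, ""),
                    flip = flips[ord], evidence = evid[ord],
                    mean_cm = mean_cm[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(constraints) && nrow(constraints)) {
    fc <- constraints[constraints$chromosome == chromosome, , drop = FALSE]
    if (any(fc$rank < 1)) stop_rhmap("FISH rank must be >= 1")
    if (nrow(fc)) {
      fc$signed <- fish_signed_rank(fc)
      grp_of <- function(mk) {
        for (z in info) if (mk %in% z$map$markers) return(z$map$group)
        NA_character_
      }
      fc$group <- vapply(fc$marker, grp_of, "")
      fc <- fc[!is.na(fc$group), , drop = FALSE]
      agg <- tapply(fc$signed, fc$group, mean)
      if (any(duplicated(paste(fc$chromosome, fc$arm, fc$rank))))
        conflicts <- c(conflicts, "duplicate FISH rank within an arm")
      fish_ord <- names(sort(agg))
      present <- out$group[out$group %in% fish_ord]
      if (!identical(present, fish_ord)) {
        conflicts <- c(conflicts, sprintf(
          "FISH order (%s) contradicts anchor order (%s); FISH order applied",
          paste(fish_ord, collapse = " < "), paste(present, collapse = " < ")))
      }
      out$fish_key <- match(out$group, fish_ord)
      out <- out[order(is.na(out$fish_key), out$fish_key, out$index), ]
      out$index <- seq_len(nrow(out))
      out$fish_key <- NULL
      # orientation from >= 2 constrained markers inside one group
      for (g in unique(fc$group)) {
        sub <- fc[fc$group == g, ]
        if (nrow(sub) >= 2L) {
          mp <- info[[which(vapply(info, function(z) z$map$group, "") == g)]]$map
          cr <- mp$cr[match(sub$marker, mp$markers)]
          rho <- suppressWarnings(cor(cr, sub$signed, method = "spearman"))
          if (is.finite(rho) && rho != 0) {
            prev <- out$flip[out$group == g]
            newf <- rho < 0
            if (!is.na(prev) && prev != newf)
              conflicts <- c(conflicts, sprintf(
                "FISH orientation of %s contradicts anchor orientation; FISH applied", g))
            out$flip[out$group == g] <- newf
            out$evidence[out$group == g] <- "fish"
          }
        }
      }
    }
  }
  structure(list(chromosome = chromosome, order = out, conflicts = conflicts),
            class = "rh_assembly")
}

lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
        else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Compare RH and genetic marker orders on an assembled chromosome
#'
#' Builds the chromosome's RH-order sequence of shared microsatellites
#' (concatenating its groups in assembly order, flipped as flagged) and
#' compares it with the genetic (cM) order: reports the longest common
#' subsequence (computed for both whole-chromosome orientations, keeping the
#' better) and the adjacent RH pairs whose genetic positions are locally
#' inverted.
#'
#' @param assembly an [assemble_chromosome()] result.
#' @param maps list of the `rh_map` objects named in the assembly.
#' @param gmap genetic map (`lg`, `marker`, `cm`).
#' @return list of class `rh_discordance`: `chromosome`, `rh_order`,
#'   `genetic_order`, `lcs`, `n_shared`, `inverted_pairs` (data frame
#'   `marker_a`, `marker_b`).
#' @export
compare_orders <- function(assembly, maps, gmap) {
  stopifnot(inherits(assembly, "rh_assembly"))
  by_id <- setNames(maps, vapply(maps, `[[`, "", "group"))
  seq_rh <- character()
  for (i in seq_len(nrow(assembly$order))) {
    g <- assembly$order$group[i]
    mp <- by_id[[g]]
    mk <- mp$markers
    if (isTRUE(assembly$order$flip[i])) mk <- rev(mk)
    seq_rh <- c(seq_rh, mk)
  }
  shared <- seq_rh[seq_rh %in% gmap$marker]
  if (length(shared) < 2L)
    stop_rhmap("need at least two shared microsatellites", "rhmap_nodata_error")
  gsub_ <- gmap[gmap$marker %in% shared, , drop = FALSE]
  gen <- gsub_$marker[order(gsub_$cm)]
  lcs_f <- lcs_length(shared, gen)
  lcs_r <- lcs_length(rev(shared), gen)
  if (lcs_r > lcs_f) {
    shared <- rev(shared)
    lcs <- lcs_r
  } else lcs <- lcs_f
  cm <- setNames(gsub_$cm, gsub_$marker)
  inv <- which(diff(cm[shared]) < 0)
  inverted <- data.frame(marker_a = shared[inv], marker_b = shared[inv + 1L],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(chromosome = assembly$chromosome, rh_order = shared,
                 genetic_order = gen, lcs = as.integer(lcs),
                 n_shared = length(shared), inverted_pairs = inverted),
            class = "rh_discordance")
}
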