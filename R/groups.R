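#' Form RH groups by single-linkage at a LOD threshold
#'
#' Builds the graph whose edges are usable marker pairs with LOD at or above
#' the threshold and returns its connected components.  Components of one
#' marker are reported as unlinked.
#'
#' @param pairs an [all_pairs()] table.
#' @param lod_threshold minimum LOD for an edge (classically 4.0, raised
#'   stepwise toward 7.0 when aberrant groups are re-analysed).
#' @param markers optional full marker set; defaults to the markers the pair
#'   table was built from, so all-ambiguous markers still appear as unlinked.
#' @return list of class `rh_groups`: `groups` (named list `RH1`, `RH2`, ...
#'   of marker vectors, largest first), `unlinked` (character vector),
#'   `lod_threshold`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 6,
#'                   false_positive_rate = 0, false_negative_rate = 0,
#'                   ambiguous_rate = 0)
#' tp <- all_pairs(simulate_panel(simulate_genome(cfg), cfg)$calls)
#' build_groups(tp, 4)
#' @export
build_groups <- function(pairs, lod_threshold = 4, markers = NULL) {
  stopifnot(inherits(pairs, "rh_pair_table"))
  markers <- markers %||% attr(pairs, "markers") %||%
    unique(c(pairs$marker_a, pairs$marker_b))
  edges <- pairs[pairs$usable & !is.na(pairs$lod) &
                   pairs$lod >= lod_threshold, c("marker_a", "marker_b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  member <- split(markers, comp$membership[markers])
  sizes <- lengths(member)
  grp <- member[sizes >= 2L]
  if (length(grp)) {
    ord <- order(-lengths(grp), vapply(grp, `[`, "", 1L))
    grp <- grp[ord]
    names(grp) <- paste0("RH", seq_along(grp))
  } else {
    grp <- setNames(list(), character())
  }
  structure(list(groups = grp,
                 unlinked = sort(unlist(member[sizes == 1L], use.names = FALSE)),
                 lod_threshold = lod_threshold),
            class = "rh_groups")
}

#' @export
print.rh_groups <- function(x, ...) {
  cat(sprintf("%d RH groups (%d markers) at LOD >= %.1f; %d unlinked\n",
              length(x$groups), sum(lengths(x$groups)), x$lod_threshold,
              length(x$unlinked)))
  invisible(x)
}

# greedy nearest-neighbour candidate order from pairwise theta estimates
greedy_order <- function(markers, pairs) {
  sub <- pairs[pairs$marker_a %in% markers & pairs$marker_b %in% markers &
                 pairs$usable, , drop = FALSE]
  th <- matrix(1, length(markers), length(markers),
               dimnames = list(markers, markers))
  th[cbind(sub$marker_a, sub$marker_b)] <- sub$theta
  th[cbind(sub$marker_b, sub$marker_a)] <- sub$theta
  diag(th) <- 0
  if (!nrow(sub)) return(markers)
  seed <- sub[which.max(sub$lod), ]
  path <- c(seed$marker_a, seed$marker_b)
  rest <- setdiff(markers, path)
  while (length(rest)) {
    d_head <- th[path[1], rest]
    d_tail <- th[path[length(path)], rest]
    if (min(d_head) <= min(d_tail)) {
      nxt <- rest[which.min(d_head)]
      path <- c(nxt, path)
    } else {
      nxt <- rest[which.min(d_tail)]
      path <- c(path, nxt)
    }
    rest <- setdiff(rest, nxt)
  }
  path
}

default_aberration_test <- function(theta_ceiling) {
  force(theta_ceiling)
  function(markers, pairs) {
    if (length(markers) < 3) return(FALSE)
    path <- greedy_order(markers, pairs)
    sub <- pairs[pairs$usable, , drop = FALSE]
    th <- setNames(sub$theta, paste(sub$marker_a, sub$marker_b))
    th2 <- setNames(sub$theta, paste(sub$marker_b, sub$marker_a))
    adj <- paste(path[-length(path)], path[-1])
    tt <- ifelse(is.na(th[adj]), th2[adj], th[adj])
    any(is.na(tt)) || any(tt > theta_ceiling)
  }
}

#' Re-analyse an aberrant RH group at stepwise higher LOD thresholds
#'
#' A group formed at a low threshold is tested for aberrations (by default: an
#' adjacent breakage fraction above `theta_ceiling` along its greedy candidate
#' order, or a missing adjacency estimate).  Failing groups are re-split into
#' connected components at the next threshold of the schedule; the process
#' repeats until every piece is clean or the schedule is exhausted, in which
#' case the piece is returned with a persistent-aberration flag.
#'
#' @param markers marker ids of the group.
#' @param pairs an [all_pairs()] table covering the group.
#' @param lod_schedule increasing LOD thresholds to escalate through.
#' @param theta_ceiling adjacent-theta ceiling of the default test.
#' @param aberration_test optional `function(markers, pairs)` returning TRUE
#'   when the group looks aberrant.
#' @return list of class `rh_refined`: `groups` (list of marker vectors),
#'   `persistent` (logical per group), `history` (data frame `lod`,
#'   `n_groups`).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 5,
#'                   false_positive_rate = 0, false_negative_rate = 0,
#'                   ambiguous_rate = 0)
#' tp <- all_pairs(simulate_panel(simulate_genome(cfg), cfg)$calls)
#' refine_group(colnames(simulate_panel(simulate_genome(cfg), cfg)$calls), tp)
#' @export
refine_group <- function(markers, pairs,
                         lod_schedule = seq(4.5, 7, by = 0.5),
                         theta_ceiling = 0.8, aberration_test = NULL) {
  stopifnot(inherits(pairs, "rh_pair_table"))
  test <- aberration_test %||% default_aberration_test(theta_ceiling)
  groups <- list(markers)
  persistent <- FALSE
  history <- data.frame(lod = numeric(), n_groups = integer())
  for (thr in lod_schedule) {
    bad <- vapply(groups, test, logical(1), pairs = pairs)
    if (!any(bad)) break
    pieces <- list()
    for (i in seq_along(groups)) {
      if (!bad[i] || length(groups[[i]]) < 2) {
        pieces[[length(pieces) + 1L]] <- groups[[i]]
        next
      }
      sub <- pairs[pairs$marker_a %in% groups[[i]] &
                     pairs$marker_b %in% groups[[i]], , drop = FALSE]
      class(sub) <- class(pairs)
      attr(sub, "markers") <- groups[[i]]
      bg <- build_groups(sub, thr)
      pieces <- c(pieces, unname(bg$groups), as.list(bg$unlinked))
    }
    groups <- pieces
    history <- rbind(history, data.frame(lod = thr, n_groups = length(groups)))
  }
  bad <- vapply(groups, test, logical(1), pairs = pairs)
  structure(list(groups = groups, persistent = bad, history = history),
            class = "rh_refined")
}
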