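#' Consecutive shared-microsatellite pairs with RH and genetic distances
#'
#' Within each (RH group, linkage group) combination, microsatellites present
#' in both maps are taken in RH (cR) order; each consecutive pair contributes
#' its absolute cR and cM differences.  Pairs with zero cM separation are
#' excluded (they carry no calibration information).
#'
#' @param maps list of `rh_map` objects.
#' @param gmap genetic map data frame (`lg`, `marker`, `cm`).
#' @return data frame `group`, `lg`, `marker_a`, `marker_b`, `d_cr`, `d_cm`.
#' @examples
#' mp <- structure(list(group = "RH1", markers = c("MS1", "MS2", "MS3"),
#'                      cr = c(0, 50, 120)), class = "rh_map")
#' gmap <- data.frame(lg = "LG1", marker = c("MS1", "MS2", "MS3"),
#'                    cm = c(0, 2, 5))
#' shared_pairs(list(mp), gmap)
#' @export
shared_pairs <- function(maps, gmap) {
  stopifnot(is.list(maps), all(c("lg", "marker", "cm") %in% names(gmap)))
  rows <- list()
  for (mp in maps) {
    shared <- mp$markers[mp$markers %in% gmap$marker]
    if (length(shared) < 2L) next
    sub <- gmap[match(shared, gmap$marker), , drop = FALSE]
    for (lg in unique(sub$lg)) {
      mk <- shared[sub$lg == lg]
      if (length(mk) < 2L) next
      cr <- mp$cr[match(mk, mp$markers)]
      cm <- sub$cm[sub$lg == lg]
      d_cr <- abs(diff(cr)); d_cm <- abs(diff(cm))
      keep <- d_cm > 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = mp$group, lg = lg,
        marker_a = mk[-length(mk)][keep], marker_b = mk[-1][keep],
        d_cr = d_cr[keep], d_cm = d_cm[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warn_rhmap("no shared microsatellite pairs found")
    return(data.frame(group = character(), lg = character(),
                      marker_a = character(), marker_b = character(),
                      d_cr = numeric(), d_cm = numeric()))
  }
  do.call(rbind, rows)
}

#' Calibrate the cR-to-kb relation and estimate map coverage
#'
#' From shared pairs totalling `sum_cr` centirays and `sum_cm` centimorgans,
#' the chain is: `cR/cM = sum_cr / sum_cm`; `kb/cR = kb_per_cm / (cR/cM)`;
#' physical map size = `total_map_cr * kb/cR`; coverage = 100 * size /
#' genome size.  Reported ratios are rounded to 1 decimal, coverage to an
#' integer percent, and the physical size is computed from the rounded kb/cR
#' (the convention of published RH reports); the exact pre-rounding chain is
#' kept alongside.
#'
#' @param pairs a [shared_pairs()] table; alternatively pass `sum_cr` and
#'   `sum_cm` directly.
#' @param sum_cr,sum_cm total cR and cM over the calibration pairs.
#' @param kb_per_cm physical distance per cM (input constant).
#' @param total_map_cr summed length of all RH groups, in cR.
#' @param genome_size_kb genome size in kb.
#' @return list of class `rh_calibration`: `n_pairs`, `sum_cr`, `sum_cm`,
#'   `cr_per_cm`, `kb_per_cr`, `map_size_kb`, `coverage_percent` (reported,
#'   rounded) and `raw` (exact chain).
#' @examples
#' calibrate(sum_cr = 18446, sum_cm = 604, kb_per_cm = 840,
#'           total_map_cr = 34084, genome_size_kb = 1060000)
#' @export
calibrate <- function(pairs = NULL, sum_cr = NULL, sum_cm = NULL,
                      kb_per_cm = 840, total_map_cr, genome_size_kb) {
  n_pairs <- NA_integer_
  if (!is.null(pairs)) {
    stopifnot(all(c("d_cr", "d_cm") %in% names(pairs)))
    sum_cr <- sum(pairs$d_cr); sum_cm <- sum(pairs$d_cm)
    n_pairs <- nrow(pairs)
  }
  if (is.null(sum_cr) || is.null(sum_cm))
    stop_rhmap("provide either pairs or sum_cr and sum_cm")
  if (sum_cm <= 0 || kb_per_cm <= 0 || genome_size_kb <= 0 ||
      total_map_cr <= 0)
    stop_rhmap("calibration inputs must be positive", "rhmap_zero_error")
  cr_per_cm_raw <- sum_cr / sum_cm
  kb_per_cr_raw <- kb_per_cm / cr_per_cm_raw
  kb_per_cr <- round(kb_per_cr_raw, 1)
  map_size_kb <- total_map_cr * kb_per_cr
  structure(list(
    n_pairs = n_pairs, sum_cr = sum_cr, sum_cm = sum_cm,
    kb_per_cm = kb_per_cm, total_map_cr = total_map_cr,
    genome_size_kb = genome_size_kb,
    cr_per_cm = round(cr_per_cm_raw, 1),
    kb_per_cr = kb_per_cr,
    map_size_kb = map_size_kb,
    coverage_percent = round(100 * map_size_kb / genome_size_kb),
    raw = list(cr_per_cm = cr_per_cm_raw, kb_per_cr = kb_per_cr_raw,
               map_size_kb = total_map_cr * kb_per_cr_raw,
               coverage_percent = 100 * total_map_cr * kb_per_cr_raw /
                 genome_size_kb)),
    class = "rh_calibration")
}

#' @export
print.rh_calibration <- function(x, ...) {
  cat(sprintf("Calibration over %s pairs: %.1f cR/cM, %.1f kb/cR\n",
              ifelse(is.na(x$n_pairs), "?", x$n_pairs), x$cr_per_cm,
              x$kb_per_cr))
  cat(sprintf("Map: %s cR -> %s kb (%d%% of %s kb genome)\n",
              format(x$total_map_cr, big.mark = ","),
              format(x$map_size_kb, big.mark = ","), x$coverage_percent,
              format(x$genome_size_kb, big.mark = ",")))
  invisible(x)
}

#' Whole-map summary statistics
#'
#' Density and spacing statistics follow the conventions of published RH
#' reports: marker density uses the full genotyped set over the genome size;
#' average inter-marker spacing divides total map length by the number of map
#' positions (co-localized markers share one position); both are reported
#' rounded (density to 2 decimals, kb/marker and cR spacing to integers).
#'
#' @param maps optional list of `rh_map` objects (ideally after
#'   [colocalize()]); used to derive mapped counts, positions and total cR.
#' @param genotyped_total number of genotyped markers.
#' @param genome_size_kb genome size in kb.
#' @param n_mapped,n_unlinked,total_cr,n_positions explicit overrides when
#'   summarizing published counts instead of map objects.
#' @return list of class `rh_map_stats`: `n_genotyped`, `n_mapped`,
#'   `n_unlinked`, `n_groups`, `n_positions`, `total_cr`,
#'   `density_per_mb`, `kb_per_marker`, `mean_spacing_cr`, `mapped_fraction`.
#' @examples
#' map_stats(genotyped_total = 1358, genome_size_kb = 1060000,
#'           n_mapped = 1296, n_unlinked = 62, total_cr = 34084,
#'           n_positions = 1255)
#' @export
map_stats <- function(maps = NULL, genotyped_total, genome_size_kb,
                      n_mapped = NULL, n_unlinked = NULL, total_cr = NULL,
                      n_positions = NULL) {
  n_groups <- NA_integer_
  if (!is.null(maps)) {
    n_groups <- length(maps)
    n_mapped <- n_mapped %||% sum(vapply(maps, function(m)
      length(m$markers), integer(1)))
    total_cr <- total_cr %||% sum(vapply(maps, `[[`, numeric(1), "length_cr"))
    n_positions <- n_positions %||% sum(vapply(maps, function(m)
      if (!is.null(m$positions)) nrow(m$positions) else length(m$markers),
      integer(1)))
  }
  if (is.null(n_mapped) || is.null(total_cr) || is.null(n_positions))
    stop_rhmap("provide maps or explicit n_mapped/total_cr/n_positions")
  n_unlinked <- n_unlinked %||% (genotyped_total - n_mapped)
  if (n_mapped + n_unlinked != genotyped_total)
    stop_rhmap("mapped + unlinked must equal the genotyped total")
  structure(list(
    n_genotyped = genotyped_total, n_mapped = n_mapped,
    n_unlinked = n_unlinked, n_groups = n_groups,
    n_positions = n_positions, total_cr = total_cr,
    density_per_mb = round(genotyped_total / (genome_size_kb / 1000), 2),
    kb_per_marker = floor(genome_size_kb / genotyped_total),
    mean_spacing_cr = round(total_cr / n_positions),
    mapped_fraction = n_mapped / genotyped_total),
    class = "rh_map_stats")
}

#' @export
print.rh_map_stats <- function(x, ...) {
  cat(sprintf(
    "%d markers (%d mapped, %d unlinked), %s positions over %s cR\n",
    x$n_genotyped, x$n_mapped, x$n_unlinked,
    format(x$n_positions, big.mark = ","),
    format(x$total_cr, big.mark = ",")))
  cat(sprintf(
    "density %.2f markers/Mb (1 per %d kb), mean spacing %d cR\n",
    x$density_per_mb, x$kb_per_marker, x$mean_spacing_cr))
  invisible(x)
}
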