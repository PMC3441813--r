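#' Construct and validate a clone-by-marker RH call matrix
#'
#' Calls are coded `0` (absent), `1` (present) and `2` (ambiguous).  Rows are
#' clones, columns are markers; both must be named.
#'
#' @param x integer matrix of calls.
#' @return the validated matrix with class `rh_calls`.
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 1L), 2, 2,
#'             dimnames = list(c("H1", "H2"), c("A", "B")))
#' rh_call_matrix(m)
#' @export
rh_call_matrix <- function(x) {
  if (!is.matrix(x)) stop_rhmap("calls must be a matrix", "rhmap_call_error")
  storage.mode(x) <- "integer"
  if (any(is.na(x)) || !all(x %in% 0:2))
    stop_rhmap("calls must all be in {0, 1, 2}", "rhmap_call_error")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_rhmap("calls need clone rownames and marker colnames",
               "rhmap_call_error")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop_rhmap("clone and marker ids must be unique", "rhmap_call_error")
  structure(x, class = c("rh_calls", "matrix", "array"))
}

#' @export
`[.rh_calls` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("rh_calls", "matrix", "array")
  out
}

#' @export
print.rh_calls <- function(x, ...) {
  cat(sprintf("RH call matrix: %d clones x %d markers (%.1f%% present, %.1f%% ambiguous)\n",
              nrow(x), ncol(x), 100 * mean(x == 1L), 100 * mean(x == 2L)))
  invisible(x)
}

#' Score fluorescence intensities into presence/absence/ambiguous calls
#'
#' Each marker is read on one fluorescence axis; a clone is called present when
#' its value exceeds `threshold + ambiguous_halfwidth`, absent below
#' `threshold - ambiguous_halfwidth`, and ambiguous inside the band.  Axis and
#' threshold can be overridden per marker, mirroring practice where the cutoff
#' is adjusted to the dot distribution of each typing profile.
#'
#' @param records data frame with columns `marker`, `clone`, `x`, `y`
#'   (normalized fluorescence, non-negative).
#' @param threshold default cutoff on the scoring axis.
#' @param ambiguous_halfwidth half-width of the ambiguity band around the
#'   threshold.
#' @param axis default scoring axis, `"y"` or `"x"`.
#' @param overrides optional data frame `marker`, `axis`, `threshold` of
#'   per-marker settings.
#' @return an [rh_call_matrix()]; missing (marker, clone) pairs are scored
#'   ambiguous with a warning.
#' @examples
#' rec <- data.frame(marker = "M1", clone = c("H1", "H2"),
#'                   x = 0, y = c(0.55, 0.10))
#' score_intensities(rec)
#' @export
score_intensities <- function(records, threshold = 0.3,
                              ambiguous_halfwidth = 0.05,
                              axis = c("y", "x"), overrides = NULL) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(records),
            all(c("marker", "clone", "x", "y") %in% names(records)))
  if (threshold <= 0) stop_rhmap("threshold must be positive")
  if (any(records$x < 0) || any(records$y < 0))
    stop_rhmap("intensities must be non-negative")
  markers <- unique(records$marker)
  clones <- unique(records$clone)
  ax <- setNames(rep(axis, length(markers)), markers)
  th <- setNames(rep(threshold, length(markers)), markers)
  if (!is.null(overrides)) {
    stopifnot(all(c("marker", "axis", "threshold") %in% names(overrides)))
    hit <- overrides$marker %in% markers
    ax[overrides$marker[hit]] <- overrides$axis[hit]
    th[overrides$marker[hit]] <- overrides$threshold[hit]
  }
  calls <- matrix(2L, length(clones), length(markers),
                  dimnames = list(clones, markers))
  val <- ifelse(ax[records$marker] == "y", records$y, records$x)
  tm <- th[records$marker]
  if (ambiguous_halfwidth > 0) {
    call <- ifelse(val > tm + ambiguous_halfwidth, 1L,
                   ifelse(val < tm - ambiguous_halfwidth, 0L, 2L))
  } else {
    # no ambiguity band: above the threshold is present, otherwise absent
    call <- ifelse(val > tm, 1L, 0L)
  }
  idx <- cbind(match(records$clone, clones), match(records$marker, markers))
  if (anyDuplicated(idx))
    stop_rhmap("duplicate (marker, clone) intensity records")
  calls[idx] <- call
  n_missing <- length(calls) - nrow(records)
  if (n_missing > 0)
    warn_rhmap(sprintf(
      "%d (marker, clone) pairs had no intensity record; scored ambiguous",
      n_missing))
  rh_call_matrix(calls)
}

#' Retention frequency per clone
#'
#' The retention frequency of a clone is the fraction of its informative
#' (non-ambiguous) calls that are present: `presents / (presents + absents)`.
#' Ambiguous calls are excluded from numerator and denominator.
#'
#' @param calls an [rh_call_matrix()].
#' @param clone optional single clone id; default computes all clones.
#' @return data frame with columns `clone`, `retention`, `n_informative`,
#'   `n_present`.
#' @examples
#' m <- rh_call_matrix(matrix(c(1L, 0L, 0L, 2L), 1, 4,
#'        dimnames = list("H1", paste0("M", 1:4))))
#' retention_frequency(m)
#' @export
retention_frequency <- function(calls, clone = NULL) {
  stopifnot(inherits(calls, "rh_calls"))
  if (!is.null(clone)) {
    if (!clone %in% rownames(calls)) stop_rhmap("unknown clone id")
    calls <- calls[clone, , drop = FALSE]
  }
  pres <- rowSums(calls == 1L)
  info <- pres + rowSums(calls == 0L)
  if (any(info == 0))
    stop_rhmap(sprintf("clone(s) %s have no informative calls",
                       paste(rownames(calls)[info == 0], collapse = ", ")),
               "rhmap_retention_error")
  data.frame(clone = rownames(calls), retention = pres / info,
             n_informative = as.integer(info), n_present = as.integer(pres),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select panel clones by retention band with genome-representation rescue
#'
#' Keeps clones whose retention frequency lies in
#' `[min_retention, max_retention]`, then adds back any excluded clone that is
#' the sole carrier of some marker, so no marker loses its only positive clone.
#'
#' @param stats output of [retention_frequency()] covering all clones.
#' @param calls the [rh_call_matrix()] the stats were computed from.
#' @param min_retention,max_retention retention band.
#' @return character vector of selected clone ids, in original matrix order.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 6,
#'                   n_clones = 12)
#' panel <- simulate_panel(simulate_genome(cfg), cfg)
#' st <- retention_frequency(panel$calls)
#' select_clones(st, panel$calls, 0.02, 0.5)
#' @export
select_clones <- function(stats, calls, min_retention = 0.05,
                          max_retention = 0.4) {
  stopifnot(inherits(calls, "rh_calls"),
            all(rownames(calls) %in% stats$clone))
  ret <- setNames(stats$retention, stats$clone)[rownames(calls)]
  keep <- ret >= min_retention & ret <= max_retention
  carriers <- colSums(calls == 1L)
  sole <- colnames(calls)[carriers == 1L]
  if (length(sole)) {
    for (mk in sole) {
      cl <- rownames(calls)[calls[, mk] == 1L]
      keep[cl] <- TRUE
    }
  }
  out <- rownames(calls)[keep]
  if (!length(out))
    stop_rhmap("no clones selected; relax the retention thresholds",
               "rhmap_selection_error")
  out
}

#' Flag markers whose calls do not separate into two intensity clusters
#'
#' For each marker, the scoring-axis values are split into two clusters
#' (1-D k-means initialized at the 25% and 75% quantiles, deterministic); a
#' marker is flagged when the cluster centers are closer than `min_separation`
#' times the pooled within-cluster spread, or when one cluster holds fewer
#' than `min_cluster` clones.  Flagged markers are typically excluded from
#' mapping -- in practice a sizeable fraction of assay markers fails this way.
#'
#' @inheritParams score_intensities
#' @param min_separation required ratio of center distance to pooled spread.
#'   Splitting one unimodal cluster in two yields ratios of about 2.7
#'   (Gaussian) to 5 (uniform), while genuinely separated presence/absence
#'   clouds sit near 8 or above, so the default of 6 flags anything not
#'   clearly bimodal.
#' @param min_cluster minimum clones per cluster.
#' @return data frame `marker`, `separation`, `n_low`, `n_high`, `flagged`.
#' @examples
#' rec <- data.frame(marker = "M1", clone = paste0("H", 1:6),
#'                   x = 0, y = c(0.05, 0.1, 0.08, 0.6, 0.7, 0.65))
#' flag_nonseparating(rec)
#' @export
flag_nonseparating <- function(records, axis = c("y", "x"),
                               min_separation = 6, min_cluster = 2L) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(records))
  v <- if (axis == "y") records$y else records$x
  out <- lapply(split(v, records$marker), function(x) {
    cen <- unname(stats::quantile(x, c(0.25, 0.75)))
    if (diff(cen) < 1e-12)
      return(data.frame(separation = 0, n_low = length(x), n_high = 0L,
                        flagged = TRUE))
    for (i in 1:25) {
      grp <- abs(x - cen[1]) > abs(x - cen[2])
      new <- c(mean(x[!grp]), mean(x[grp]))
      new[is.na(new)] <- cen[is.na(new)]
      if (isTRUE(all.equal(new, cen))) break
      cen <- new
    }
    grp <- abs(x - cen[1]) > abs(x - cen[2])
    spread <- sqrt(mean(c(x[!grp] - cen[1], x[grp] - cen[2])^2))
    sep <- if (spread < 1e-9) Inf else abs(diff(cen)) / spread
    data.frame(separation = sep, n_low = sum(!grp), n_high = sum(grp),
               flagged = sep < min_separation ||
                 min(sum(!grp), sum(grp)) < min_cluster)
  })
  res <- do.call(rbind, out)
  res$marker <- names(out)
  res[, c("marker", "separation", "n_low", "n_high", "flagged")]
}
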