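#' Multipoint retention model along an ordered set of markers
#'
#' @param markers ordered marker ids.
#' @param thetas adjacent breakage fractions, length `length(markers) - 1`,
#'   each in `[0, 1)`.
#' @param r fragment retention probability.
#' @param error_rate per-call flip probability of the emission model.
#' @return list of class `rh_mp_model`.
#' @examples
#' multipoint_model(c("A", "B"), 0.2, 0.117)
#' @export
multipoint_model <- function(markers, thetas, r, error_rate = 0) {
  if (length(thetas) != length(markers) - 1L)
    stop_rhmap("thetas must have length markers - 1")
  if (any(thetas < 0) || any(thetas >= 1))
    stop_rhmap("each theta must lie in [0, 1)")
  stopifnot(r > 0, r < 1, error_rate >= 0, error_rate < 0.5)
  structure(list(markers = markers, thetas = as.numeric(thetas), r = r,
                 error_rate = error_rate), class = "rh_mp_model")
}

#' Multipoint log-likelihood of a marker order
#'
#' Each clone is a realisation of a two-state (retained/lost) Markov chain
#' along the order: initial distribution `(r, 1 - r)`, transition governed by
#' the adjacent breakage fraction (`stay` with probability `1 - theta` plus a
#' re-draw from `(r, 1 - r)` with probability `theta`), emission equal to the
#' observed call with optional flip error.  Ambiguous calls contribute no
#' emission factor (they are marginalized).  Because the initial distribution
#' is stationary and the chain reversible, the likelihood is invariant under
#' order reversal.
#'
#' @param order marker ids, a subset of `colnames(calls)`.
#' @param calls an [rh_call_matrix()].
#' @param model an [multipoint_model()] consistent with `order`.
#' @return total log-likelihood over clones.
#' @examples
#' m <- rh_call_matrix(matrix(c(1L, 0L, 1L, 0L), 2, 2,
#'        dimnames = list(c("H1", "H2"), c("A", "B"))))
#' multipoint_loglik(c("A", "B"), m, multipoint_model(c("A", "B"), 0.3, 0.2))
#' @export
multipoint_loglik <- function(order, calls, model) {
  stopifnot(inherits(calls, "rh_calls"), inherits(model, "rh_mp_model"))
  if (!all(order %in% colnames(calls)))
    stop_rhmap("order contains markers absent from the call matrix")
  if (!identical(as.character(order), as.character(model$markers)))
    stop_rhmap("model markers do not match the order")
  sub <- calls[, order, drop = FALSE]
  if (length(order) == 1L) {
    r <- model$r; e <- model$error_rate
    p1 <- r * (1 - e) + (1 - r) * e
    v <- sub[, 1]
    return(sum(log(ifelse(v == 1L, p1, ifelse(v == 0L, 1 - p1, 1)))))
  }
  .mp_loglik_cpp(unclass(sub), model$thetas, model$r, model$error_rate)
}

# moment initialization of adjacent thetas from pairwise discordance
init_thetas <- function(sub, r) {
  m <- ncol(sub)
  vapply(seq_len(m - 1L), function(k) {
    a <- sub[, k]; b <- sub[, k + 1L]
    info <- a != 2L & b != 2L
    N <- sum(info)
    if (N == 0) return(0.3)
    disc <- sum(a[info] != b[info])
    min(max(disc / (2 * N * r * (1 - r)), 1e-4), 0.95)
  }, numeric(1))
}

#' Fit adjacent breakage fractions for a fixed marker order
#'
#' The retention `r` is estimated as the overall presence fraction among
#' informative calls; each adjacent theta is then maximized by bounded 1-D
#' optimization of the full multipoint likelihood, sweeping the adjacencies in
#' coordinate-ascent fashion (at least two sweeps, until the log-likelihood
#' gain falls below `tol`).
#'
#' @inheritParams multipoint_loglik
#' @param error_rate per-call flip probability (0 for pre-cleaned vectors).
#' @param r optional fixed retention; default estimates it from the calls.
#' @param tol log-likelihood convergence tolerance between sweeps.
#' @param xtol absolute tolerance on each theta.
#' @param max_sweeps sweep budget; non-convergence warns and returns the last
#'   iterate.
#' @return an [multipoint_model()] with attributes `loglik` and `converged`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 4,
#'                   false_positive_rate = 0, false_negative_rate = 0,
#'                   ambiguous_rate = 0)
#' panel <- simulate_panel(simulate_genome(cfg), cfg)
#' fit_adjacent_thetas(colnames(panel$calls), panel$calls)
#' @export
fit_adjacent_thetas <- function(order, calls, error_rate = 0, r = NULL,
                                tol = 1e-6, xtol = 1e-6, max_sweeps = 60L) {
  stopifnot(inherits(calls, "rh_calls"), length(order) >= 2L,
            all(order %in% colnames(calls)))
  sub <- unclass(calls[, order, drop = FALSE])
  if (is.null(r)) {
    n1 <- sum(sub == 1L); n0 <- sum(sub == 0L)
    if (n1 + n0 == 0) stop_rhmap("no informative calls")
    r <- min(max(n1 / (n1 + n0), 1e-4), 1 - 1e-4)
  }
  fit <- .mp_fit_thetas_cpp(sub, r, error_rate, init_thetas(sub, r),
                            tol, xtol, 2L, as.integer(max_sweeps))
  if (!fit$converged)
    warn_rhmap(sprintf("theta fit did not converge in %d sweeps", fit$sweeps))
  model <- multipoint_model(order, fit$thetas, r, error_rate)
  attr(model, "loglik") <- fit$loglik
  attr(model, "converged") <- fit$converged
  model
}

# fast objective used during order search: refit thetas, return loglik
order_objective <- function(sub, r, error_rate, ord_idx, xtol) {
  f <- .mp_fit_thetas_cpp(sub[, ord_idx, drop = FALSE], r, error_rate,
                          init_thetas(sub[, ord_idx, drop = FALSE], r),
                          1e-4, xtol, 2L, 30L)
  f$loglik
}

canonical_orientation <- function(markers) {
  if (markers[length(markers)] < markers[1]) rev(markers) else markers
}

#' Search the maximum-likelihood marker order of an RH group
#'
#' The objective is the multipoint log-likelihood with refit adjacent thetas.
#' Construction is greedy best-insertion seeded from the highest-LOD pair;
#' each restart perturbs the seed pair and insertion sequence.  Improvement
#' combines 2-opt segment reversal with a sliding-window ripple (window 4,
#' all permutations) to a local optimum; the best restart wins and the order
#' is reported in canonical orientation (lexicographically smaller end marker
#' first).
#'
#' @param markers marker ids of the group (>= 2).
#' @param calls an [rh_call_matrix()].
#' @param seed integer seed controlling restarts.
#' @param n_restarts number of seeded restarts.
#' @param error_rate per-call flip probability passed to the model.
#' @param pairs optional [all_pairs()] table used for seeding; computed on the
#'   group's submatrix when absent.
#' @param max_distance cap on adjacent cR distances.
#' @param group id stored in the resulting map.
#' @return list of class `rh_map`: `group`, `markers` (ordered), `cr`
#'   (cumulative cR from 0, reported to 0.1), `length_cr`, `thetas`, `r`,
#'   `loglik`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 5,
#'                   false_positive_rate = 0, false_negative_rate = 0,
#'                   ambiguous_rate = 0)
#' panel <- simulate_panel(simulate_genome(cfg), cfg)
#' search_order(colnames(panel$calls), panel$calls, seed = 1, n_restarts = 2)
#' @export
search_order <- function(markers, calls, seed = 1L, n_restarts = 10L,
                         error_rate = 0, pairs = NULL, max_distance = 300,
                         group = "RH1") {
  stopifnot(inherits(calls, "rh_calls"), length(markers) >= 2L,
            all(markers %in% colnames(calls)))
  m <- length(markers)
  sub <- unclass(calls[, markers, drop = FALSE])
  n1 <- sum(sub == 1L); n0 <- sum(sub == 0L)
  r <- min(max(n1 / (n1 + n0), 1e-4), 1 - 1e-4)
  if (m == 2L) {
    model <- fit_adjacent_thetas(canonical_orientation(markers), calls,
                                 error_rate, r = r)
    return(new_rh_map(group, model, max_distance))
  }
  lodm <- matrix(0, m, m, dimnames = list(markers, markers))
  if (is.null(pairs)) {
    pr <- suppressWarnings(all_pairs(calls[, markers, drop = FALSE],
                                     min_informative = 1L))
  } else pr <- pairs
  pr <- pr[pr$marker_a %in% markers & pr$marker_b %in% markers & pr$usable, ]
  lodm[cbind(pr$marker_a, pr$marker_b)] <- pr$lod
  lodm[cbind(pr$marker_b, pr$marker_a)] <- pr$lod
  obj <- function(idx) order_objective(sub, r, error_rate, idx, 1e-3)
  best_idx <- NULL; best_ll <- -Inf
  for (restart in seq_len(n_restarts)) {
    set.seed(seed + restart - 1L)
    if (restart == 1L && any(lodm > 0)) {
      sd_pair <- which(lodm == max(lodm), arr.ind = TRUE)[1, ]
    } else {
      sd_pair <- sample.int(m, 2)
    }
    placed <- as.integer(sd_pair)
    rest <- setdiff(seq_len(m), placed)
    if (restart > 1L) rest <- sample(rest)
    else if (length(rest) > 1L) {
      link <- vapply(rest, function(i) max(lodm[i, placed]), numeric(1))
      rest <- rest[order(-link)]
    }
    for (nxt in rest) {
      cand_ll <- -Inf; cand <- NULL
      for (pos in 0:length(placed)) {
        trial <- append(placed, nxt, after = pos)
        ll <- obj(trial)
        if (ll > cand_ll) { cand_ll <- ll; cand <- trial }
      }
      placed <- cand
    }
    cur <- placed; cur_ll <- obj(cur)
    repeat {
      improved <- FALSE
      for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
        trial <- cur; trial[i:j] <- rev(trial[i:j])
        ll <- obj(trial)
        if (ll > cur_ll + 1e-9) { cur <- trial; cur_ll <- ll; improved <- TRUE }
      }
      w <- 4L
      if (m > w) {
        perms <- permutations_of(w)
        for (s in seq_len(m - w + 1L)) {
          win <- seq(s, s + w - 1L)
          for (p in perms) {
            trial <- cur; trial[win] <- cur[win][p]
            if (identical(trial, cur)) next
            ll <- obj(trial)
            if (ll > cur_ll + 1e-9) { cur <- trial; cur_ll <- ll; improved <- TRUE }
          }
        }
      }
      if (!improved) break
    }
    if (cur_ll > best_ll + 1e-9) { best_ll <- cur_ll; best_idx <- cur }
  }
  ord <- canonical_orientation(markers[best_idx])
  model <- fit_adjacent_thetas(ord, calls, error_rate, r = r)
  new_rh_map(group, model, max_distance)
}

new_rh_map <- function(group, model, max_distance = 300) {
  d <- theta_to_cr(model$thetas, max_distance)
  cr <- round(cumsum(c(0, d)), 1)
  structure(list(group = group, markers = model$markers, cr = cr,
                 length_cr = cr[length(cr)], thetas = model$thetas,
                 r = model$r, loglik = attr(model, "loglik")),
            class = "rh_map")
}

#' @export
print.rh_map <- function(x, ...) {
  cat(sprintf("RH group %s: %d markers, %.1f cR (loglik %.2f)\n",
              x$group, length(x$markers), x$length_cr, x$loglik %||% NA_real_))
  invisible(x)
}

# all permutations of 1..n (small n), in lexicographic order
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(n)[-i])[p])
    }
  }
  out
}

#' Merge co-localized markers into shared map positions
#'
#' Adjacent markers whose calls agree on every clone informative for both (or
#' whose fitted adjacent theta is at or below `tol`) cannot be resolved by the
#' panel and are merged into one map position.
#'
#' @param map an `rh_map` from [search_order()].
#' @param calls the [rh_call_matrix()] the map was built from.
#' @param tol breakage-fraction tolerance below which adjacent markers are
#'   considered co-localized (0 keeps the identical-calls rule only).
#' @return `map` with a `positions` data frame added: `position`, `cr`,
#'   `n_markers`, `markers` (comma-joined).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 4,
#'                   false_positive_rate = 0, false_negative_rate = 0,
#'                   ambiguous_rate = 0)
#' panel <- simulate_panel(simulate_genome(cfg), cfg)
#' mp <- search_order(colnames(panel$calls), panel$calls, n_restarts = 2)
#' colocalize(mp, panel$calls)$positions
#' @export
colocalize <- function(map, calls, tol = 0) {
  stopifnot(inherits(map, "rh_map"), inherits(calls, "rh_calls"))
  mk <- map$markers
  pos_id <- integer(length(mk)); pos_id[1] <- 1L
  if (length(mk) > 1) {
    for (k in seq(2L, length(mk))) {
      a <- calls[, mk[k - 1L]]; b <- calls[, mk[k]]
      info <- a != 2L & b != 2L
      same <- sum(info) > 0 && all(a[info] == b[info])
      near <- map$thetas[k - 1L] <= tol
      pos_id[k] <- if (same || near) pos_id[k - 1L] else pos_id[k - 1L] + 1L
    }
  }
  cr <- vapply(split(map$cr, pos_id), `[`, numeric(1), 1L)
  members <- split(mk, pos_id)
  map$positions <- data.frame(
    position = seq_along(members),
    cr = unname(cr),
    n_markers = lengths(members),
    markers = vapply(members, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  map
}
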