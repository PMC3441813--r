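#' Linked-model log-likelihood of a two-point count table
#'
#' Haploid equal-retention breakage model.  With breakage fraction `theta` and
#' retention `r`, the cell probabilities for the presence pattern of a marker
#' pair are `P(1,1) = r(1-theta) + r^2 theta`, `P(1,0) = P(0,1) =
#' r theta (1-r)` and `P(0,0) = (1-theta)(1-r) + theta (1-r)^2`.
#'
#' @param theta breakage fraction in `[0, 1]`.
#' @param r retention probability in `(0, 1)`.
#' @param n11,n10,n01,n00 clone counts for each joint presence pattern.
#' @return the multinomial log-likelihood.
#' @examples
#' tp_loglik(0.3, 0.117, 10, 4, 5, 150)
#' @export
tp_loglik <- function(theta, r, n11, n10, n01, n00) {
  p11 <- r * (1 - theta) + r^2 * theta
  p10 <- r * theta * (1 - r)
  p00 <- (1 - theta) * (1 - r) + theta * (1 - r)^2
  n11 * log(pmax(p11, 1e-300)) + (n10 + n01) * log(pmax(p10, 1e-300)) +
    n00 * log(pmax(p00, 1e-300))
}

tp_unlinked_loglik <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  ra <- (n11 + n10) / N
  rb <- (n11 + n01) / N
  xlx <- function(n, p) if (n == 0) 0 else n * log(p)
  xlx(n11, ra * rb) + xlx(n10, ra * (1 - rb)) +
    xlx(n01, (1 - ra) * rb) + xlx(n00, (1 - ra) * (1 - rb))
}

# bounded multi-start ML fit of (theta, r) from a two-point count table
tp_mle <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  r0 <- min(max((2 * n11 + n10 + n01) / (2 * N), 1e-4), 1 - 1e-4)
  t0 <- min(1 - 1e-4, (n10 + n01) / (2 * N * r0 * (1 - r0)))
  nll <- function(p) -tp_loglik(p[1], p[2], n11, n10, n01, n00)
  starts <- list(c(t0, r0), c(0.3, r0), c(0.7, r0), c(max(t0, 1e-3), 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(0, 1e-6), upper = c(1 - 1e-6, 1 - 1e-6),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  list(theta = best$par[1], retention = best$par[2], loglik = -best$value)
}

#' Two-point breakage/retention estimate for a marker pair
#'
#' Counts the joint presence patterns over clones informative (calls 0/1) at
#' both markers, maximizes the linked-model likelihood ([tp_loglik()]) by
#' bounded optimization, and reports the base-10 LOD against an unlinked model
#' in which each marker retains with its own marginal frequency.
#'
#' @param a,b per-clone call vectors in `{0, 1, 2}` (2 = ambiguous; such
#'   clones are dropped for this pair only).
#' @param max_distance cap on the reported cR distance.
#' @return list of class `rh_twopoint`: `theta`, `retention`, `lod`,
#'   `n_informative`, `distance` (cR, `-100 log(1 - theta)` capped).
#' @examples
#' a <- c(1, 1, 0, 0, 1, 0, 0, 0)
#' b <- c(1, 0, 0, 0, 1, 0, 0, 1)
#' estimate_two_point(a, b)
#' @export
estimate_two_point <- function(a, b, max_distance = 300) {
  if (length(a) != length(b)) stop_rhmap("call vectors differ in length")
  info <- a %in% 0:1 & b %in% 0:1
  N <- sum(info)
  if (N == 0)
    stop_rhmap("no clone is informative at both markers", "rhmap_nodata_error")
  a <- a[info]; b <- b[info]
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    stop_rhmap("a marker is constant across informative clones",
               "rhmap_uninformative_error")
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  fit <- tp_mle(n11, n10, n01, n00)
  lod <- (fit$loglik - tp_unlinked_loglik(n11, n10, n01, n00)) / log(10)
  structure(list(theta = fit$theta, retention = fit$retention, lod = lod,
                 n_informative = N,
                 distance = theta_to_cr(fit$theta, max_distance),
                 counts = c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)),
            class = "rh_twopoint")
}

#' Exhaustive lattice search for the two-point maximum likelihood
#'
#' Brute-force reference estimator: evaluates the linked log-likelihood on a
#' full `(theta, r)` lattice (`theta` in `{0, step, ..., 1}`, `r` in
#' `{step, ..., 1 - step}`) and returns the best lattice point.  Used to
#' validate the bounded-optimization estimator; shares no code with it.
#'
#' @param n11,n10,n01,n00 count table.
#' @param step lattice resolution.
#' @return list `theta`, `retention`, `loglik`.
#' @examples
#' tp_grid_search(30, 5, 5, 150, step = 0.01)
#' @export
tp_grid_search <- function(n11, n10, n01, n00, step = 1e-3) {
  res <- .tp_grid_search_cpp(cbind(n11, n10 + n01, n00), step)
  list(theta = res[1, 1], retention = res[1, 2], loglik = res[1, 3])
}

tp_grid_search_batch <- function(tables, step = 1e-3) {
  .tp_grid_search_cpp(tables, step)
}

#' Two-point estimates for every marker pair of a call matrix
#'
#' @param calls an [rh_call_matrix()].
#' @param min_informative minimum clones informative at both markers for the
#'   pair to be usable as a linkage edge.
#' @param max_distance cap on reported cR distances.
#' @return data frame of class `rh_pair_table`: one row per unordered pair
#'   with `marker_a`, `marker_b`, `theta`, `retention`, `lod`, `n`,
#'   `distance`, `usable`.  Pairs below the informative floor or involving a
#'   constant/all-ambiguous marker carry `usable = FALSE` and NA estimates.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 4,
#'                   n_clones = 50, false_positive_rate = 0,
#'                   false_negative_rate = 0, ambiguous_rate = 0)
#' tp <- all_pairs(simulate_panel(simulate_genome(cfg), cfg)$calls)
#' @export
all_pairs <- function(calls, min_informative = 25, max_distance = 300) {
  stopifnot(inherits(calls, "rh_calls"))
  m <- ncol(calls)
  if (m < 2) stop_rhmap("need at least two markers")
  P <- (calls == 1L) + 0
  Z <- (calls == 0L) + 0
  N11 <- crossprod(P); N10 <- crossprod(P, Z); N00 <- crossprod(Z)
  pairs <- which(upper.tri(N11), arr.ind = TRUE)
  n11 <- N11[pairs]; n10 <- N10[pairs]
  n01 <- t(N10)[pairs]; n00 <- N00[pairs]
  N <- n11 + n10 + n01 + n00
  ra_num <- n11 + n10; rb_num <- n11 + n01
  usable <- N >= min_informative & ra_num > 0 & ra_num < N &
    rb_num > 0 & rb_num < N
  theta <- retention <- lod <- dist <- rep(NA_real_, length(N))
  for (k in which(usable)) {
    fit <- tp_mle(n11[k], n10[k], n01[k], n00[k])
    theta[k] <- fit$theta
    retention[k] <- fit$retention
    lod[k] <- (fit$loglik -
                 tp_unlinked_loglik(n11[k], n10[k], n01[k], n00[k])) / log(10)
    dist[k] <- theta_to_cr(fit$theta, max_distance)
  }
  out <- data.frame(marker_a = colnames(calls)[pairs[, 1]],
                    marker_b = colnames(calls)[pairs[, 2]],
                    theta = theta, retention = retention, lod = lod,
                    n = as.integer(N), distance = dist, usable = usable,
                    stringsAsFactors = FALSE)
  structure(out, class = c("rh_pair_table", "data.frame"),
            markers = colnames(calls), min_informative = min_informative)
}
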