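# shared fixtures: everything is generated in code, no data files

# a clean (noise-free) panel configuration with gaps bounded inside the
# linkable range: even spacing with jitter keeps every adjacent gap
# within roughly [0.2, 1.8] * mean gap
clean_config <- function(n_chromosomes = 2, markers_per_chromosome = 10,
                         mean_gap_cr = 30, seed = 1, jitter = 0.4,
                         ambiguous_rate = 0, ...) {
  gap_kb <- mean_gap_cr * 27.5
  sim_config(n_chromosomes = n_chromosomes,
             markers_per_chromosome = markers_per_chromosome,
             chromosome_length_kb = (markers_per_chromosome + 1) * gap_kb,
             false_positive_rate = 0, false_negative_rate = 0,
             ambiguous_rate = ambiguous_rate, spacing = "even",
             spacing_jitter = jitter, seed = seed, ...)
}

# wrap a plain data frame as an all_pairs()-style table
make_pair_table <- function(df, markers = NULL) {
  df$usable <- df$usable %||% rep(TRUE, nrow(df))
  df$n <- df$n %||% rep(100L, nrow(df))
  df$retention <- df$retention %||% rep(0.117, nrow(df))
  df$distance <- df$distance %||% theta_to_cr(df$theta)
  structure(df, class = c("rh_pair_table", "data.frame"),
            markers = markers %||% unique(c(df$marker_a, df$marker_b)),
            min_informative = 25)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# build an rh_map directly from fitted thetas on a fixed order
map_from_order <- function(group, order, calls, ...) {
  model <- fit_adjacent_thetas(order, calls, ...)
  rhmap:::new_rh_map(group, model)
}

# brute-force LCS by subsequence enumeration (oracle for compare_orders)
brute_lcs <- function(a, b) {
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    sub <- a[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
    if (length(sub) <= best) next
    # is sub a subsequence of b?
    j <- 1L; ok <- TRUE
    for (x in sub) {
      while (j <= length(b) && b[j] != x) j <- j + 1L
      if (j > length(b)) { ok <- FALSE; break }
      j <- j + 1L
    }
    if (ok) best <- length(sub)
  }
  best
}

# exhaustive order search oracle: best multipoint log-likelihood over all
# permutations (up to reversal) of a small marker set
exhaustive_best_loglik <- function(markers, calls, r = NULL) {
  perms <- rhmap:::permutations_of(length(markers))
  best <- -Inf
  for (p in perms) {
    if (p[1] > p[length(p)]) next  # skip reversals
    ord <- markers[p]
    f <- fit_adjacent_thetas(ord, calls, r = r)
    if (attr(f, "loglik") > best) best <- attr(f, "loglik")
  }
  best
}
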