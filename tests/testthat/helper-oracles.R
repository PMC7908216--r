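# Independent brute-force oracles used to check the fast implementations.
# These re-derive each quantity by exhaustive scanning, not by calling the
# package internals.

# Exhaustive scan for the most negative interior local minimum with two-sided
# prominence >= min_prom. Assumes no exact ties among values (random traces).
oracle_shortening_peak <- function(times, values, t0, t1, min_prom) {
  idx <- which(times >= t0 & times <= t1)
  t <- times[idx]; v <- values[idx]
  n <- length(v)
  best <- NULL
  for (i in 2:(n - 1)) {
    if (v[i] < v[i - 1] && v[i] < v[i + 1]) {
      lmax <- -Inf
      for (j in (i - 1):1) {
        if (v[j] < v[i]) break
        lmax <- max(lmax, v[j])
      }
      rmax <- -Inf
      for (j in (i + 1):n) {
        if (v[j] < v[i]) break
        rmax <- max(rmax, v[j])
      }
      prom <- min(lmax - v[i], rmax - v[i])
      if (prom >= min_prom) {
        if (is.null(best) || v[i] < best$value) {
          best <- list(time = t[i], value = v[i], prominence = prom)
        }
      }
    }
  }
  best
}

oracle_argmin_time <- function(times, values, t0, t1) {
  best_t <- NA_real_; best_v <- Inf
  for (i in seq_along(times)) {
    if (times[i] >= t0 && times[i] <= t1 && values[i] < best_v) {
      best_v <- values[i]; best_t <- times[i]
    }
  }
  best_t
}

oracle_argmax_time <- function(times, values, t0, t1) {
  best_t <- NA_real_; best_v <- -Inf
  for (i in seq_along(times)) {
    if (times[i] >= t0 && times[i] <= t1 && values[i] > best_v) {
      best_v <- values[i]; best_t <- times[i]
    }
  }
  best_t
}

# Probability that a random positive outscores a random negative, ties 1/2:
# the all-pairs concordance definition of the AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive-pair recomputation of the time-to-peak velocity panel from the
# measured per-segment peak times and their view/wall/level labels.
oracle_panel <- function(ttp, view, wall, level) {
  n <- length(ttp)
  mtd <- 0
  for (i in 1:n) for (j in 1:n) mtd <- max(mtd, ttp[i] - ttp[j])
  vmax <- sapply(unique(view), function(v) {
    x <- ttp[view == v]
    m <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) m <- max(m, x[i] - x[j])
    m
  })
  opp <- 0
  for (i in 1:n) for (j in 1:n) {
    if (view[i] == view[j] && level[i] == level[j] && wall[i] != wall[j]) {
      opp <- max(opp, abs(ttp[i] - ttp[j]))
    }
  }
  mu <- sum(ttp) / n
  yu <- sqrt(sum((ttp - mu)^2) / (n - 1))
  list(view_max_delay = vmax, max_time_delay = mtd,
       opposing_wall_delay = opp, yu_index = yu)
}

# A wiggly random strain trace on a regular grid (no exact value ties,
# almost surely).
random_strain_trace <- function(n = 80, dt = 5, view = "4CH",
                                wall = "septal", level = "mid") {
  t <- seq(0, by = dt, length.out = n)
  v <- cumsum(rnorm(n, 0, 1.2)) - 8 * sin(seq(0, 3, length.out = n))
  strain_trace(t, v, view, wall, level)
}

random_bits <- function() {
  b <- rbinom(4, 1, 0.5)
  if (b[3] == 1 && b[1] == 0) b[3] <- 0
  b
}
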