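# Brute-force oracles computed on the per-seed expansion: each germinated
# seed is assigned the end time of its counting interval, and every index is
# recomputed from that flat list of times, independently of the package's
# count-weighted formulas.

oracle_metrics <- function(time, count, seeds_planted) {
  x <- rep(time, count)
  n <- length(x)
  freq <- as.numeric(table(x))
  list(
    germinated = n,
    final_percent = 100 * n / seeds_planted,
    mean_time = if (n > 0) mean(x) else NA_real_,
    cv_time = if (n >= 2) 100 * stats::sd(x) / mean(x) else NA_real_,
    mean_rate = if (n > 0) 1 / mean(x) else NA_real_,
    uncertainty = if (n > 0) {
      f <- freq / n
      -sum(f * log2(f))
    } else NA_real_,
    synchrony = if (n >= 2) sum(freq * (freq - 1) / 2) / (n * (n - 1) / 2) else NA_real_
  )
}

# Interpolated time to reach `percent` of seeds planted, walking the
# cumulative step function directly.
oracle_time_to_percent <- function(time, count, percent, seeds_planted) {
  target <- percent / 100 * seeds_planted
  cum <- 0
  t_prev <- 0
  n_prev <- 0
  for (i in seq_along(time)) {
    cum <- cum + count[i]
    if (cum >= target) {
      return(t_prev + (time[i] - t_prev) * (target - n_prev) / (cum - n_prev))
    }
    t_prev <- time[i]
    n_prev <- cum
  }
  NA_real_
}

# Random interval-count sample on a random schedule (may contain zero counts
# and zero-germination samples).
random_sample <- function() {
  k <- sample(2:12, 1)
  time <- sort(sample(seq(0.5, 60, by = 0.5), k))
  seeds <- sample(10:40, 1)
  germ <- sample(0:seeds, 1)
  count <- as.vector(stats::rmultinom(1, germ, prob = rep(1, k)))
  list(time = time, count = count, seeds = seeds)
}
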