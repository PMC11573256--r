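# Independent oracles and small simulation helpers used across test files.
# These deliberately re-derive results with different code paths (explicit
# loops, hist() binning, exhaustive enumeration) so they can check the
# package implementations rather than mirror them.

# Homogeneous-Poisson trials at `rate` Hz over (0, duration] ms.
make_poisson_trials <- function(rate, duration, n_trials) {
  lapply(seq_len(n_trials), function(i) {
    n <- rpois(1, rate * duration / 1000)
    sort(runif(n, 0, duration))
  })
}

# Exhaustive leave-one-out nearest-neighbor accuracy with paired folds and
# ties credited 0.5 (matches tie_mode = "expected", template = "paired").
oracle_nn_accuracy <- function(trials_a, trials_b, window, bin) {
  breaks <- seq(window[1], window[2], by = bin)
  bin_one <- function(tt) {
    tt <- tt[tt >= window[1] & tt < window[2]]
    if (!length(tt)) {
      return(rep(0, length(breaks) - 1))
    }
    hist(tt, breaks = breaks, plot = FALSE, right = FALSE)$counts
  }
  A <- lapply(trials_a, bin_one)
  B <- lapply(trials_b, bin_one)
  na <- length(A)
  nb <- length(B)
  score <- 0
  judge <- function(x, own_rest, other_rest) {
    t_own <- Reduce(`+`, own_rest) / length(own_rest)
    t_oth <- Reduce(`+`, other_rest) / length(other_rest)
    d_own <- sqrt(sum((x - t_own)^2))
    d_oth <- sqrt(sum((x - t_oth)^2))
    if (isTRUE(all.equal(d_own, d_oth, tolerance = 1e-9))) {
      0.5
    } else if (d_own < d_oth) {
      1
    } else {
      0
    }
  }
  for (i in seq_len(na)) {
    j <- ((i - 1) %% nb) + 1
    score <- score + judge(A[[i]], A[-i], B[-j])
  }
  for (i in seq_len(nb)) {
    j <- ((i - 1) %% na) + 1
    score <- score + judge(B[[i]], B[-i], A[-j])
  }
  100 * score / (na + nb)
}

# Exhaustive two-sided permutation p value for the Mann-Whitney U statistic
# (no ties assumed): proportion of group relabelings whose U deviates from
# n1*n2/2 at least as much as the observed U.
oracle_mw_permutation_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(idx) {
    g1 <- pooled[idx]
    g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  center <- n1 * (n - n1) / 2
  obs_dev <- abs(u_stat(seq_len(n1)) - center)
  combos <- combn(n, n1)
  devs <- apply(combos, 2, function(idx) abs(u_stat(idx) - center))
  mean(devs >= obs_dev - 1e-12)
}
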