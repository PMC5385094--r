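# Independent brute-force oracles used to verify the package implementations.
# These deliberately avoid the code paths they check.

# Two-sided Fisher p by explicit hypergeometric enumeration with choose().
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; kk <- a + c_; N <- m + n
  denom <- choose(N, kk)
  xs <- max(0, kk - n):min(kk, m)
  probs <- choose(m, xs) * choose(n, kk - xs) / denom
  p_obs <- choose(m, a) * choose(n, kk - a) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Pearson chi-square statistic by explicit cellwise loop.
chisq_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    E <- rs[i] * cs[j] / N
    stat <- stat + (tab[i, j] - E)^2 / E
  }
  unname(stat)
}

# Welch t / df by direct formula evaluation.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# BH step-up by direct evaluation of the running minimum.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric enrichment p by explicit summation.
hyper_oracle <- function(overlap, set_size, query_size, universe_size) {
  xs <- overlap:min(set_size, query_size)
  sum(choose(set_size, xs) *
        choose(universe_size - set_size, query_size - xs)) /
    choose(universe_size, query_size)
}

# Product-limit estimator by hand, ties aggregated per distinct time.
km_oracle <- function(times, events) {
  tt <- sort(unique(times))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    n_i <- sum(times >= tt[i])
    d_i <- sum(times == tt[i] & events == 1)
    if (d_i > 0) s <- s * (1 - d_i / n_i)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank chi-square by O-E / hypergeometric-variance tabulation.
logrank_oracle_2g <- function(times, events, groups) {
  g1 <- sort(unique(groups))[1]
  evt <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in evt) {
    at <- times >= t
    n <- sum(at); d <- sum(events == 1 & times == t)
    n1 <- sum(at & groups == g1)
    O <- O + sum(events == 1 & times == t & groups == g1)
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Naive O(n^3) complete-linkage agglomeration on a dissimilarity matrix.
complete_linkage_oracle <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- Inf; bi <- bj <- NA
    for (i in 2:length(clusters)) for (j in 1:(i - 1)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# Same partition up to relabeling?
same_partition <- function(a, b) {
  tab <- table(a, b)
  sum(tab > 0) == max(length(unique(a)), length(unique(b)))
}

# A small fast simulation config shared across tests.
tiny_config <- function(seed = 1, n_normals = 10, ...) {
  simulation_config(
    n_tumors = 60, cluster_sizes = c(20L, 20L, 20L), n_normals = n_normals,
    n_lnc = 120, n_pcg = 150, markers_per_cluster = 10,
    pcg_up_per_cluster = 10, pcg_down_per_cluster = 10,
    marker_shift = 2, noise_sd = 0.5, seed = seed, ...)
}

# Map each truth cluster to the recovered cluster holding most of its samples.
truth_to_recovered <- function(truth_labels, labels) {
  ks <- sort(unique(truth_labels))
  vapply(ks, function(tc) {
    ids <- names(truth_labels)[truth_labels == tc]
    as.integer(names(sort(table(labels[ids]), decreasing = TRUE))[1])
  }, integer(1))
}
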