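# Shared fixture builders and independent oracles.

# one-treatment design with n replicate groups at given (phase, time)
make_design <- function(phases, times, n_rep = 3L, treatment = "heat35") {
  stopifnot(length(phases) == length(times))
  rows <- do.call(rbind, lapply(seq_along(phases), function(i)
    data.frame(
      sample_id = sprintf("%s_%s_%g_r%d", treatment, phases[i], times[i],
                          seq_len(n_rep)),
      treatment = treatment, phase = phases[i], time_h = times[i],
      replicate = seq_len(n_rep))))
  tc_design(rows)
}

# matrix of log-normal intensities keyed to a design
make_proteome <- function(design, n_prot = 20L, seed = 1L, sd = 0.3,
                          mean_log2 = 20) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_prot * nrow(design), mean_log2, sd), n_prot,
              dimnames = list(sprintf("p%03d", seq_len(n_prot)),
                              design$sample_id))
  proteome_matrix(m)
}

# brute-force Benjamini-Hochberg: sort, q_i = p_i * m / i, running minimum
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force upper-tail hypergeometric P(X >= k) by direct enumeration
hyper_brute <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two decoupled planted blocks: entities x time profiles with orthogonal
# block patterns, plus the resulting correlation matrix
make_two_blocks <- function(seed, t_pts = 30L, sigma = 1, n = 200L) {
  set.seed(seed)
  half <- n / 2
  b1 <- rnorm(t_pts)
  b2 <- rnorm(t_pts)
  b2 <- b2 - sum(b2 * b1) / sum(b1^2) * b1
  prof <- rbind(
    t(sapply(seq_len(half), function(i) b1 * 3 + rnorm(t_pts) * sigma)),
    t(sapply(seq_len(half), function(i) b2 * 3 + rnorm(t_pts) * sigma)))
  rownames(prof) <- sprintf("p%03d", seq_len(n))
  list(profiles = prof, corr = cor(t(prof)), half = half)
}
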