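# Independent brute-force oracles. Deliberately naive (explicit loops,
# no shared code with the implementation) so they can arbitrate.

# per-slice area/density/intensity by triple loop
oracle_channel_metrics <- function(channel, threshold) {
  d <- dim(channel)
  area <- integer(d[3]); density <- rep(NA_real_, d[3]); intensity <- numeric(d[3])
  for (k in seq_len(d[3])) {
    cnt <- 0L; tot <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      v <- channel[i, j, k]
      if (v > threshold) { cnt <- cnt + 1L; tot <- tot + v }
    }
    area[k] <- cnt
    if (cnt > 0L) { density[k] <- tot / cnt; intensity[k] <- tot }
  }
  list(area = area, density = density, intensity = intensity,
       mean_area = mean(area),
       mean_density = mean(density, na.rm = TRUE),
       mean_intensity = mean(intensity))
}

# histogram-based mean and population sd (independent accumulation)
oracle_mu_sigma <- function(channel) {
  v <- as.numeric(channel)
  s <- 0; s2 <- 0; n <- 0
  for (x in v) { s <- s + x; s2 <- s2 + x^2; n <- n + 1 }
  mu <- s / n
  list(mu = mu, sigma = sqrt(s2 / n - mu^2))
}

# permutation Kruskal-Wallis p-value
oracle_kw_perm <- function(values, groups, n_perm = 4000, seed = 99) {
  obs <- kruskal.test(values, factor(groups))$statistic
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    h <- kruskal.test(values, factor(sample(groups)))$statistic
    if (h >= obs - 1e-12) ge <- ge + 1L
  }
  (ge + 1) / (n_perm + 1)
}

# direct Beer-Lambert transmitted light for one pixel
oracle_transmit <- function(conc, basis, I0 = 255) {
  out <- numeric(3)
  for (ch in 1:3) {
    od <- 0
    for (s in 1:3) od <- od + conc[s] * basis[s, ch]
    out[ch] <- I0 * 10^(-od)
  }
  out
}
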