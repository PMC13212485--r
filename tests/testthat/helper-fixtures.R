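# Shared fixtures, built in code at test time.

# standard synthetic fixture: the full 103-record design with 5% noise
std_fixture <- local({
  cache <- new.env()
  function(seed = 7, noise_cv = 0.05) {
    key <- paste(seed, noise_cv)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_dataset(generator_config(noise_cv = noise_cv,
                                                        seed = seed))
    }
    cache[[key]]
  }
})

# small smooth single-compound dataset with an exactly linear response in
# the two varying features (for learner / attribution recovery checks)
linear_fixture <- function(n_t = 5, n_p = 6, noise = 0) {
  grid <- expand.grid(temperature = seq(308, 338, length.out = n_t),
                      pressure = seq(12, 30, length.out = n_p))
  y <- 0.05 * grid$pressure + 0.01 * grid$temperature
  if (noise > 0) y <- y + rnorm(nrow(grid), 0, noise)
  solubility_dataset(data.frame(
    compound = "synthA", grid,
    molecular_weight = 500, melting_point = 150, solubility = y))
}

# brute-force population summary oracle (explicit loops, two-pass variance)
oracle_summary <- function(x) {
  n <- length(x)
  mn <- Inf; mx <- -Inf; s <- 0
  for (v in x) { if (v < mn) mn <- v; if (v > mx) mx <- v; s <- s + v }
  mean_x <- s / n
  ss <- 0
  for (v in x) ss <- ss + (v - mean_x)^2
  c(min = mn, max = mx, mean = mean_x, sd = sqrt(ss / n))
}

# brute-force Dempster combination over all focal-set pairs (singletons + theta)
oracle_dempster <- function(m1, m2) {
  k <- m1$frame$k
  focal1 <- c(as.list(seq_len(k)), list(seq_len(k)))
  w1 <- c(m1$m, m1$m_theta)
  w2 <- c(m2$m, m2$m_theta)
  out <- numeric(k); out_theta <- 0; conflict <- 0
  for (i in seq_along(focal1)) {
    for (j in seq_along(focal1)) {
      inter <- intersect(focal1[[i]], focal1[[j]])
      p <- w1[i] * w2[j]
      if (length(inter) == 0) {
        conflict <- conflict + p
      } else if (length(inter) == k) {
        out_theta <- out_theta + p
      } else {
        out[inter[1]] <- out[inter[1]] + p
      }
    }
  }
  list(m = out / (1 - conflict), m_theta = out_theta / (1 - conflict),
       conflict = conflict)
}

# brute-force Kruskal-Wallis H with tie correction
oracle_kw <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(groups)) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# random mass function on a frame (for property tests)
random_mass <- function(frame, seed) {
  set.seed(seed)
  raw <- runif(frame$k + 1)
  raw <- raw / sum(raw)
  ghef:::mass_function(frame, raw[seq_len(frame$k)], raw[frame$k + 1])
}
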