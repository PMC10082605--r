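# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops so they share no code path with the
# package internals.

bf_median_filter <- function(px, window = 3L) {
  nr <- nrow(px); nc <- ncol(px); h <- window %/% 2
  out <- px
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -h:h) {
        for (dj in -h:h) {
          ci <- min(max(i + di, 1), nr)
          cj <- min(max(j + dj, 1), nc)
          vals <- c(vals, px[ci, cj])
        }
      }
      out[i, j] <- sort(vals)[(length(vals) + 1) %/% 2]
    }
  }
  out
}

# Otsu by looping over every candidate threshold (foreground = value > t).
bf_otsu <- function(px, levels = 256L) {
  n <- length(px)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:(levels - 2)) {
    bg <- px[px <= t]; fg <- px[px > t]
    if (length(bg) == 0 || length(fg) == 0) next
    w0 <- length(bg) / n; w1 <- length(fg) / n
    v <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# First-order statistics straight from the pixels (no histogram).
bf_histogram_features <- function(px, levels = 256L) {
  x <- as.numeric(px)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  counts <- table(x)
  p <- as.numeric(counts) / length(x)
  list(mean_int = m, std = s,
       smoothness = 1 - 1 / (1 + (s / (levels - 1))^2),
       skewness = if (s > 0) mean(((x - m) / s)^3) else 0,
       uniformity = sum(p^2),
       entropy = -sum(p * log2(p)))
}

# Exhaustive pair enumeration for the co-occurrence table.
bf_glcm <- function(codes, levels, offsets) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(codes); nc <- ncol(codes)
  for (o in seq_len(nrow(offsets))) {
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        i2 <- i + offsets[o, 1]; j2 <- j + offsets[o, 2]
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
          a <- codes[i, j] + 1; b <- codes[i2, j2] + 1
          counts[a, b] <- counts[a, b] + 1
          counts[b, a] <- counts[b, a] + 1
        }
      }
    }
  }
  counts / sum(counts)
}

bf_glcm_features <- function(tab) {
  n <- nrow(tab)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + (i - 1) * tab[i, j]
    mu_j <- mu_j + (j - 1) * tab[i, j]
  }
  sd_i <- 0; sd_j <- 0; cov_ <- 0
  for (i in 1:n) for (j in 1:n) {
    contrast <- contrast + (i - j)^2 * tab[i, j]
    energy <- energy + tab[i, j]^2
    homog <- homog + tab[i, j] / (1 + abs(i - j))
    sd_i <- sd_i + (i - 1 - mu_i)^2 * tab[i, j]
    sd_j <- sd_j + (j - 1 - mu_j)^2 * tab[i, j]
    cov_ <- cov_ + (i - 1 - mu_i) * (j - 1 - mu_j) * tab[i, j]
  }
  corr <- if (sd_i > 0 && sd_j > 0) cov_ / sqrt(sd_i * sd_j) else 1
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# Plug-in mutual information by explicit double loop (bits).
bf_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        mi <- mi + pab * log2(pab / (pa * pb))
      }
    }
  }
  max(mi, 0)
}

# Greedy max-relevance min-redundancy ranking, re-evaluating the objective
# over every candidate at every step.
bf_mrmr_rank <- function(codes, target) {
  feats <- colnames(codes)
  selected <- character(0)
  remaining <- feats
  while (length(remaining) > 0) {
    obj <- sapply(remaining, function(f) {
      rel <- bf_mi(codes[, f], target)
      if (length(selected) == 0) return(rel)
      red <- mean(sapply(selected, function(s) bf_mi(codes[, f], codes[, s])))
      rel - red
    })
    best <- remaining[which.max(round(obj, 10))]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# AUC via the rank-based (Mann-Whitney) statistic with midrank tie handling.
bf_auc_u <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Inverse-CDF sampler for the semicircular von Mises law on a fine grid;
# independent of the package's rejection sampler.
bf_rvm_semicircular <- function(n, mu_deg, kappa) {
  grid <- seq(0, 180, length.out = 14401)
  dens <- exp(kappa * cos(2 * (grid - mu_deg) * pi / 180))
  cdf <- cumsum(dens) / sum(dens)
  u <- runif(n)
  grid[findInterval(u, cdf) + 1]
}

# Circular SD of doubled angles (degrees in [0,180) domain).
circ_sd2 <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sqrt(-2 * log(R))
}
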