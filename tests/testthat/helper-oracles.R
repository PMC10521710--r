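# Brute-force oracles and small fixtures shared across tests.

# flood-fill connected components (recursive queue), independent of the
# package's C++ labelling
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0]) next
    cur <- cur + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (r >= 1 && r <= H && cc >= 1 && cc <= W &&
            mask[r, cc] && !lab[r, cc]) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# per-pixel smooth L1, written directly from the defining formula
smooth_l1_oracle <- function(a, b, beta = 1) {
  d <- a - b
  tot <- 0
  for (i in seq_along(d)) {
    tot <- tot + if (abs(d[i]) < beta) 0.5 * d[i]^2 / beta
    else abs(d[i]) - 0.5 * beta
  }
  tot / length(d)
}

# global-statistics SSIM from the defining ratio (population moments)
ssim_oracle <- function(a, b, c1 = 1e-4, c2 = 9e-4) {
  n <- length(a)
  muA <- sum(a) / n; muB <- sum(b) / n
  vA <- sum((a - muA)^2) / n; vB <- sum((b - muB)^2) / n
  cAB <- sum((a - muA) * (b - muB)) / n
  (2 * muA * muB + c1) * (2 * cAB + c2) /
    ((muA^2 + muB^2 + c1) * (vA + vB + c2))
}

bce_oracle <- function(p, q) {
  s <- 1 / (1 + exp(-p))
  mean(-q * log(s) - (1 - q) * log(1 - s))
}

# Pearson chi-square from first principles
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive between-class-variance Otsu search over candidate thresholds
otsu_oracle <- function(x, candidates = sort(unique(as.numeric(x)))) {
  best <- NA; best_v <- -Inf
  for (t in candidates) {
    w0 <- mean(x <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(x[x > t]) - mean(x[x <= t]))^2
    if (v > best_v) { best_v <- v; best <- t }
  }
  best
}

# small cached synthetic dataset shared by the slower tests
tiny_geometry <- function(size = 96) her2_geometry(height = size, width = size)

tiny_pairs_cache <- new.env()
tiny_pairs <- function(n_per_grade = 2, size = 96, seed = 42) {
  key <- paste(n_per_grade, size, seed, sep = "_")
  if (is.null(tiny_pairs_cache[[key]]))
    tiny_pairs_cache[[key]] <- synth_dataset(
      n_per_grade = n_per_grade, tiles_per_patient = 1,
      geometry = tiny_geometry(size), seed = seed)
  tiny_pairs_cache[[key]]
}

expect_same_dims <- function(a, b) expect_identical(dim(a), dim(b))
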