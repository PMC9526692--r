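# Independent brute-force oracles used to cross-check the implementation.
# They are deliberately written from first principles (explicit loops,
# textbook formulas) and share no code with the package internals.

# One-way ANOVA from raw sums of squares
oracle_anova <- function(values, classes) {
  groups <- split(values, classes)
  k <- length(groups)
  N <- length(values)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, p = pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Tukey-Kramer studentized-range test from the q distribution
oracle_tukey <- function(values, classes) {
  groups <- split(values, classes)
  k <- length(groups)
  N <- length(values)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (N - k)
  nms <- names(groups)
  out <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- groups[[i]]; b <- groups[[j]]
      se <- sqrt(mse / 2 * (1 / length(a) + 1 / length(b)))
      q <- abs(mean(a) - mean(b)) / se
      p <- ptukey(q, k, N - k, lower.tail = FALSE)
      out <- rbind(out, data.frame(a = nms[i], b = nms[j],
                                   diff = mean(b) - mean(a), p = p))
    }
  }
  out
}

# normalized radius recomputed per pixel with a scalar 2x2 linear solve
# per polygon segment (closed polygon, nearest positive hit)
oracle_rho <- function(p, centro, polygon) {
  d <- p - centro
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  u <- d / len
  v <- nrow(polygon)
  best <- Inf
  for (i in seq_len(v)) {
    a <- polygon[i, ]
    b <- polygon[if (i == v) 1 else i + 1, ]
    A <- cbind(u, -(b - a))
    if (abs(det(A)) < 1e-12) next
    sol <- solve(A, a - centro)
    if (sol[2] >= -1e-9 && sol[2] <= 1 + 1e-9 && sol[1] > 1e-9)
      best <- min(best, sol[1])
  }
  len / best
}

# brute-force average-linkage agglomeration: returns the merge heights
# in order, computed from the full pairwise-distance definition
oracle_average_linkage_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  dmat <- as.matrix(dist(x))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# exhaustive hypergeometric upper tail by enumerating all draws
oracle_hyper_upper <- function(k, K, N, n) {
  total <- choose(N, n)
  num <- 0
  for (x in k:min(n, K))
    num <- num + choose(K, x) * choose(N - K, n - x)
  num / total
}

# circular polygon helper (row, col) around a centre
circle_polygon <- function(centre, radius, n_vertices = 128) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(centre[1] + radius * sin(th), centre[2] + radius * cos(th))
}

# small 14-sample study-design intensity matrix with fixed contents
toy_study_matrix <- function(n = 40, seed = 42) {
  sim <- simulate_proteomics(proteomics_sim_spec(
    n, frac_dapg = 0, noise_sd = 0.25, mnar_quantile = 0.05, seed = seed))
  sim$matrix
}
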