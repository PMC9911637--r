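# Independent oracles used to pin the package's implementations.
# These deliberately share no code with the implementation paths they check.

# Brute-force elastic net by FISTA (accelerated proximal gradient) on the
# objective (1/2n)*RSS + lambda*(alpha*L1 + (1-alpha)/2*L2) with predictors
# standardized by their biased (1/n) standard deviation, matching the
# fitting routine's convention. Returns coefficients on the original scale.
enet_fista <- function(x, y, alpha, lambda, iters = 50000, tol = 1e-12) {
  n <- nrow(x)
  xbar <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, xbar)^2))
  xs <- sweep(sweep(x, 2, xbar), 2, s, "/")
  yc <- y - mean(y)
  L <- max(eigen(crossprod(xs) / n, symmetric = TRUE, only.values = TRUE)$values) +
    (1 - alpha) * lambda
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  b <- rep(0, ncol(x)); z <- b; tk <- 1
  for (i in seq_len(iters)) {
    grad <- -crossprod(xs, yc - xs %*% z) / n + (1 - alpha) * lambda * z
    b_new <- soft(z - grad / L, alpha * lambda / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    if (max(abs(b_new - b)) < tol && i > 10) { b <- b_new; break }
    b <- b_new; tk <- t_new
  }
  beta <- drop(b) / s
  list(intercept = mean(y) - sum(beta * xbar), beta = beta)
}

# Histogram mode counter: bins of width `bin`; candidate modes are local
# maxima above `frac` of the largest bin; a candidate only counts as a
# separate mode if it sits at least `merge_dist` from every accepted mode
# AND is separated from each by a genuine valley (some bin between them
# falls below half the candidate's count).
hist_modes <- function(x, bin = 0.05, frac = 0.2, merge_dist = 0.2) {
  br <- seq(0, 1, by = bin)
  cnt <- graphics::hist(pmin(pmax(x, 0), 1), breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-length(br)]) / 2
  n <- length(cnt)
  cand <- which(cnt >= frac * max(cnt) &
                cnt >= c(-1, cnt[-n]) & cnt >= c(cnt[-1], -1))
  cand <- cand[order(cnt[cand], decreasing = TRUE)]
  acc <- integer(0)
  for (p in cand) {
    ok <- TRUE
    for (a in acc) {
      between <- cnt[(min(p, a)):(max(p, a))]
      if (abs(mids[p] - mids[a]) < merge_dist || min(between) > 0.5 * cnt[p]) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, p)
  }
  sort(mids[acc])
}

# One-way ANOVA F recomputed from group summaries (for pinning batch_pca).
f_from_groups <- function(x, g) {
  g <- factor(g)
  means <- tapply(x, g, mean); ns <- tapply(x, g, length)
  ssb <- sum(ns * (means - mean(x))^2)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (nlevels(g) - 1)) / (ssw / (length(x) - nlevels(g)))
}

# Bare value matrix of a beta_matrix, bookkeeping attributes dropped.
strip_attrs <- function(bm) {
  m <- unclass(bm)
  attr(m, "n_clipped") <- NULL
  attr(m, "batch_model") <- NULL
  attr(m, "clip_fraction") <- NULL
  m
}

# Small labelled beta matrix for IO / filtering tests.
toy_beta <- function(n_sites = 6, n_samples = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_sites * n_samples, 0.05, 0.95), n_sites, n_samples,
                dimnames = list(sprintf("cg%06d", seq_len(n_sites)),
                                sprintf("S%03d", seq_len(n_samples))))
    beta_matrix(m)
  })
}

# Shared default simulation used by several expensive tests; computed once
# per test run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config())
    cache
  }
})
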