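# Shared fixtures and independent oracles. The small seascape is built
# once per test run and reused read-only.

fixture_env <- new.env()

small_seascape <- function() {
  if (is.null(fixture_env$ss))
    fixture_env$ss <- generate_seascape(c(40, 50, -24, -14), 2008:2009,
                                        9:12, seed = 424)
  fixture_env$ss
}

# Straight-line trajectory builder: positions at given lon/lat with gaps
# in hours.
make_traj <- function(lon, lat, gap_h = 1, id = "T1",
                      t0 = as.POSIXct("2008-09-01 00:00:00", tz = "UTC")) {
  n <- length(lon)
  gaps <- if (length(gap_h) == 1) rep(gap_h, n - 1) else gap_h
  data.frame(id = id, timestamp = t0 + c(0, cumsum(gaps)) * 3600,
             lon = lon, lat = lat, device = "GPS",
             stringsAsFactors = FALSE)
}

# Independent AUC oracle: brute-force pair counting, ties one half.
auc_pairs <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Independent logistic-regression oracle: iteratively reweighted least
# squares, no glm()/glmer() involved.
irls_logistic <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Simulated binary dataset on independent covariates with group structure.
make_glmm_data <- function(n, beta, sigma, n_groups, seed) {
  set.seed(seed)
  k <- length(beta) - 1
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  g <- factor(rep_len(seq_len(n_groups), n))
  b <- rnorm(n_groups, 0, sigma)
  lp <- beta[1] + drop(X %*% beta[-1]) + b[as.integer(g)]
  d <- data.frame(response = rbinom(n, 1, plogis(lp)), X,
                  group = g)
  d
}

# Exhaustive threshold-scan oracle for the ROC threshold.
roc_scan_oracle <- function(labels, scores) {
  cand <- sort(unique(scores))
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec > best_j + 1e-12) { best_j <- sens + spec; best_t <- t }
  }
  list(p_th = best_t, j = best_j)
}
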