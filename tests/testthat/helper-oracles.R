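# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct dense linear algebra for the GP
# posterior, and exhaustive enumeration for the exact tests.

# closed-form GP posterior by plain solve(), mirroring the textbook
# equations; hp on the natural scale, inputs as (pma, pnd, male) matrices
oracle_gp_posterior <- function(hp, X, y, Xs) {
  k_fun <- function(a, b) {
    hp["sf"]^2 * exp(-0.5 * ((a[1] - b[1])^2 / hp["len_pma"]^2 +
                               (a[2] - b[2])^2 / hp["len_pnd"]^2 +
                               (a[3] - b[3])^2 / hp["len_sex"]^2)) +
      hp["wl"]^2 * (a[1] - 40) * (b[1] - 40)
  }
  n <- nrow(X); m <- nrow(Xs)
  K <- matrix(0, n, n); Ks <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:n) K[i, j] <- k_fun(X[i, ], X[j, ])
  for (i in 1:n) for (j in 1:m) Ks[i, j] <- k_fun(X[i, ], Xs[j, ])
  K <- K + diag(hp["sn"]^2 + 1e-8, n)
  ybar <- mean(y)
  Kinv <- solve(K)
  mu <- drop(t(Ks) %*% Kinv %*% (y - ybar)) + ybar
  kss <- vapply(1:m, function(j) k_fun(Xs[j, ], Xs[j, ]), numeric(1))
  var_lat <- kss - vapply(1:m, function(j) {
    drop(t(Ks[, j]) %*% Kinv %*% Ks[, j])
  }, numeric(1))
  list(mu = mu, sigma = sqrt(pmax(var_lat, 0) + hp["sn"]^2))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  W_obs <- sum(r[d > 0])
  min(1, 2 * min(mean(W_all >= W_obs), mean(W_all <= W_obs)))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(x, y) {
  n <- length(x)
  rr <- rank(c(x, y))
  U_obs <- sum(rr[seq_len(n)]) - n * (n + 1) / 2
  cmb <- utils::combn(length(rr), n)
  U_all <- apply(cmb, 2, function(ix) sum(rr[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(U_all >= U_obs), mean(U_all <= U_obs)))
}

# exact two-sided Spearman permutation p by full n! enumeration
oracle_spearman_perm <- function(x, y) {
  permn <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in permn(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  S_obs <- sum((rx - ry)^2)
  S_all <- vapply(permn(seq_len(n)),
                  function(p) sum((sort(rx) - sort(ry)[p])^2), numeric(1))
  min(1, 2 * min(mean(S_all <= S_obs), mean(S_all >= S_obs)))
}

# exact two-sided Fisher 2x2 p by hypergeometric point-probability rule
oracle_fisher_2x2 <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  ks <- max(0, k - n):min(m, k)
  pr <- stats::dhyper(ks, m, n, k)
  sum(pr[pr <= stats::dhyper(tb[1, 1], m, n, k) * (1 + 1e-7)])
}

# partial rank correlation via the inverse-correlation-matrix identity
oracle_partial_spearman <- function(x, y, Z) {
  R <- stats::cor(cbind(rank(x), rank(y), apply(as.matrix(Z), 2, rank)))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# small fully-specified hyperparameter set for fixed-GP tests
fixed_hp <- c(len_pma = 2.5, len_pnd = 15, len_sex = 1, sf = 8, wl = 1.5,
              sn = 0.8)

# compact noise-free scan table on a PMA grid
grid_scans <- function(n, seed = 1, volume_fun,
                       ga = 40) {
  set.seed(seed)
  pma <- seq(37.5, 44.5, length.out = n)
  pnd <- pmax(0L, as.integer(round(7 * (pma - ga))))
  sex <- rep(c("F", "M"), length.out = n)
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   group = "normative", sex = sex, ga_birth_weeks = ga,
                   pma_scan_weeks = pma, postnatal_days = pnd,
                   timepoint = "single", stringsAsFactors = FALSE)
  df$vol <- volume_fun(pma, pnd, as.numeric(sex == "M"))
  df
}
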