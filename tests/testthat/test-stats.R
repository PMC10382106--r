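test_that("paired signed-rank test matches enumeration and handles degeneracy", {
  r <- wilcoxon_paired(c(2, 4, 7), c(1, 2, 4))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_raw, 0.25)
  expect_warning(r0 <- wilcoxon_paired(1:5, 1:5), "zero")
  expect_equal(r0$p_raw, 1)
  set.seed(17)
  for (k in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    r <- wilcoxon_paired(x, y)
    expect_equal(r$p_raw, oracle_signed_rank(x - y), tolerance = 1e-12)
  }
  # missing pairs are dropped, zeros excluded from ranking
  r2 <- wilcoxon_paired(c(1, NA, 5, 3, 2, 9, 4, 6), c(2, 1, 5, 1, 5, 2, 2, 8))
  expect_equal(r2$n_used, 7)
})

test_that("Kruskal-Wallis reproduces the hand-computed H and degenerate case", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 4.571, tolerance = 5e-4)
  expect_warning(r0 <- kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  expect_error(kruskal_wallis(list(1:3)), "non-empty")
  # two-group Kruskal-Wallis agrees with Mann-Whitney asymptotically
  set.seed(23)
  x <- rnorm(100); y <- rnorm(100, 0.3)
  pk <- kruskal_wallis(list(x, y))$p_raw
  pm <- mann_whitney(x, y)$p_raw
  expect_lt(abs(pk - pm), 0.02)
})

test_that("Mann-Whitney matches enumeration, symmetry, and Hodges-Lehmann effect", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1 / 3, tolerance = 1e-12)
  x <- c(5, 7, 9, 11)
  r2 <- mann_whitney(x, x)
  expect_equal(r2$statistic, length(x)^2 / 2)
  set.seed(29)
  for (k in 1:4) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(mann_whitney(x, y)$p_raw, oracle_mann_whitney(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(mann_whitney(c(10, 20), c(1, 2))$effect,
               median(outer(c(10, 20), c(1, 2), `-`)))
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_raw, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_raw, 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(31)
  for (k in 1:5) {
    tb <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact(tb)$p_raw, oracle_fisher_2x2(tb),
                 tolerance = 1e-12)
  }
  # empty-category invariance and degenerate margins
  tb3 <- rbind(c(4, 1, 2), c(0, 0, 0), c(1, 3, 2))
  expect_equal(fisher_exact(tb3)$p_raw, fisher_exact(tb3[-2, ])$p_raw)
  expect_error(fisher_exact(matrix(0, 2, 2)), "degenerate")
  # 3xC exact path on a small table
  expect_s3_class(fisher_exact(rbind(c(3, 1), c(2, 4), c(1, 5))),
                  "data.frame")
})

test_that("Spearman correlation hits the trivial poles and permutation oracle", {
  expect_equal(spearman(1:6, c(2, 4, 5, 7, 8, 11))$effect, 1)
  expect_equal(spearman(1:6, -(1:6)^3)$effect, -1)
  set.seed(37)
  x <- sample(1000, 7); y <- sample(1000, 7)
  expect_equal(spearman(x, y)$p_raw, oracle_spearman_perm(x, y),
               tolerance = 1e-12)
  expect_warning(r <- spearman(rep(1, 6), rnorm(6)), "zero rank variance")
  expect_true(is.na(r$p_raw))
  # invariance under strictly monotone transforms
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearman(x, y)$p_raw, spearman(exp(x), rank(y))$p_raw,
               tolerance = 1e-12)
})

test_that("partial Spearman matches the matrix-inversion oracle and reduces to plain", {
  set.seed(41)
  for (k in 1:4) {
    x <- rnorm(50); z <- rnorm(50); z2 <- rnorm(50)
    y <- 0.5 * x + 0.7 * z + rnorm(50)
    r1 <- partial_spearman(x, y, z)
    expect_equal(r1$effect, oracle_partial_spearman(x, y, cbind(z)),
                 tolerance = 1e-10)
    r2 <- partial_spearman(x, y, cbind(z, z2))
    expect_equal(r2$effect, oracle_partial_spearman(x, y, cbind(z, z2)),
                 tolerance = 1e-10)
  }
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_spearman(x, y)$effect, spearman(x, y)$effect,
               tolerance = 1e-12)
  expect_equal(partial_spearman(x, y)$p_raw, spearman(x, y)$p_raw,
               tolerance = 1e-12)
  # constant covariate projects onto the intercept only
  expect_equal(partial_spearman(x, y, rep(2, 30))$effect,
               spearman(x, y)$effect, tolerance = 1e-12)
  expect_error(partial_spearman(x, y, cbind(a = x, b = 2 * rank(x))),
               "collinear")
  expect_error(partial_spearman(x, y, covariates = x), "degenerate")
})

test_that("BH adjustment follows the step-up rule and restores missing", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
  p <- c(0.9, NA, 0.001, 0.04, NA, 0.2)
  adj <- bh_fdr(p)
  expect_equal(is.na(adj), is.na(p))
  expect_equal(adj[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  set.seed(43)
  p <- runif(13)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("region families apply one test per region and correct within family", {
  set.seed(47)
  n <- 30
  regions <- modelled_regions()
  tr <- expand.grid(subject_id = sprintf("s%02d", 1:n), region = regions,
                    stringsAsFactors = FALSE)
  tr$z_pre <- rnorm(nrow(tr))
  tr$z_post <- tr$z_pre + rnorm(nrow(tr), -0.3, 0.5)
  tr$delta_z <- tr$z_post - tr$z_pre
  cov <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    picu_days = rlnorm(n, log(4), 0.4),
                    age_surgery_days = rlnorm(n, log(12), 0.5),
                    rrt = rbinom(n, 1, 0.3),
                    chd_category = sample(c("streaming", "left", "right"),
                                          n, TRUE))
  fam <- run_region_family(tr, test = "wilcoxon")
  expect_equal(nrow(fam), 13)
  expect_equal(fam$p_fdr, p.adjust(fam$p_raw, "BH"))
  fam2 <- run_region_family(tr, cov, test = "partial_spearman",
                            var = "picu_days", given = "age_surgery_days")
  expect_equal(unique(fam2$n_used), n)
  fam3 <- run_region_family(tr, cov, test = "kruskal_wallis",
                            var = "chd_category")
  expect_equal(nrow(fam3), 13)
  # a fully-missing region shrinks the family to m = 12
  tr2 <- tr
  tr2$delta_z[tr2$region == "brainstem"] <- NA
  tr2$z_post[tr2$region == "brainstem"] <- NA
  expect_warning(fam4 <- run_region_family(tr2, cov, test = "spearman",
                                           var = "picu_days"),
                 "brainstem")
  ok <- !is.na(fam4$p_raw)
  expect_equal(sum(ok), 12)
  expect_equal(fam4$p_fdr[ok], p.adjust(fam4$p_raw[ok], "BH"))
})
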