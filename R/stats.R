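test_result <- function(test_name, statistic, effect, p_raw, n_used,
                        family = NA_character_, note = NA_character_) {
  data.frame(test_name = test_name, family = family,
             statistic = unname(statistic), effect = unname(effect),
             p_raw = unname(p_raw), p_fdr = NA_real_,
             n_used = as.integer(n_used), note = note,
             stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired measurements (e.g. a region's Z-score before and after
#' surgery). Pairs with a missing value are dropped; zero differences are
#' dropped before ranking (Wilcoxon's original rule); ties are mid-ranked.
#' The exact two-sided p-value is used when at most 25 non-zero,
#' untied differences remain, otherwise the normal approximation with
#' continuity correction. The effect is the median of the paired
#' differences `x - y`.
#'
#' @param x,y equal-length paired samples.
#' @param family optional multiple-testing family label.
#' @return one-row data.frame (`test_name`, `family`, `statistic` = the
#'   positive-rank sum, `effect`, `p_raw`, `p_fdr` (NA until adjusted),
#'   `n_used`, `note`).
#' @export
wilcoxon_paired <- function(x, y, family = NA_character_) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  eff <- stats::median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate test",
            call. = FALSE)
    return(test_result("wilcoxon_paired", 0, eff, 1, sum(ok), family,
                       "all differences zero"))
  }
  exact <- n <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  test_result("wilcoxon_paired", wt$statistic, eff, wt$p.value, sum(ok),
              family, if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups list of numeric samples (e.g. Z-slope changes split by CHD
#'   category). The H statistic carries the usual tie correction; p is
#'   chi-squared with `k - 1` degrees of freedom.
#' @inheritParams wilcoxon_paired
#' @return one-row TestResult data.frame (effect is NA: no single
#'   median-difference summarises more than two groups).
#' @export
kruskal_wallis <- function(groups, family = NA_character_) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(!lengths(groups))) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  v <- unlist(groups)
  if (length(unique(v)) == 1L) {
    warning("all observations identical; H set to 0", call. = FALSE)
    return(test_result("kruskal_wallis", 0, NA_real_, 1, length(v), family,
                       "degenerate: all values tied"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(v, g)
  test_result("kruskal_wallis", kt$statistic, NA_real_, kt$p.value,
              length(v), family)
}

#' Mann-Whitney U test with Hodges-Lehmann effect
#'
#' Two-sample rank test; exact two-sided p when the smaller sample has at
#' most 8 observations and there are no cross-sample ties, otherwise the
#' normal approximation with tie correction and continuity correction. The
#' effect is the median of all pairwise differences `x - y`
#' (Hodges-Lehmann).
#'
#' @param x,y numeric samples.
#' @inheritParams wilcoxon_paired
#' @return one-row TestResult data.frame (`statistic` is U for `x`).
#' @export
mann_whitney <- function(x, y, family = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  exact <- min(length(x), length(y)) <= 8 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  eff <- stats::median(outer(x, y, `-`))
  test_result("mann_whitney", wt$statistic, eff, wt$p.value,
              length(x) + length(y), family,
              if (exact) "exact" else "normal approximation")
}

#' Fisher exact test on a contingency table
#'
#' Two-sided by the point-probability rule for 2x2 tables; larger tables
#' (up to 3 rows) are evaluated exactly when the total count is at most 40
#' and by seeded Monte-Carlo otherwise (the Monte-Carlo standard error is
#' recorded in `note`). All-zero rows or columns are dropped first, so an
#' empty category never changes the p-value.
#'
#' @param table matrix of non-negative integer counts.
#' @param mc_b Monte-Carlo replicates for large tables.
#' @param mc_seed seed for the Monte-Carlo path.
#' @inheritParams wilcoxon_paired
#' @return one-row TestResult data.frame (`statistic` is the sample odds
#'   ratio for 2x2 tables, NA otherwise).
#' @export
fisher_exact <- function(table, family = NA_character_, mc_b = 1e5,
                         mc_seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table degenerate after dropping empty categories", call. = FALSE)
  }
  note <- NA_character_
  if (all(dim(table) == 2)) {
    ft <- stats::fisher.test(table)
    or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
    return(test_result("fisher_exact", or, NA_real_, ft$p.value,
                       sum(table), family, "exact 2x2"))
  }
  if (sum(table) <= 40) {
    ft <- stats::fisher.test(table, workspace = 2e6)
    note <- "exact"
  } else {
    ft <- with_seed(mc_seed,
                    stats::fisher.test(table, simulate.p.value = TRUE,
                                       B = mc_b))
    note <- sprintf("monte-carlo B=%d se=%.2g", as.integer(mc_b),
                    sqrt(ft$p.value * (1 - ft$p.value) / mc_b))
  }
  test_result("fisher_exact", NA_real_, NA_real_, ft$p.value, sum(table),
              family, note)
}

#' Spearman rank correlation
#'
#' Mid-ranked correlation with exact permutation p for n at most 9 without
#' ties, and the t approximation with `n - 2` degrees of freedom otherwise.
#' Missing values are dropped pairwise.
#'
#' @param x,y numeric samples.
#' @inheritParams wilcoxon_paired
#' @return one-row TestResult data.frame (`statistic` and `effect` are both
#'   rho); a rank-degenerate input gives an NA result with a warning.
#' @export
spearman <- function(x, y, family = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("zero rank variance; correlation undefined", call. = FALSE)
    return(test_result("spearman", NA_real_, NA_real_, NA_real_, n, family,
                       "degenerate ranks"))
  }
  exact <- n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  test_result("spearman", ct$estimate, ct$estimate, ct$p.value, n, family,
              if (exact) "exact" else "t approximation")
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables (mid-ranks), residualises the ranks of `x`
#' and `y` on the ranks of the covariates by least squares, and correlates
#' the residuals; the p-value uses the t approximation with `n - 2 - k`
#' degrees of freedom for `k` covariates. With zero covariates this reduces
#' exactly to the plain Spearman rho.
#'
#' @param x,y numeric samples.
#' @param covariates numeric vector, matrix or data.frame of controlling
#'   variables (may be empty).
#' @inheritParams wilcoxon_paired
#' @return one-row TestResult data.frame.
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             family = NA_character_) {
  Z <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  k <- ncol(Z)
  ok <- is.finite(x) & is.finite(y)
  if (k > 0) ok <- ok & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  if (n < k + 4) stop("need >= k + 4 complete rows", call. = FALSE)
  # a constant covariate is just the intercept projection: drop it
  if (k > 0) {
    keep <- apply(Z, 2, function(v) stats::var(v) > 0)
    Z <- Z[, keep, drop = FALSE]
    k <- ncol(Z)
  }
  rx <- rank(x); ry <- rank(y)
  M <- if (k > 0) {
    cbind(`(intercept)` = rep(1, n), apply(Z, 2, rank))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  }
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    dropped <- colnames(M)[qr_m$pivot[(qr_m$rank + 1):ncol(M)]]
    stop("collinear rank covariate(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  ex <- stats::residuals(stats::lm.fit(M, rx))
  ey <- stats::residuals(stats::lm.fit(M, ry))
  if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12) {
    stop("degenerate: a variable is fully explained by the covariate ranks",
         call. = FALSE)
  }
  rho <- stats::cor(ex, ey)
  df <- n - 2 - k
  tt <- rho * sqrt(df / max(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tt), df)
  test_result("partial_spearman", rho, rho, p, n, family,
              sprintf("k=%d covariate(s)", k))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in \[0, 1\]; missing entries are excluded
#'   from the family size and restored as missing.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Run one statistical family across all regions
#'
#' Applies one test per region of a trajectory table and adjusts the raw
#' p-values with Benjamini-Hochberg across the regions of the family (the
#' family size `m` counts only regions where the test produced a p-value;
#' regions failing the test's minimum-data requirement are reported as
#' missing rows and excluded from `m` with a warning).
#'
#' @param trajectories output of [build_trajectories()].
#' @param covariates per-subject covariate table keyed by `subject_id`.
#' @param test one of `"wilcoxon"` (z_pre vs z_post), `"kruskal_wallis"`
#'   (delta_z across the groups of `var`), `"mann_whitney"` (delta_z by the
#'   binary `var`; x = var == 0, y = var == 1), `"spearman"` (delta_z vs
#'   `var`) or `"partial_spearman"` (delta_z vs `var` given `given`).
#' @param var covariate column name (unused for `"wilcoxon"`).
#' @param given character vector of covariate columns to control for
#'   (partial Spearman only).
#' @param family family label recorded in the results (defaults to a
#'   test/var string).
#' @param response trajectory column tested (default `"delta_z"`).
#' @return data.frame with one row per region: region + TestResult columns,
#'   `p_fdr` filled in.
#' @export
run_region_family <- function(trajectories, covariates = NULL,
                              test = c("wilcoxon", "kruskal_wallis",
                                       "mann_whitney", "spearman",
                                       "partial_spearman"),
                              var = NULL, given = NULL, family = NULL,
                              response = "delta_z") {
  test <- match.arg(test)
  if (is.null(family)) {
    family <- paste(c(test, var, if (length(given)) paste0("given_", given)),
                    collapse = ".")
  }
  regions <- unique(trajectories$region)
  need_cov <- test != "wilcoxon"
  if (need_cov) {
    stopifnot(!is.null(covariates), !is.null(var))
    missing_cols <- setdiff(c(var, given), names(covariates))
    if (length(missing_cols)) {
      stop("covariate column(s) not found: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  rows <- lapply(regions, function(r) {
    tr <- trajectories[trajectories$region == r, ]
    if (need_cov) {
      tr <- merge(tr, covariates, by = "subject_id", sort = FALSE)
    }
    res <- tryCatch(switch(test,
      wilcoxon = wilcoxon_paired(tr$z_post, tr$z_pre, family = family),
      kruskal_wallis = {
        g <- split(tr[[response]], tr[[var]])
        kruskal_wallis(g, family = family)
      },
      mann_whitney = mann_whitney(tr[[response]][tr[[var]] == 0],
                                  tr[[response]][tr[[var]] == 1],
                                  family = family),
      spearman = spearman(tr[[var]], tr[[response]], family = family),
      partial_spearman = partial_spearman(tr[[var]], tr[[response]],
                                          tr[given], family = family)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("region %s excluded from family '%s': %s", r, family,
                      conditionMessage(res)), call. = FALSE)
      res <- test_result(test, NA_real_, NA_real_, NA_real_, 0L, family,
                         conditionMessage(res))
    }
    cbind(region = r, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  rownames(out) <- NULL
  out
}
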