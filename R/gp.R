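#' Control parameters for normative-model fitting
#'
#' @param restarts number of random restarts for hyperparameter
#'   optimisation (each an L-BFGS-B run from a jittered data-driven start;
#'   the best marginal likelihood wins, ties broken by lowest noise SD).
#' @param seed integer seed governing the restart initialisations.
#' @param min_n minimum number of complete training rows per region.
#' @param margin PMA margin (weeks) beyond the training range within which
#'   prediction is still allowed.
#' @param strict if `TRUE`, predicting outside the permitted PMA range is an
#'   error; otherwise a warning.
#' @param scale `"raw"` models volumes in mL; `"log"` models log-volumes
#'   (Z-scores are then deviations on the log scale).
#' @param maxit maximum L-BFGS-B iterations per restart.
#' @return list of class `gp_control`.
#' @export
gp_control <- function(restarts = 5, seed = 1, min_n = 30, margin = 1,
                       strict = FALSE, scale = c("raw", "log"),
                       maxit = 200) {
  scale <- match.arg(scale)
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 min_n = as.integer(min_n), margin = margin, strict = strict,
                 scale = scale, maxit = as.integer(maxit)),
            class = "gp_control")
}

hyper_names <- c("len_pma", "len_pnd", "len_sex", "sf", "wl", "sn")

# squared distance matrices for the three covariates
sq_dists <- function(X1, X2) {
  lapply(1:3, function(j) outer(X1[, j], X2[, j], `-`)^2)
}

# kernel: anisotropic RBF on (pma, pnd, sex01) + linear in centred pma
# + (optionally) white noise on the diagonal. `hp` on the natural scale.
kern <- function(hp, X1, X2, noise = FALSE) {
  D <- sq_dists(X1, X2)
  R <- exp(-0.5 * (D[[1]] / hp["len_pma"]^2 + D[[2]] / hp["len_pnd"]^2 +
                     D[[3]] / hp["len_sex"]^2))
  K <- hp["sf"]^2 * R + hp["wl"]^2 * outer(X1[, 1] - 40, X2[, 1] - 40)
  if (noise) K <- K + diag(hp["sn"]^2, nrow(K))
  K
}

# negative log marginal likelihood and gradient in log(hp)
gp_nlml <- function(ltheta, X, yc, D, G) {
  hp <- exp(ltheta)
  n <- length(yc)
  R <- exp(-0.5 * (D[[1]] / hp[1]^2 + D[[2]] / hp[2]^2 + D[[3]] / hp[3]^2))
  K <- hp[4]^2 * R + hp[5]^2 * G + diag(hp[6]^2 + 1e-8, n)
  U <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-6 * mean(diag(K)), n)))
  alpha <- backsolve(U, forwardsolve(t(U), yc))
  nlml <- 0.5 * sum(yc * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)
  A <- tcrossprod(alpha) - chol2inv(U)
  gr <- numeric(6)
  sR <- hp[4]^2 * R
  gr[1] <- -0.5 * sum(A * (sR * (D[[1]] / hp[1]^2)))
  gr[2] <- -0.5 * sum(A * (sR * (D[[2]] / hp[2]^2)))
  gr[3] <- -0.5 * sum(A * (sR * (D[[3]] / hp[3]^2)))
  gr[4] <- -0.5 * sum(A * (2 * sR))
  gr[5] <- -0.5 * sum(A * (2 * hp[5]^2 * G))
  gr[6] <- -0.5 * sum(diag(A)) * 2 * hp[6]^2
  list(value = nlml, gradient = gr)
}

scan_design <- function(scans) {
  cbind(pma = scans$pma_scan_weeks, pnd = scans$postnatal_days,
        male = sex_to_male(scans$sex))
}

#' Fit a Gaussian-process normative curve for one region
#'
#' Models a regional volume as a function of postmenstrual age at scan,
#' postnatal days and sex with a Gaussian process whose covariance is the
#' sum of an anisotropic RBF kernel over the three covariates, a linear
#' kernel in centred PMA, and white observation noise. Hyperparameters
#' (three length-scales, signal SD, linear-weight SD, noise SD) are chosen
#' to maximise the log marginal likelihood via multi-start L-BFGS-B on the
#' log scale. The predictive SD returned by [predict.gp_region()] is that
#' of a new observation (latent variance plus observation noise), so
#' deviation Z-scores of typical held-out infants are approximately
#' standard normal.
#'
#' @param train scan table (see [simulate_normative()]) containing the
#'   region column; rows with missing volume or covariates are dropped.
#' @param region region label (a column of `train`).
#' @param control a [gp_control()] list.
#' @param fixed optional named vector of hyperparameters
#'   (`len_pma, len_pnd, len_sex, sf, wl, sn`, natural scale). When given,
#'   optimisation is bypassed and the GP posterior is computed at these
#'   values.
#' @return object of class `gp_region` with `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate`, `plot` and `logLik` methods.
#' @export
fit_region_model <- function(train, region, control = gp_control(),
                             fixed = NULL) {
  if (!region %in% names(train)) {
    stop("region column not found in training table: ", region,
         call. = FALSE)
  }
  X <- scan_design(train)
  y <- train[[region]]
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (nrow(X) < control$min_n) {
    stop(sprintf("region '%s': %d complete rows < minimum %d", region,
                 nrow(X), control$min_n), call. = FALSE)
  }
  if (control$scale == "log") y <- log(y)
  ybar <- mean(y)
  yc <- y - ybar
  sdy <- max(stats::sd(yc), 1e-3)

  D <- sq_dists(X, X)
  G <- outer(X[, 1] - 40, X[, 1] - 40)

  if (is.null(fixed)) {
    base <- log(c(len_pma = 4, len_pnd = 20, len_sex = 1,
                  sf = sdy / 2, wl = sdy / 4, sn = sdy / 2))
    lower <- log(c(0.25, 1, 0.1, sdy * 1e-4, sdy * 1e-5, sdy * 1e-3))
    upper <- log(c(200, 1000, 50, sdy * 50, sdy * 20, sdy * 20))
    fits <- with_seed(control$seed, lapply(seq_len(control$restarts),
      function(k) {
        init <- pmin(pmax(base + if (k == 1) 0 else stats::runif(6, -1, 1),
                          lower), upper)
        stats::optim(init, fn = function(p) gp_nlml(p, X, yc, D, G)$value,
                     gr = function(p) gp_nlml(p, X, yc, D, G)$gradient,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = control$maxit))
      }))
    vals <- vapply(fits, `[[`, numeric(1), "value")
    noise <- vapply(fits, function(f) f$par[6], numeric(1))
    best <- order(vals, noise)[1]
    hp <- exp(fits[[best]]$par)
    names(hp) <- hyper_names
    convergence <- fits[[best]]$convergence
  } else {
    if (!all(hyper_names %in% names(fixed))) {
      stop("`fixed` must name all of: ", paste(hyper_names, collapse = ", "),
           call. = FALSE)
    }
    hp <- fixed[hyper_names]
    convergence <- 0L
  }
  if (any(hp[c("sf", "sn")] <= 0)) {
    stop("signal and noise SD hyperparameters must be positive",
         call. = FALSE)
  }

  K <- kern(hp, X, X, noise = TRUE) + diag(1e-8, nrow(X))
  U <- chol(K)
  alpha <- backsolve(U, forwardsolve(t(U), yc))
  lml <- -(0.5 * sum(yc * alpha) + sum(log(diag(U))) +
             0.5 * length(yc) * log(2 * pi))

  structure(list(region = region, hyperparams = hp, X = X, y = y,
                 ybar = ybar, alpha = alpha, U = U, lml = lml,
                 scale = control$scale,
                 ranges = list(pma = range(X[, 1]), pnd = range(X[, 2])),
                 margin = control$margin, strict = control$strict,
                 n = length(y), convergence = convergence),
            class = "gp_region")
}

check_range <- function(object, pma) {
  lo <- object$ranges$pma[1] - object$margin
  hi <- object$ranges$pma[2] + object$margin
  out <- pma < lo | pma > hi
  if (any(out, na.rm = TRUE)) {
    msg <- sprintf(
      "%d prediction point(s) outside the supported PMA range [%.2f, %.2f]",
      sum(out, na.rm = TRUE), lo, hi)
    if (object$strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
}

#' Predictive mean and SD from a fitted normative curve
#'
#' @param object a `gp_region` fit.
#' @param newdata data.frame with columns `pma_scan_weeks`,
#'   `postnatal_days`, `sex`.
#' @param ... unused.
#' @return data.frame with `mu_pred` and `sigma_pred` (observation scale;
#'   `sigma_pred` includes the learned observation-noise SD).
#' @export
predict.gp_region <- function(object, newdata, ...) {
  Xs <- scan_design(newdata)
  check_range(object, Xs[, 1])
  Ks <- kern(object$hyperparams, object$X, Xs)
  v <- forwardsolve(t(object$U), Ks)
  mu <- drop(crossprod(Ks, object$alpha)) + object$ybar
  kss <- object$hyperparams["sf"]^2 +
    object$hyperparams["wl"]^2 * (Xs[, 1] - 40)^2
  var_lat <- pmax(kss - colSums(v^2), 0)
  data.frame(mu_pred = mu,
             sigma_pred = sqrt(var_lat + object$hyperparams["sn"]^2))
}

#' Deviation Z-scores of scans against a fitted normative curve
#'
#' The Z-score is the observed volume minus the predictive mean, divided by
#' the predictive SD: the individual deviation from the normative
#' expectation given PMA at scan, postnatal days and sex. A missing volume
#' propagates to a missing Z without failing.
#'
#' @param model a `gp_region` fit.
#' @param scans scan table containing the model's region column.
#' @return data.frame: subject_id, timepoint, region, observed, mu_pred,
#'   sigma_pred, z.
#' @export
deviation_z <- function(model, scans) {
  pr <- predict(model, scans)
  obs <- scans[[model$region]]
  if (is.null(obs)) obs <- rep(NA_real_, nrow(scans))
  ob <- if (model$scale == "log") log(obs) else obs
  data.frame(subject_id = scans$subject_id, timepoint = scans$timepoint,
             region = model$region, observed = obs, mu_pred = pr$mu_pred,
             sigma_pred = pr$sigma_pred,
             z = (ob - pr$mu_pred) / pr$sigma_pred,
             stringsAsFactors = FALSE)
}

#' Fit normative curves for all modelled regions
#'
#' @param train normative scan table.
#' @param regions region set (default the 13 modelled regions).
#' @param control a [gp_control()]; per-region fits use seeds derived from
#'   `control$seed` so a refit with the same seed is identical.
#' @return object of class `gp_normative`: a named list of `gp_region`
#'   fits. Per-region failures are collected and reported together.
#' @export
fit_all_regions <- function(train, regions = modelled_regions(),
                            control = gp_control()) {
  missing_cols <- setdiff(regions, names(train))
  if (length(missing_cols)) {
    stop("training table lacks region column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fits <- vector("list", length(regions))
  names(fits) <- regions
  errs <- character()
  for (i in seq_along(regions)) {
    ctl <- control
    ctl$seed <- control$seed + i
    fits[[i]] <- tryCatch(fit_region_model(train, regions[i], ctl),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      errs <- c(errs, sprintf("%s: %s", regions[i],
                              conditionMessage(fits[[i]])))
    }
  }
  if (length(errs)) {
    stop("normative fitting failed for ", length(errs), " region(s):\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  structure(fits, class = "gp_normative", control = control)
}

#' Score a scan table against a set of fitted normative curves
#'
#' @param models a `gp_normative` object.
#' @param scans scan table; regions absent from `scans` are scored as
#'   missing.
#' @return long data.frame of deviation scores (one row per scan x region).
#' @export
score_scans <- function(models, scans) {
  out <- do.call(rbind, lapply(unclass(models), deviation_z, scans = scans))
  rownames(out) <- NULL
  out
}

#' Normative centile-curve table
#'
#' Evaluates a fitted region curve on a dense PMA grid for each sex,
#' exporting mean and the +/-1, 2, 3 SD bands that define the normative
#' envelope. Postnatal days are set to their value for birth at `ga_ref`
#' weeks (a typical term gestation).
#'
#' @param model a `gp_region` fit.
#' @param pma grid of postmenstrual ages (weeks); points outside the
#'   model's supported range (training range plus margin) are dropped.
#' @param ga_ref reference gestational age at birth used to derive
#'   postnatal days along the grid.
#' @return data.frame: region, sex, pma_scan_weeks, mu, and columns
#'   `lo3,lo2,lo1,hi1,hi2,hi3`.
#' @export
centile_table <- function(model, pma = seq(37, 45, by = 0.25),
                          ga_ref = 40) {
  pma <- pma[pma >= model$ranges$pma[1] - model$margin &
               pma <= model$ranges$pma[2] + model$margin]
  do.call(rbind, lapply(c("F", "M"), function(sx) {
    nd <- data.frame(pma_scan_weeks = pma,
                     postnatal_days = pmax(0, round(7 * (pma - ga_ref))),
                     sex = sx)
    pr <- predict(model, nd)
    data.frame(region = model$region, sex = sx, pma_scan_weeks = pma,
               mu = pr$mu_pred,
               lo3 = pr$mu_pred - 3 * pr$sigma_pred,
               lo2 = pr$mu_pred - 2 * pr$sigma_pred,
               lo1 = pr$mu_pred - pr$sigma_pred,
               hi1 = pr$mu_pred + pr$sigma_pred,
               hi2 = pr$mu_pred + 2 * pr$sigma_pred,
               hi3 = pr$mu_pred + 3 * pr$sigma_pred,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.gp_region <- function(x, ...) {
  cat(sprintf("Gaussian-process normative curve: %s (%s scale)\n",
              x$region, x$scale))
  cat(sprintf("  n = %d; PMA range %.1f-%.1f weeks; log marginal lik %.2f\n",
              x$n, x$ranges$pma[1], x$ranges$pma[2], x$lml))
  cat("  hyperparameters:\n")
  print(round(x$hyperparams, 4))
  invisible(x)
}

#' @export
coef.gp_region <- function(object, ...) object$hyperparams

#' @export
logLik.gp_region <- function(object, ...) {
  structure(object$lml, df = length(object$hyperparams), nobs = object$n,
            class = "logLik")
}

#' @export
residuals.gp_region <- function(object, ...) {
  nd <- data.frame(pma_scan_weeks = object$X[, 1],
                   postnatal_days = object$X[, 2],
                   sex = c("F", "M")[object$X[, 3] + 1])
  pr <- predict(object, nd)
  (object$y - pr$mu_pred) / pr$sigma_pred
}

#' @export
summary.gp_region <- function(object, ...) {
  r <- residuals(object)
  out <- list(region = object$region, n = object$n,
              hyperparams = object$hyperparams, lml = object$lml,
              train_z_mean = mean(r), train_z_sd = stats::sd(r),
              ranges = object$ranges)
  class(out) <- "summary.gp_region"
  out
}

#' @export
print.summary.gp_region <- function(x, ...) {
  cat(sprintf("Region %s: n=%d, LML=%.2f, training-Z mean %.3f sd %.3f\n",
              x$region, x$n, x$lml, x$train_z_mean, x$train_z_sd))
  print(round(x$hyperparams, 4))
  invisible(x)
}

#' @export
simulate.gp_region <- function(object, nsim = 1, seed = NULL, newdata,
                               ...) {
  with_seed(seed, {
    pr <- predict(object, newdata)
    out <- replicate(nsim,
                     stats::rnorm(nrow(newdata), pr$mu_pred, pr$sigma_pred))
    as.data.frame(out)
  })
}

#' @export
plot.gp_region <- function(x, pma = seq(37, 45, by = 0.1), ...) {
  ct <- centile_table(x, pma = pma)
  for (sx in c("F", "M")) {
    d <- ct[ct$sex == sx, ]
    graphics::plot(d$pma_scan_weeks, d$mu, type = "n",
                   ylim = range(d$lo3, d$hi3),
                   xlab = "Postmenstrual age (weeks)",
                   ylab = sprintf("%s volume", x$region),
                   main = sprintf("%s (%s)", x$region, sx), ...)
    for (k in 3:1) {
      graphics::polygon(c(d$pma_scan_weeks, rev(d$pma_scan_weeks)),
                        c(d[[paste0("lo", k)]], rev(d[[paste0("hi", k)]])),
                        col = grDevices::grey(0.95 - 0.07 * (3 - k)),
                        border = NA)
    }
    graphics::lines(d$pma_scan_weeks, d$mu, lwd = 2)
    pts <- x$X[, 3] == (sx == "M")
    graphics::points(x$X[pts, 1], x$y[pts], pch = 16, cex = 0.5)
  }
  invisible(ct)
}

#' @export
print.gp_normative <- function(x, ...) {
  cat(sprintf("Normative model set: %d regions\n", length(x)))
  for (m in unclass(x)) {
    cat(sprintf("  %-14s n=%d  LML=%.1f  noise SD=%.3g\n", m$region, m$n,
                m$lml, m$hyperparams["sn"]))
  }
  invisible(x)
}

# --- serialization -----------------------------------------------------

# order-sensitive polynomial hash of serialized data, for provenance
data_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  b <- b[seq(1, length(b), by = max(1L, length(b) %/% 4096))]
  h <- 0
  for (v in b) h <- (h * 131 + v + 7) %% 2147483647
  sprintf("%08x", h)
}

#' Save / load fitted normative curves as JSON
#'
#' The JSON stores, per region, the kernel family, hyperparameters,
#' training covariates and volumes, ranges, and a training-data hash;
#' solve artifacts are re-derived on load by refitting with the stored
#' hyperparameters fixed.
#'
#' @param models a `gp_normative` object.
#' @param path JSON file path.
#' @return `write_models_json` returns `path` invisibly;
#'   `read_models_json` returns a `gp_normative` object.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(unclass(models), function(m) {
    list(region = m$region, kernel = "rbf(pma,pnd,sex)+linear(pma)+noise",
         scale = m$scale, hyperparams = as.list(m$hyperparams),
         ranges = m$ranges, margin = m$margin, strict = m$strict,
         n = m$n,
         train_hash = data_hash(lapply(list(m$X, m$y), signif, digits = 10)),
         X = apply(m$X, 2, identity, simplify = FALSE), y = m$y)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(payload, function(p) {
    train <- data.frame(pma_scan_weeks = p$X$pma,
                        postnatal_days = p$X$pnd,
                        sex = c("F", "M")[p$X$male + 1])
    train[[p$region]] <- if (p$scale == "log") exp(p$y) else p$y
    ctl <- gp_control(min_n = 1, margin = p$margin, strict = p$strict,
                      scale = p$scale)
    m <- fit_region_model(train, p$region, control = ctl,
                          fixed = unlist(p$hyperparams))
    if (data_hash(lapply(list(m$X, m$y), signif, digits = 10)) !=
          p$train_hash) {
      warning("training-data hash mismatch for region ", p$region,
              call. = FALSE)
    }
    m
  })
  names(fits) <- vapply(payload, `[[`, character(1), "region")
  structure(fits, class = "gp_normative")
}
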