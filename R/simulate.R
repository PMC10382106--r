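#' Growth-curve parameters for one simulated region
#'
#' The synthetic cohort generator draws each regional volume around a smooth
#' quadratic mean curve in postmenstrual age (PMA, weeks), with a male sex
#' offset, a postnatal-days effect, and heteroscedastic Gaussian noise whose
#' SD changes linearly with PMA. All parameters are configuration constants
#' chosen to give plausible neonatal volumes; they are not estimates.
#'
#' The mean at covariates (pma, pnd, male) is
#' \deqn{a + b (pma - 40) + c (pma - 40)^2 + s \cdot male + d \cdot pnd}
#' and the residual SD is \eqn{\sigma_0 (1 + \kappa (pma - 40))}.
#'
#' @param region region label.
#' @param a intercept volume at 40 weeks PMA (mL).
#' @param b linear PMA slope (mL/week).
#' @param c quadratic PMA term (mL/week^2).
#' @param s additive male offset (mL).
#' @param d postnatal-days effect (mL/day).
#' @param sigma0 residual SD at 40 weeks (mL); may be 0 for noise-free
#'   simulations.
#' @param kappa fractional SD change per week of PMA (unitless).
#' @return an object of class `growth_curve_params`.
#' @export
growth_curve_params <- function(region, a, b, c = 0, s = 0, d = 0,
                                sigma0 = 1, kappa = 0) {
  p <- list(region = as.character(region), a = a, b = b, c = c, s = s, d = d,
            sigma0 = sigma0, kappa = kappa)
  if (sigma0 < 0) stop("sigma0 must be >= 0", call. = FALSE)
  pma <- seq(37, 45, by = 0.25)
  if (sigma0 > 0 && any(sigma0 * (1 + kappa * (pma - 40)) <= 0)) {
    stop(sprintf("region '%s': residual SD non-positive within PMA 37-45",
                 region), call. = FALSE)
  }
  # mean is linear in pnd and male, so corners of the covariate box suffice
  grid <- expand.grid(pma = pma, pnd = c(0, 56), male = c(0, 1))
  mu <- curve_mean(p, grid$pma, grid$pnd, grid$male)
  if (any(mu <= 0)) {
    stop(sprintf("region '%s': mean curve non-positive on covariate range",
                 region), call. = FALSE)
  }
  class(p) <- "growth_curve_params"
  p
}

curve_mean <- function(p, pma, pnd, male) {
  p$a + p$b * (pma - 40) + p$c * (pma - 40)^2 + p$s * male + p$d * pnd
}

curve_sd <- function(p, pma) {
  p$sigma0 * (1 + p$kappa * (pma - 40))
}

#' Default synthetic growth curves
#'
#' Documented constants giving plausible regional volumes for term neonates
#' between 37 and 45 weeks PMA (total tissue around 360 mL at 40 weeks).
#' A common heteroscedasticity coefficient is used across regions so that
#' the total-tissue residual SD (the root-sum-of-squares of its independent
#' components) keeps the same linear-in-PMA form.
#'
#' @return named list of [growth_curve_params()] for every simulated region.
#' @export
default_curve_params <- function() {
  k <- 0.03
  spec <- list(
    cortical_gm    = c(160,  12,   0.20, 6.0,  0.100, 14.0),
    white_matter   = c(145,   6,   0.10, 6.0,  0.050, 12.0),
    cerebellum     = c(22,    1.8, 0.05, 0.8,  0.020,  2.2),
    brainstem      = c(6.5,   0.35, 0.01, 0.25, 0.005, 0.55),
    deep_gm_total  = c(24,    1.2, 0.02, 0.8,  0.010,  1.8),
    hippo_amygdala = c(4.2,   0.25, 0.005, 0.15, 0.003, 0.40),
    csf            = c(45,    2.5, 0.10, 2.0,  0.080,  9.0),
    ventricles     = c(3.2,   0.15, 0.010, 0.15, 0.004, 0.90),
    caudate_l      = c(4.0,   0.22, 0.004, 0.12, 0.002, 0.38),
    caudate_r      = c(4.0,   0.22, 0.004, 0.12, 0.002, 0.38),
    lentiform_l    = c(4.6,   0.26, 0.004, 0.14, 0.002, 0.42),
    lentiform_r    = c(4.6,   0.26, 0.004, 0.14, 0.002, 0.42),
    thalamus_l     = c(5.2,   0.30, 0.005, 0.16, 0.002, 0.45),
    thalamus_r     = c(5.2,   0.30, 0.005, 0.16, 0.002, 0.45)
  )
  out <- lapply(names(spec), function(r) {
    v <- spec[[r]]
    growth_curve_params(r, a = v[1], b = v[2], c = v[3], s = v[4], d = v[5],
                        sigma0 = v[6], kappa = k)
  })
  names(out) <- names(spec)
  out
}

check_params <- function(params) {
  need <- simulated_regions()
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing growth-curve parameters for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params
}

# Effective total-tissue curve: mean coefficients add across components;
# the SD is the root-sum-of-squares of independent component SDs.
ttv_mean <- function(params, pma, pnd, male) {
  Reduce(`+`, lapply(params[ttv_components()], curve_mean,
                     pma = pma, pnd = pnd, male = male))
}

ttv_sd <- function(params, pma) {
  sqrt(Reduce(`+`, lapply(params[ttv_components()],
                          function(p) curve_sd(p, pma)^2)))
}

#' Normative mean and SD of any modelled region under a simulator
#' configuration
#'
#' @param params named list of [growth_curve_params()] (see
#'   [default_curve_params()]).
#' @param region one of [modelled_regions()] or a simulated component.
#' @param pma,pnd numeric vectors of postmenstrual age (weeks) and postnatal
#'   days.
#' @param sex `"F"`/`"M"` (or 0/1) vector.
#' @return data.frame with columns `mu` (mL) and `sd` (mL).
#' @export
curve_mean_sd <- function(params, region, pma, pnd, sex) {
  check_params(params)
  male <- sex_to_male(sex)
  if (region == "total_tissue") {
    data.frame(mu = ttv_mean(params, pma, pnd, male),
               sd = ttv_sd(params, pma))
  } else {
    p <- params[[region]]
    if (is.null(p)) stop("unknown region: ", region, call. = FALSE)
    data.frame(mu = curve_mean(p, pma, pnd, male), sd = curve_sd(p, pma))
  }
}

sex_to_male <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex != 0))
  m <- toupper(as.character(sex))
  out <- ifelse(m %in% c("M", "MALE", "1"), 1,
                ifelse(m %in% c("F", "FEMALE", "0"), 0, NA_real_))
  if (anyNA(out)) stop("unknown sex code(s): ",
                       paste(unique(sex[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  out
}

new_scan_table <- function(ids, vols) {
  stopifnot(identical(names(ids), scan_id_cols()))
  cols <- c(setdiff(modelled_regions(), "total_tissue"),
            "deep_gm_total", "hippo_amygdala")
  vols <- vols[cols]
  vols$total_tissue <- Reduce(`+`, vols[ttv_components()])
  cbind(as.data.frame(ids, stringsAsFactors = FALSE),
        as.data.frame(vols)[c("total_tissue", setdiff(names(vols), "total_tissue"))])
}

#' Simulate a normative (healthy term) cohort
#'
#' One scan per infant. Gestational age at birth is drawn from a truncated
#' normal calibrated to a term cohort (median 40.1 weeks, IQR 39.1-41), PMA
#' at scan uniformly over the supported window \[37, 45\] weeks (never before
#' birth), sex is Bernoulli(0.5), and postnatal days are derived as
#' `round(7 * (pma - ga_birth))`. Each simulated regional volume is its mean
#' curve plus heteroscedastic Gaussian noise; total tissue volume is the sum
#' of its six components, never drawn independently.
#'
#' @param params named list of [growth_curve_params()].
#' @param n number of infants (default 219, a typical normative reference
#'   cohort size).
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with one row per infant: `r paste(scan_id_cols(),
#'   collapse = ", ")` followed by regional volumes in mL.
#' @export
simulate_normative <- function(params = default_curve_params(), n = 219,
                               seed = 1) {
  stopifnot_scalar_count(n)
  check_params(params)
  with_seed(seed, {
    ga <- round(stats::qnorm(stats::runif(n, stats::pnorm(37, 40.1, 1.41),
                                          stats::pnorm(42.5, 40.1, 1.41)),
                             40.1, 1.41), 2)
    pma <- round(stats::runif(n, pmax(37, ga), 45), 2)
    pnd <- pmax(0L, as.integer(round(7 * (pma - ga))))
    male <- stats::rbinom(n, 1, 0.5)
    vols <- lapply(params[simulated_regions()], function(p) {
      curve_mean(p, pma, pnd, male) + curve_sd(p, pma) * stats::rnorm(n)
    })
    ids <- list(subject_id = sprintf("N%03d", seq_len(n)),
                group = rep("normative", n),
                sex = c("F", "M")[male + 1L],
                ga_birth_weeks = ga,
                pma_scan_weeks = pma,
                postnatal_days = pnd,
                timepoint = rep("single", n))
    new_scan_table(ids, vols)
  })
}

#' Specify an injected effect on perioperative growth
#'
#' An effect spec displaces the true preoperative Z-score of the regions it
#' covers by `baseline_dev`, and contributes to the true pre-to-post Z
#' change (delta Z) a fixed `drift`, linear terms `beta` in named clinical
#' covariates, and Gaussian noise with SD `noise_sd`. Covariate terms are
#' applied relative to a reference exposure (see [covariate_refs()]):
#' `beta * (covariate - reference)`, so `drift` is the expected delta Z of
#' a typically-exposed infant and `beta` only spreads infants around it.
#' Several specs may cover the same region; their contributions add (noise
#' SDs add in quadrature).
#'
#' @param regions character vector of simulated regions the effect applies
#'   to. Effects on `total_tissue` cannot be injected directly: total tissue
#'   is a sum, and inherits whatever its components are given.
#' @param baseline_dev mean preoperative Z displacement (Z units).
#' @param drift mean delta-Z displacement independent of covariates (Z
#'   units).
#' @param beta named numeric vector mapping covariate column to its
#'   coefficient on delta Z (Z units per covariate unit).
#' @param noise_sd residual SD of the delta-Z contribution (Z units).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(regions, baseline_dev = 0, drift = 0,
                        beta = numeric(), noise_sd = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(beta) && is.null(names(beta)))
    stop("beta must be a named vector of covariate coefficients",
         call. = FALSE)
  bad <- setdiff(regions, simulated_regions())
  if (length(bad)) {
    stop("effect_spec regions not simulated: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(regions = regions, baseline_dev = baseline_dev,
                 drift = drift, beta = beta, noise_sd = noise_sd),
            class = "effect_spec")
}

#' Reference exposures for centred covariate effects
#'
#' The typical (median) value of each clinical covariate in the emulated
#' surgical cohort; injected covariate effects act on deviations from
#' these references. Covariates without a documented reference use 0.
#'
#' @return named numeric vector.
#' @export
covariate_refs <- function() {
  c(age_surgery_days = 12, bypass_min = 153, arrest_min = 0,
    picu_days = 4, ventilation_days = 3, inotrope_days = 3,
    creatinine_umol_l = 39, age_creatinine_days = 10, rrt = 0, nec = 0)
}

#' Default injected clinical effects for the synthetic surgical cohort
#'
#' The defaults emulate, qualitatively, the pattern reported for infants
#' with congenital heart disease: tissue volumes sit below the normative
#' mean before surgery and CSF above it; growth slows across most tissue
#' regions after surgery (region-specific drifts); longer intensive-care
#' stay slows growth of cortical gray matter, white matter, cerebellum,
#' brainstem and left thalamus (total tissue inherits these); longer bypass
#' affects brainstem and right caudate; higher preoperative creatinine
#' affects brainstem, both caudate nuclei and right thalamus; later surgery
#' affects brainstem and right lentiform.
#'
#' @return list of [effect_spec()].
#' @export
default_effect_specs <- function() {
  tissue <- c("cortical_gm", "white_matter", "cerebellum", "brainstem",
              "deep_gm_total", "hippo_amygdala",
              "caudate_l", "caudate_r", "lentiform_l", "lentiform_r",
              "thalamus_l", "thalamus_r")
  drifts <- c(cortical_gm = -0.30, white_matter = -0.10, cerebellum = -0.65,
              brainstem = -0.75, deep_gm_total = -0.10,
              hippo_amygdala = -0.10, caudate_l = 0.03, caudate_r = -0.07,
              lentiform_l = 0.30, lentiform_r = -0.15, thalamus_l = -0.09,
              thalamus_r = -0.26)
  c(list(effect_spec(tissue, baseline_dev = -0.8, noise_sd = 0.35),
         effect_spec("csf", baseline_dev = 0.8, drift = -0.5,
                     noise_sd = 0.35),
         effect_spec("ventricles", baseline_dev = 0.4, drift = 0.07,
                     noise_sd = 0.35)),
    lapply(names(drifts), function(r) effect_spec(r, drift = drifts[[r]])),
    list(
      effect_spec(c("cortical_gm", "white_matter", "cerebellum",
                    "brainstem", "thalamus_l"),
                  beta = c(picu_days = -0.10)),
      effect_spec(c("brainstem", "caudate_r"),
                  beta = c(bypass_min = -0.004)),
      effect_spec(c("brainstem", "caudate_l", "caudate_r", "thalamus_r"),
                  beta = c(creatinine_umol_l = -0.02)),
      effect_spec(c("brainstem", "lentiform_r"),
                  beta = c(age_surgery_days = -0.03))
    ))
}

draw_chd_covariates <- function(n) {
  surg <- pmax(2, round(rlnorm_iqr(n, 12, 7, 14.25, lo = 1, hi = 45)))
  data.frame(
    subject_id = sprintf("C%03d", seq_len(n)),
    age_surgery_days = surg,
    bypass_min = round(rlnorm_iqr(n, 153, 128, 162, lo = 40, hi = 400)),
    arrest_min = ifelse(stats::rbinom(n, 1, 0.25) == 1,
                        round(rlnorm_iqr(n, 10, 6, 18, lo = 2, hi = 60)), 0),
    picu_days = round(rlnorm_iqr(n, 4, 3, 5, lo = 1, hi = 40), 1),
    ventilation_days = round(rlnorm_iqr(n, 3, 2, 4, lo = 0.5, hi = 30), 1),
    inotrope_days = round(rlnorm_iqr(n, 3, 2, 4, lo = 0.5, hi = 30), 1),
    rrt = stats::rbinom(n, 1, 6 / 36),
    nec = stats::rbinom(n, 1, 4 / 36),
    creatinine_umol_l = round(rlnorm_iqr(n, 39, 34, 46, lo = 15, hi = 120)),
    age_creatinine_days = pmax(1, surg - sample(1:3, n, replace = TRUE)),
    chd_category = sample(c("streaming", "left", "right"), n, replace = TRUE,
                          prob = c(20, 12, 4) / 36),
    injury_pre = stats::rbinom(n, 1, 17 / 36),
    injury_post = stats::rbinom(n, 1, 24 / 36),
    weight_z_pre = round(stats::rnorm(n, 0.1, 1), 2),
    weight_z_post = NA_real_,
    hc_z_pre = round(stats::rnorm(n, 0.3, 1), 2),
    hc_z_post = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a surgical (CHD) cohort with paired pre/post scans and ground
#' truth
#'
#' Each infant receives a preoperative and a postoperative scan. Scan and
#' surgery timing, bypass and circulatory-arrest minutes, intensive-care and
#' support durations, renal-replacement and necrotising-enterocolitis flags,
#' creatinine and CHD category are drawn from right-skewed (log-normal) or
#' Bernoulli distributions calibrated to the demographic envelope of a
#' neonatal surgical cohort. True preoperative Z-scores are
#' Normal(baseline, 1) per region; the true pre-to-post change is the sum of
#' the configured effects plus noise; and observed volumes are reconstructed
#' from the true Z-scores through the generating curves, so the generator
#' and the scoring model agree by construction. Total tissue volume is
#' always the component sum, and its true Z-scores are the ones implied by
#' that sum.
#'
#' @inheritParams simulate_normative
#' @param effects list of [effect_spec()].
#' @param n number of infants (default 36).
#' @return list with elements `scans` (2n rows), `covariates` (n rows) and
#'   `truth` (long data.frame: subject_id, region, z_pre, z_post, delta_z
#'   for all 13 modelled regions, with the generating parameters attached as
#'   attribute `params`).
#' @export
simulate_chd <- function(params = default_curve_params(),
                         effects = default_effect_specs(), n = 36,
                         seed = 1) {
  stopifnot_scalar_count(n)
  check_params(params)
  stopifnot(all(vapply(effects, inherits, logical(1), "effect_spec")))

  with_seed(seed, {
    cov <- draw_chd_covariates(n)
    bad_beta <- setdiff(unique(unlist(lapply(effects, function(e) names(e$beta)))),
                        names(cov))
    if (length(bad_beta)) {
      stop("effect covariate(s) not in covariate table: ",
           paste(bad_beta, collapse = ", "), call. = FALSE)
    }

    ga <- round(stats::qnorm(stats::runif(n, stats::pnorm(37, 38.5, 0.67),
                                          stats::pnorm(41, 38.5, 0.67)),
                             38.5, 0.67), 2)
    # scan timing: pre scan strictly before surgery, post scan after it,
    # post PMA below the 46-week ceiling; the log-normal draws are
    # truncated to keep every subject consistent with these constraints
    cov$age_surgery_days <- pmin(cov$age_surgery_days,
                                 pmax(3, floor(7 * (46 - ga)) - 4L))
    cov$age_creatinine_days <- pmin(cov$age_creatinine_days,
                                    cov$age_surgery_days)
    pre_day <- pmin(pmax(1, round(rlnorm_iqr(n, 5, 2.75, 7))),
                    cov$age_surgery_days - 1L)
    gap <- pmax(2, round(rlnorm_iqr(n, 8, 6.75, 11.25)))
    gap_max <- pmax(2, floor(7 * (45.99 - ga)) - cov$age_surgery_days)
    post_day <- cov$age_surgery_days + pmin(gap, gap_max)
    male <- stats::rbinom(n, 1, 19 / 36)
    pma_pre <- round(ga + pre_day / 7, 2)
    pma_post <- round(ga + post_day / 7, 2)

    # true per-region Z-scores
    regs <- simulated_regions()
    z_pre <- dz <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
    base <- drift <- noise_var <- stats::setNames(numeric(length(regs)), regs)
    lin <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
    for (e in effects) {
      base[e$regions] <- base[e$regions] + e$baseline_dev
      drift[e$regions] <- drift[e$regions] + e$drift
      noise_var[e$regions] <- noise_var[e$regions] + e$noise_sd^2
      if (length(e$beta)) {
        refs <- covariate_refs()[names(e$beta)]
        refs[is.na(refs)] <- 0
        centred <- sweep(as.matrix(cov[names(e$beta)]), 2, refs)
        lin[, e$regions] <- lin[, e$regions] + as.vector(centred %*% e$beta)
      }
    }
    for (r in regs) {
      z_pre[, r] <- stats::rnorm(n, base[r], 1)
      dz[, r] <- drift[r] + lin[, r] +
        stats::rnorm(n, 0, sqrt(noise_var[r]))
    }
    z_post <- z_pre + dz

    vol_at <- function(z, pma, pnd) {
      out <- lapply(regs, function(r) {
        p <- params[[r]]
        curve_mean(p, pma, pnd, male) + z[, r] * curve_sd(p, pma)
      })
      names(out) <- regs
      out
    }
    vols_pre <- vol_at(z_pre, pma_pre, pre_day)
    vols_post <- vol_at(z_post, pma_post, post_day)

    mk_ids <- function(tp, pma, pnd) {
      list(subject_id = cov$subject_id, group = rep("chd", n),
           sex = c("F", "M")[male + 1L], ga_birth_weeks = ga,
           pma_scan_weeks = pma, postnatal_days = as.integer(pnd),
           timepoint = rep(tp, n))
    }
    scans <- rbind(new_scan_table(mk_ids("pre", pma_pre, pre_day), vols_pre),
                   new_scan_table(mk_ids("post", pma_post, post_day),
                                  vols_post))
    scans <- scans[order(scans$subject_id, scans$timepoint == "post"), ]
    rownames(scans) <- NULL

    # implied true Z for the summed total-tissue compartment
    zt_pre <- (scans$total_tissue[scans$timepoint == "pre"] -
                 ttv_mean(params, pma_pre, pre_day, male)) /
      ttv_sd(params, pma_pre)
    zt_post <- (scans$total_tissue[scans$timepoint == "post"] -
                  ttv_mean(params, pma_post, post_day, male)) /
      ttv_sd(params, pma_post)

    mreg <- modelled_regions()
    truth <- do.call(rbind, lapply(mreg, function(r) {
      if (r == "total_tissue") {
        data.frame(subject_id = cov$subject_id, region = r,
                   z_pre = zt_pre, z_post = zt_post,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(subject_id = cov$subject_id, region = r,
                   z_pre = z_pre[, r], z_post = z_post[, r],
                   stringsAsFactors = FALSE)
      }
    }))
    truth$delta_z <- truth$z_post - truth$z_pre
    rownames(truth) <- NULL
    attr(truth, "params") <- params

    # somatic growth tracks brain-tissue growth imperfectly
    mean_dz <- rowMeans(dz[, c("cortical_gm", "white_matter")])
    cov$weight_z_post <- round(cov$weight_z_pre +
                                 0.3 * mean_dz + stats::rnorm(n, -0.8, 0.6), 2)
    cov$hc_z_post <- round(cov$hc_z_pre +
                             0.3 * mean_dz + stats::rnorm(n, -0.6, 0.5), 2)
    cov$interscan_days <- as.integer(post_day - pre_day)
    cov$surgery_to_postmri_days <- as.integer(post_day - cov$age_surgery_days)

    list(scans = scans, covariates = cov, truth = truth)
  })
}

#' Score scans against the generating (true) curves
#'
#' Mainly for validation: returns the deviation Z-scores a perfect normative
#' model would produce, using the simulator's own mean and SD curves.
#'
#' @inheritParams curve_mean_sd
#' @param scans a scan table (see [simulate_normative()]).
#' @param regions regions to score (default the 13 modelled regions).
#' @return long data.frame: subject_id, timepoint, region, observed,
#'   mu_pred, sigma_pred, z.
#' @export
true_deviation_scores <- function(params, scans,
                                  regions = modelled_regions()) {
  check_params(params)
  do.call(rbind, lapply(regions, function(r) {
    ms <- curve_mean_sd(params, r, scans$pma_scan_weeks,
                        scans$postnatal_days, scans$sex)
    obs <- scans[[r]]
    data.frame(subject_id = scans$subject_id, timepoint = scans$timepoint,
               region = r, observed = obs, mu_pred = ms$mu,
               sigma_pred = ms$sd, z = (obs - ms$mu) / ms$sd,
               stringsAsFactors = FALSE)
  }))
}
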