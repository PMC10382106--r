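#' Standard-normal upper-tail probability
#'
#' Translates an extreme-deviation threshold into the tail probability it
#' corresponds to: a Z-score beyond +/-2.6 places an infant in the top or
#' bottom 0.5% of the typical population (`normal_tail(2.6)` is about
#' 0.0047), and the thresholds 2.3 and 1.65 likewise correspond to tail
#' levels 0.01 and 0.05.
#'
#' @param z numeric vector of thresholds / scores.
#' @return `P(Z > z)` for standard normal Z.
#' @export
normal_tail <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Classify a score against an extreme-deviation threshold
#'
#' Strict comparison: a score is flagged `"negative"` iff `z < -threshold`,
#' `"positive"` iff `z > threshold`, otherwise `"none"`. Values exactly at
#' the boundary are unflagged; non-finite scores give `NA`.
#'
#' @param z numeric vector of Z-scores or Z-slope changes.
#' @param threshold positive threshold (e.g. 1.65, 2.3, 2.6).
#' @return character vector in `{"negative", "none", "positive"}`.
#' @export
flag_extremes <- function(z, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  out <- ifelse(z > threshold, "positive",
                ifelse(z < -threshold, "negative", "none"))
  out[!is.finite(z)] <- NA_character_
  out
}

#' Pair pre- and post-operative deviation scores into growth trajectories
#'
#' For each subject and region, the Z-score slope change is
#' `delta_z = z_post - z_pre`: a negative value means growth slowed
#' relative to normative peers over the perioperative interval. Missing
#' scores in either scan (for instance regions excluded because injury
#' corrupted their segmentation) propagate to a missing `delta_z` without
#' dropping the subject's other regions.
#'
#' @param scores_pre,scores_post deviation-score tables as returned by
#'   [score_scans()] (columns subject_id, region, z).
#' @param thresholds positive thresholds at which to flag `delta_z`.
#' @return data.frame: subject_id, region, z_pre, z_post, delta_z, and a
#'   `flag_<threshold>` column per threshold.
#' @export
build_trajectories <- function(scores_pre, scores_post,
                               thresholds = c(1.65, 2.3, 2.6)) {
  for (nm in c("pre", "post")) {
    s <- if (nm == "pre") scores_pre else scores_post
    dup <- duplicated(s[c("subject_id", "region")])
    if (any(dup)) {
      stop(sprintf("duplicate %s-operative score rows for: %s", nm,
                   paste(unique(paste(s$subject_id[dup], s$region[dup],
                                      sep = "/")), collapse = ", ")),
           call. = FALSE)
    }
  }
  pre <- scores_pre[c("subject_id", "region", "z")]
  names(pre)[3] <- "z_pre"
  post <- scores_post[c("subject_id", "region", "z")]
  names(post)[3] <- "z_post"
  tr <- merge(pre, post, by = c("subject_id", "region"), all = TRUE)
  tr$delta_z <- tr$z_post - tr$z_pre
  for (th in sort(thresholds)) {
    tr[[sprintf("flag_%g", th)]] <- flag_extremes(tr$delta_z, th)
  }
  tr <- tr[order(tr$subject_id, tr$region), ]
  rownames(tr) <- NULL
  tr
}

#' Census of extreme deviations in growth trajectories
#'
#' Counts, at each threshold, the subjects with at least one flagged region
#' (counted once however many regions are flagged), the corresponding
#' percentage of the analysable cohort, and the breakdown by CHD category.
#' The denominator is the number of subjects with at least one non-missing
#' `delta_z` and is recorded in the output.
#'
#' @param trajectories output of [build_trajectories()].
#' @param thresholds positive thresholds, ascending.
#' @param categories optional named vector mapping subject_id to CHD
#'   category; subjects absent from the map are labelled `"unknown"` with a
#'   warning.
#' @return list of class `deviation_census`: `denominator`, and per
#'   threshold `count`, `percent`, and `by_category`.
#' @export
census <- function(trajectories, thresholds = c(1.65, 2.3, 2.6),
                   categories = NULL) {
  thresholds <- sort(thresholds)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  subjects <- unique(trajectories$subject_id[!is.na(trajectories$delta_z)])
  denom <- length(subjects)
  cat_map <- if (is.null(categories)) {
    stats::setNames(rep("unknown", denom), subjects)
  } else {
    m <- stats::setNames(unname(categories[subjects]), subjects)
    if (anyNA(m)) {
      warning("subject(s) missing from category map: ",
              paste(subjects[is.na(m)], collapse = ", "), call. = FALSE)
      m[is.na(m)] <- "unknown"
    }
    m
  }
  per <- lapply(thresholds, function(th) {
    fl <- flag_extremes(trajectories$delta_z, th)
    hit <- unique(trajectories$subject_id[!is.na(fl) & fl != "none"])
    list(threshold = th, count = length(hit),
         percent = if (denom > 0) 100 * length(hit) / denom else 0,
         by_category = as.list(table(cat_map[hit])))
  })
  names(per) <- sprintf("%g", thresholds)
  structure(list(denominator = denom, thresholds = per),
            class = "deviation_census")
}

#' @export
print.deviation_census <- function(x, ...) {
  cat(sprintf("Deviation census (denominator %d subjects)\n",
              x$denominator))
  for (p in x$thresholds) {
    bc <- paste(sprintf("%s=%d", names(p$by_category),
                        unlist(p$by_category)), collapse = ", ")
    cat(sprintf("  |dZ| > %-4g : %2d subjects (%.1f%%)%s\n", p$threshold,
                p$count, p$percent,
                if (nzchar(bc)) paste0("  [", bc, "]") else ""))
  }
  invisible(x)
}
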