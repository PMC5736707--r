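# Clone growth kinetics: absolute circulating cell counts, exponential
# fits, the mutation-reassignment MCMC, back-extrapolation to treatment
# start, and CCF rate/deceleration statistics.

#' Circulating cells carried by a clone
#'
#' Absolute clone size in peripheral blood: the product of the absolute
#' lymphocyte count (cells/µL), the blood volume (µL), the sample purity
#' and the clone's CCF.
#'
#' @param ccf Clone cancer cell fraction.
#' @param alc Absolute lymphocyte count, cells per microliter.
#' @param purity Sample purity (tumor fraction).
#' @param blood_volume_ul Blood volume in microliters (default 5 L).
#' @return Cell count.
#' @examples
#' clone_cell_count(0.5, 1e4, 0.9, 5e6)  # 2.25e10 cells
#' @export
clone_cell_count <- function(ccf, alc, purity, blood_volume_ul = 5e6) {
  stopifnot(all(ccf >= 0), all(alc >= 0), all(purity >= 0),
            blood_volume_ul >= 0)
  ccf * alc * purity * blood_volume_ul
}

#' Least-squares exponential growth fit
#'
#' Fits `ln(count) = ln(N0) + g * day` by ordinary least squares over
#' the timepoints with positive counts. With exactly two usable points
#' the fit is exact (R-squared 1) and flagged, since goodness of fit is
#' then uninformative.
#'
#' @param counts Cell counts per timepoint (zeros excluded with a
#'   warning).
#' @param days Days since treatment start.
#' @param conf Confidence level for the regression-theory interval.
#' @param quiet Suppress the zero-count warning.
#' @return Object of class `growth_fit`: `g` (per day), `ci_low`,
#'   `ci_high`, `r2`, `n_points`, `n0`, `n0_ci`, `two_point`.
#' @export
fit_exponential <- function(counts, days, conf = 0.95, quiet = FALSE) {
  stopifnot(length(counts) == length(days))
  keep <- which(counts > 0)
  if (length(keep) < length(counts) && !quiet) {
    warning("excluding ", length(counts) - length(keep),
            " timepoint(s) with zero count from exponential fit",
            call. = FALSE)
  }
  if (length(keep) < 2) {
    return(new_growth_fit(g = NA_real_, ci = c(NA_real_, NA_real_),
                          r2 = NA_real_, n_points = length(keep),
                          n0 = NA_real_, n0_ci = c(NA_real_, NA_real_),
                          two_point = FALSE))
  }
  x <- days[keep]; y <- log(counts[keep])
  fit <- lm(y ~ x)
  g <- unname(coef(fit)[2]); b0 <- unname(coef(fit)[1])
  n <- length(keep)
  r2 <- if (n == 2) 1 else {
    sst <- sum((y - mean(y))^2)
    if (sst < 1e-12) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  }
  if (n > 2) {
    # suppressed: summary.lm warns on noiseless (perfect-fit) input
    se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
    ci <- g + c(-1, 1) * tq * se[2]
    n0_ci <- exp(b0 + c(-1, 1) * tq * se[1])
  } else {
    ci <- c(g, g)
    n0_ci <- exp(c(b0, b0))
  }
  new_growth_fit(g = g, ci = ci, r2 = r2, n_points = n, n0 = exp(b0),
                 n0_ci = n0_ci, two_point = n == 2)
}

new_growth_fit <- function(g, ci, r2, n_points, n0, n0_ci, two_point,
                           clone_id = NA_integer_, method = "lsq") {
  structure(list(clone_id = clone_id, g = g, ci_low = ci[1], ci_high = ci[2],
                 r2 = r2, n_points = n_points, n0 = n0,
                 n0_ci = n0_ci, two_point = two_point, method = method),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (is.na(x$g)) {
    cat("growth fit: insufficient positive timepoints\n")
  } else {
    cat(sprintf(
      "growth rate %.4g/day [%.4g, %.4g], R2 = %.3f (%d points%s), N0 = %.4g\n",
      x$g, x$ci_low, x$ci_high, x$r2, x$n_points,
      if (x$two_point) ", two-point" else "", x$n0))
  }
  invisible(x)
}

#' Growth-rate inference by mutation-reassignment MCMC
#'
#' Clusters and the phylogeny are fixed; in each of `n_iter` iterations
#' every mutation is reassigned to a clone from a multinomial
#' distribution proportional to its grid-overlap likelihood under each
#' clone's consensus CCF posterior, clone CCF point estimates are
#' recomputed from the reassigned members, converted to circulating
#' cell counts and fitted with an exponential curve. Reported rates are
#' the posterior medians with 2.5/97.5 percentile credible intervals.
#' Clones whose consensus CCF never reaches `min_ccf` are excluded from
#' the output; singleton clusters fall back to a deterministic
#' regression on their own CCF point estimates.
#'
#' @param clusters A `clone_clusters` object.
#' @param tree The fixed `clone_tree` topology.
#' @param timeline Data.frame with `day`, `alc_per_ul`, `purity` for the
#'   patient's samples (timeline order must match the clustering).
#' @param n_iter MCMC iterations (default 10000).
#' @param seed Optional integer seed.
#' @param blood_volume_ul Blood volume in microliters.
#' @param min_ccf Minimum max-CCF for a clone to be reported (0.1).
#' @param draw_ccf Draw each clone's per-timepoint CCF from its
#'   member-product posterior within each iteration (default), so the
#'   read-count uncertainty of the cluster CCF propagates into the rate
#'   credible intervals; `FALSE` uses the posterior mode, making the
#'   chain vary only through mutation reassignment.
#' @param ccf_floor Detection floor on the CCF scale: within an
#'   iteration, timepoints where a clone's (exclusive) CCF falls below
#'   this value are treated as non-detections and excluded from that
#'   iteration's exponential fit (default 0.02, two grid steps; at the
#'   grid resolution a clone cannot be distinguished from absence).
#' @return List of `growth_fit` objects indexed by clone id, with the
#'   per-iteration rate draws attached as attribute `draws`.
#' @export
kinetics_mcmc <- function(clusters, tree, timeline, n_iter = 10000,
                          seed = NULL, blood_volume_ul = 5e6,
                          min_ccf = 0.1, draw_ccf = TRUE,
                          ccf_floor = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  cm <- clusters$cm
  K <- length(clusters$clusters)
  G <- length(ccf_grid())
  Tn <- length(clusters$sample_id)
  stopifnot(nrow(timeline) == Tn)
  scale_t <- timeline$alc_per_ul * timeline$purity * blood_volume_ul
  days <- timeline$day

  # membership likelihood of each mutation under each clone (grid dot
  # product per timepoint, multiplied over timepoints)
  W <- matrix(0, nrow(cm$prob), K)
  for (k in seq_len(K)) {
    probs <- clusters$clusters[[k]]$ccf_probs
    ll <- rep(0, nrow(cm$prob))
    for (t in seq_len(Tn)) {
      blk <- cm$prob[, ((t - 1) * G + 1):(t * G), drop = FALSE]
      ll <- ll + log(pmax(blk %*% probs[, t], 1e-300))
    }
    W[, k] <- ll
  }
  W <- exp(W - apply(W, 1, max))
  W <- W / rowSums(W)
  cumW <- t(apply(W, 1, cumsum))
  if (K == 1) cumW <- matrix(cumW, ncol = 1)

  parent0 <- unname(tree$parent) - 1L  # -1 encodes the germline parent
  res <- kinetics_chain(cm$logp, cumW, parent0, ccf_grid(), scale_t,
                        days, as.integer(n_iter), isTRUE(draw_ccf),
                        ccf_floor)

  keep <- vapply(clusters$clusters, function(cl) max(cl$ccf_point) >= min_ccf,
                 logical(1))
  if (any(!keep)) {
    message("excluding clone(s) ",
            paste(which(!keep), collapse = ", "),
            " with max CCF < ", min_ccf, " from kinetics output")
  }
  ex <- exclusive_ccf(tree)
  fits <- list()
  for (k in which(keep)) {
    cl <- clusters$clusters[[k]]
    if (cl$singleton) {
      # deterministic fallback: regression on the cluster's own CCF
      # point estimates (reassignment would dissolve a singleton)
      exk <- ifelse(ex[k, ] < ccf_floor, 0, ex[k, ])
      f <- fit_exponential(exk * scale_t, days, quiet = TRUE)
      f$clone_id <- cl$cluster_id
      f$method <- "singleton_regression"
      fits[[as.character(cl$cluster_id)]] <- f
      next
    }
    gk <- res$g[, k]; n0k <- res$n0[, k]; r2k <- res$r2[, k]
    if (all(is.na(gk))) {
      f <- new_growth_fit(NA_real_, c(NA_real_, NA_real_), NA_real_, 0L,
                          NA_real_, c(NA_real_, NA_real_), FALSE,
                          clone_id = cl$cluster_id, method = "mcmc")
    } else {
      qs <- quantile(gk, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
      n0q <- quantile(n0k, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
      npos <- sum(ex[k, ] * scale_t > 0)
      f <- new_growth_fit(qs[2], qs[c(1, 3)],
                          r2 = median(r2k, na.rm = TRUE),
                          n_points = npos, n0 = n0q[2],
                          n0_ci = n0q[c(1, 3)], two_point = npos == 2,
                          clone_id = cl$cluster_id, method = "mcmc")
      attr(f, "draws") <- gk
    }
    fits[[as.character(cl$cluster_id)]] <- f
  }
  fits
}

#' Back-extrapolate a clone size to treatment initiation
#'
#' Projects an exponentially growing (or shrinking) clone backwards:
#' `N0 = n_ref * exp(-g * t_ref)`, with the credible bounds of the rate
#' propagated to the size.
#'
#' @param fit A `growth_fit` (or any list with `g`, `ci_low`, `ci_high`).
#' @param t_ref Day of the reference measurement.
#' @param n_ref Cells at `t_ref`.
#' @return List with `n0`, `ci_low`, `ci_high` (cells at day 0).
#' @export
back_extrapolate <- function(fit, t_ref, n_ref) {
  g <- fit$g
  n0 <- n_ref * exp(-g * t_ref)
  bounds <- n_ref * exp(-c(fit$ci_low, fit$ci_high) * t_ref)
  list(n0 = n0, ci_low = min(bounds), ci_high = max(bounds))
}

#' CCF rate and deceleration statistics
#'
#' Splits each clone trajectory at the sample nearest `boundary` days
#' (a note is emitted when that sample is not at the boundary itself):
#' period-1 rate is |dCCF|/dt from baseline to the boundary sample,
#' period-2 from the boundary sample to the last sample within
#' `horizon`. Deceleration is the difference in absolute rates divided
#' by the difference of period midpoints, and concordance records
#' whether the signed changes agree in direction.
#'
#' @param ccf Clone CCF values per timepoint (single clone) or K x T
#'   matrix.
#' @param days Sample days.
#' @param boundary Day splitting the two periods (default 30).
#' @param horizon Last day considered (default 365).
#' @return Data.frame with `rate1`, `rate2` (per day, absolute),
#'   `deceleration` (per day^2), `concordant`, `boundary_day`.
#' @export
ccf_rate_stats <- function(ccf, days, boundary = 30, horizon = 365) {
  if (is.null(dim(ccf))) ccf <- matrix(ccf, nrow = 1)
  keep <- which(days <= horizon)
  ccf <- ccf[, keep, drop = FALSE]
  days <- days[keep]
  if (length(days) < 3) stop("need at least 3 timepoints within the horizon")
  ib <- which.min(abs(days - boundary))
  if (ib == 1) ib <- 2
  if (ib == length(days)) ib <- length(days) - 1
  tb <- days[ib]
  if (tb != boundary) {
    message("no sample at day ", boundary, "; using nearest sample at day ", tb)
  }
  t0 <- days[1]; tl <- days[length(days)]
  out <- do.call(rbind, lapply(seq_len(nrow(ccf)), function(k) {
    d1 <- ccf[k, ib] - ccf[k, 1]
    d2 <- ccf[k, length(days)] - ccf[k, ib]
    r1 <- abs(d1) / (tb - t0)
    r2 <- abs(d2) / (tl - tb)
    mid1 <- (t0 + tb) / 2
    mid2 <- (tb + tl) / 2
    data.frame(clone = k, rate1 = r1, rate2 = r2,
               deceleration = (r2 - r1) / (mid2 - mid1),
               concordant = sign(d1) == sign(d2),
               boundary_day = tb)
  }))
  rownames(out) <- NULL
  out
}
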