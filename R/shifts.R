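# Early clonal-shift detection. Per patient, the largest rising and
# falling clones between baseline and the latest pre-relapse sample are
# tested: the probability that the two-dimensional cluster CCF
# distribution lies within +/-0.1 of the diagonal (i.e. the clone did
# not move) is the test's null-band probability, and these are pooled
# across the cohort into one Benjamini-Hochberg family. A patient is
# called evolved when any of its tests has adjusted q below the cutoff
# and an absolute CCF change above the threshold.

#' Largest rising and falling clusters between two timepoints
#'
#' @param clusters A `clone_clusters` object.
#' @param t0,t1 Timepoint indices (into `clusters$sample_id`).
#' @return List with `rising` and `falling` cluster ids (`NA` when all
#'   changes share the opposite sign); ties go to the smaller cluster
#'   id. With a single cluster it is both candidates.
#' @export
max_shift_clusters <- function(clusters, t0, t1) {
  delta <- vapply(clusters$clusters,
                  function(cl) cl$ccf_point[t1] - cl$ccf_point[t0],
                  numeric(1))
  ids <- vapply(clusters$clusters, `[[`, integer(1), "cluster_id")
  if (length(delta) == 1) {
    return(list(rising = ids[1], falling = ids[1], delta = delta))
  }
  rising <- if (max(delta) > 0) ids[which.max(delta)] else NA_integer_
  falling <- if (min(delta) < 0) ids[which.min(delta)] else NA_integer_
  list(rising = rising, falling = falling, delta = setNames(delta, ids))
}

#' Probability that a clone stayed within the diagonal band
#'
#' Treats the cluster's CCF posteriors at the two timepoints as
#' independent marginals and sums the joint mass within `delta` of the
#' diagonal: `p = sum over (i, j) with |grid_i - grid_j| <= delta of
#' probs_t0[i] * probs_t1[j]`. Small values indicate a real shift.
#'
#' @param cluster A cluster from a `clone_clusters` object (list with
#'   `ccf_probs`), or a G x T probability matrix.
#' @param t0,t1 Timepoint indices.
#' @param delta Band half-width on the CCF scale (default 0.1).
#' @return Probability in \[0, 1\].
#' @export
band_probability <- function(cluster, t0, t1, delta = 0.1) {
  probs <- if (is.list(cluster)) cluster$ccf_probs else cluster
  g <- ccf_grid()
  inband <- abs(outer(g, g, "-")) <= delta + 1e-12
  sum(outer(probs[, t0], probs[, t1]) * inband)
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up FDR adjustment (monotone, capped at 1).
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) p.adjust(pvals, method = "BH")

# Baseline and latest pre-relapse timepoint indices for one patient.
shift_window <- function(timeline, horizon = 365) {
  t0 <- 1L
  ok <- which(!timeline$is_relapse & timeline$day <= horizon)
  ok <- ok[ok > t0]
  if (!length(ok)) return(NULL)
  list(t0 = t0, t1 = max(ok))
}

#' Per-patient candidate shift tests
#'
#' Identifies the largest rising and falling clusters between the
#' baseline and the latest pre-relapse sample within the horizon and
#' computes their diagonal-band probabilities (cohort FDR adjustment is
#' applied later by [classify_cohort()]).
#'
#' @param clusters A `clone_clusters` object.
#' @param timeline The patient's timeline (sorted by day; relapse
#'   samples are excluded from the window).
#' @param delta Diagonal band half-width (default 0.1).
#' @param horizon Latest day eligible as the comparison sample (365).
#' @param patient_id Patient label for the output rows.
#' @return Data.frame with one row per direction (or `NULL` when no
#'   post-baseline pre-relapse sample exists).
#' @export
patient_shift_tests <- function(clusters, timeline, delta = 0.1,
                                horizon = 365, patient_id = NA_character_) {
  w <- shift_window(timeline, horizon)
  if (is.null(w)) return(NULL)
  cand <- max_shift_clusters(clusters, w$t0, w$t1)
  rows <- list()
  for (dir in c("rising", "falling")) {
    id <- cand[[dir]]
    if (is.na(id)) next
    cl <- clusters$clusters[[which(vapply(clusters$clusters, `[[`,
                                          integer(1), "cluster_id") == id)]]
    rows[[dir]] <- data.frame(
      patient_id = patient_id, cluster_id = id, direction = dir,
      t0_day = timeline$day[w$t0], t1_day = timeline$day[w$t1],
      delta_ccf = cl$ccf_point[w$t1] - cl$ccf_point[w$t0],
      band_prob = band_probability(cl, w$t0, w$t1, delta))
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-wide clonal-shift classification
#'
#' Pools the rising/falling band probabilities of all patients into a
#' single Benjamini-Hochberg family and flags a patient as evolved when
#' any of its tests has `q_adj < q_cut` and `|delta_ccf| > tau`.
#'
#' @param tests Data.frame of per-patient tests (rows from
#'   [patient_shift_tests()], i.e. columns `patient_id`, `cluster_id`,
#'   `direction`, `delta_ccf`, `band_prob`).
#' @param tau Minimum absolute CCF change (default 0.1; the sensitivity
#'   re-analysis uses 0.05).
#' @param q_cut FDR cutoff (default 0.1).
#' @return List with `tests` (the input plus `q_adj`, `significant`) and
#'   `patients` (per-patient `evolved` flag and largest significant
#'   shift magnitude).
#' @export
classify_cohort <- function(tests, tau = 0.1, q_cut = 0.1) {
  stopifnot(nrow(tests) >= 1)
  tests$q_adj <- bh_adjust(tests$band_prob)
  tests$significant <- tests$q_adj < q_cut & abs(tests$delta_ccf) > tau
  patients <- do.call(rbind, lapply(split(tests, tests$patient_id), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    data.frame(patient_id = d$patient_id[1],
               evolved = nrow(sig) > 0,
               max_shift = if (nrow(sig)) max(abs(sig$delta_ccf)) else NA_real_)
  }))
  rownames(patients) <- NULL
  list(tests = tests, patients = patients)
}
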