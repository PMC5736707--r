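# The per-patient model: CCF posteriors -> Dirichlet-process clustering
# -> consensus subclones -> constrained phylogeny -> growth-rate MCMC.
# clone_fit() is the front door; the staged functions remain exported
# for piecewise use.

#' Fit the clonal-dynamics model for one patient
#'
#' Runs the full per-patient analysis: per-mutation CCF posteriors from
#' force-called counts given purity and local copy number; joint
#' multi-timepoint Dirichlet-process clustering; consensus subclones;
#' exhaustive phylogeny enumeration under the pigeonhole and sibling-sum
#' constraints with selection by exponential-fit goodness; and the
#' mutation-reassignment MCMC for per-clone growth rates with credible
#' intervals and back-extrapolated day-0 sizes.
#'
#' @param mutations Mutation table for one patient (schema of
#'   [read_mutation_table()]).
#' @param timeline Sample timeline for the patient ([read_timeline()]).
#' @param segments Optional copy-number segments ([read_segments()]);
#'   `NULL` assumes diploid.
#' @param n_iter,burn_in Clustering chain length (defaults 1000/500).
#' @param mcmc_iter Kinetics MCMC iterations (default 10000).
#' @param seed Integer seed.
#' @param blood_volume_ul Blood volume in microliters (default 5 L).
#' @param min_ccf Minimum max-CCF for a clone to enter kinetics (0.1).
#' @param eps CCF tolerance for the phylogeny constraints (0.02).
#' @return Object of class `clonefit` with components `clusters`
#'   (`clone_clusters`), `tree` (`clone_tree`), `fits` (list of
#'   `growth_fit`), `chain`, `timeline`, `patient_id`, `shift_tests`.
#' @seealso [cohort_fit()] for the cohort-level analysis.
#' @export
clone_fit <- function(mutations, timeline, segments = NULL,
                      n_iter = 1000, burn_in = 500, mcmc_iter = 10000,
                      seed = NULL, blood_volume_ul = 5e6, min_ccf = 0.1,
                      eps = 0.02) {
  stopifnot(nrow(timeline) >= 1, nrow(mutations) >= 1)
  pid <- timeline$patient_id[1]
  timeline <- timeline[order(timeline$day), , drop = FALSE]
  cm <- patient_ccf_matrix(mutations, segments, timeline)
  chain <- gibbs_cluster(cm, n_iter = n_iter, burn_in = burn_in, seed = seed)
  clusters <- consensus_clusters(chain)
  scale_t <- timeline$alc_per_ul * timeline$purity * blood_volume_ul
  # escalate the CCF tolerance when posterior-mode noise leaves no
  # feasible topology at the default
  trees <- NULL
  eps_try <- eps
  while (is.null(trees)) {
    trees <- tryCatch(feasible_trees(clusters, eps = eps_try),
                      error = function(e) NULL)
    if (is.null(trees)) {
      if (eps_try > 0.32) {
        stop("no feasible phylogeny for patient ", pid,
             " even at eps = ", eps_try)
      }
      eps_try <- eps_try * 2
      message("patient ", pid, ": no feasible phylogeny at eps = ",
              signif(eps_try / 2, 3), "; retrying at ", signif(eps_try, 3))
    }
  }
  tree <- select_tree(trees, timeline$day, scale_t)
  fits <- kinetics_mcmc(clusters, tree, timeline, n_iter = mcmc_iter,
                        seed = if (is.null(seed)) NULL else seed + 1L,
                        blood_volume_ul = blood_volume_ul,
                        min_ccf = min_ccf)
  shifts <- patient_shift_tests(clusters, timeline, patient_id = pid)
  structure(list(patient_id = pid, clusters = clusters, tree = tree,
                 fits = fits, chain = chain, timeline = timeline,
                 shift_tests = shifts, blood_volume_ul = blood_volume_ul,
                 n_trees = length(trees), seed = seed),
            class = "clonefit")
}

#' @export
print.clonefit <- function(x, ...) {
  cat(sprintf("Clonal dynamics fit: patient %s, %d mutations, %d subclones, %d timepoints\n",
              x$patient_id, nrow(x$clusters$cm$prob),
              length(x$clusters$clusters), nrow(x$timeline)))
  print(x$tree)
  for (f in x$fits) print(f)
  invisible(x)
}

#' @export
summary.clonefit <- function(object, ...) {
  x <- object
  kin <- kinetics_table(x)
  cl <- cluster_table(x$clusters, x$patient_id)
  out <- list(patient_id = x$patient_id, clusters = cl, kinetics = kin,
              newick = tree_newick(x$tree), shift_tests = x$shift_tests,
              n_trees = x$n_trees)
  class(out) <- "summary.clonefit"
  out
}

#' @export
print.summary.clonefit <- function(x, ...) {
  cat("Patient", x$patient_id, "\n\nSubclone CCFs:\n")
  print(x$clusters, row.names = FALSE)
  cat("\nPhylogeny:", x$newick, sprintf("(%d feasible)\n", x$n_trees))
  cat("\nGrowth kinetics:\n")
  print(x$kinetics, row.names = FALSE)
  if (!is.null(x$shift_tests)) {
    cat("\nShift candidates (cohort FDR pending):\n")
    print(x$shift_tests, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.clonefit <- function(object, ...) {
  setNames(vapply(object$fits, `[[`, numeric(1), "g"),
           paste0("clone", vapply(object$fits, `[[`, integer(1), "clone_id")))
}

#' Kinetics table for a fitted patient
#' @param x A `clonefit`.
#' @return Data.frame: clone, rate/day, 95% interval, R2, two-point
#'   flag, back-extrapolated day-0 cells with interval.
#' @export
kinetics_table <- function(x) {
  do.call(rbind, lapply(x$fits, function(f) {
    data.frame(patient_id = x$patient_id, clone = f$clone_id, g = f$g,
               ci_low = f$ci_low, ci_high = f$ci_high, r2 = f$r2,
               n_points = f$n_points, two_point = f$two_point,
               n0 = f$n0, n0_low = f$n0_ci[1], n0_high = f$n0_ci[2],
               method = f$method, row.names = NULL)
  }))
}

#' Predicted clone trajectories
#'
#' Clone-exclusive circulating cell counts from the fitted exponential
#' rates, evaluated at arbitrary days.
#'
#' @param object A `clonefit`.
#' @param newdata Optional data.frame with a `day` column (defaults to
#'   the observed days).
#' @param type `"cells"` (clone-exclusive counts from the fitted
#'   exponentials) or `"ccf"` (consensus cluster CCF point estimates at
#'   the observed days; ignores `newdata`).
#' @param ... Unused.
#' @return Matrix, clones x days.
#' @export
predict.clonefit <- function(object, newdata = NULL,
                             type = c("cells", "ccf"), ...) {
  type <- match.arg(type)
  if (type == "ccf") {
    return(as_ccf_matrix(object$clusters))
  }
  days <- if (is.null(newdata)) object$timeline$day else newdata$day
  out <- t(vapply(object$fits, function(f) f$n0 * exp(f$g * days),
                  numeric(length(days))))
  dimnames(out) <- list(
    paste0("clone", vapply(object$fits, `[[`, integer(1), "clone_id")),
    days)
  out
}

#' @export
residuals.clonefit <- function(object, ...) {
  # log-scale residuals of the observed clone-exclusive counts against
  # the fitted exponentials
  ex <- exclusive_ccf(object$tree)
  scale_t <- object$timeline$alc_per_ul * object$timeline$purity *
    object$blood_volume_ul
  obs <- sweep(ex, 2, scale_t, "*")
  out <- lapply(object$fits, function(f) {
    o <- obs[f$clone_id, ]
    keep <- o > 0 & !is.na(f$g)
    r <- rep(NA_real_, length(o))
    r[keep] <- log(o[keep]) - (log(f$n0) + f$g * object$timeline$day[keep])
    r
  })
  m <- do.call(rbind, out)
  dimnames(m) <- list(paste0("clone", vapply(object$fits, `[[`, integer(1),
                                             "clone_id")),
                      object$timeline$day)
  m
}

#' Plot CCF trajectories and fitted kinetics
#'
#' Left panel: consensus subclone CCF trajectories. Right panel:
#' clone-exclusive circulating cell counts (points) with the fitted
#' exponential curves, log scale.
#'
#' @param x A `clonefit`.
#' @param ... Passed to [matplot()].
#' @export
plot.clonefit <- function(x, ...) {
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  days <- x$timeline$day
  ccf <- as_ccf_matrix(x$clusters)
  matplot(days, t(ccf), type = "b", pch = 19, lty = 1,
          xlab = "day", ylab = "CCF", ylim = c(0, 1),
          main = paste("subclone CCF,", x$patient_id), ...)
  legend("topright", legend = rownames(ccf), col = seq_len(nrow(ccf)),
         lty = 1, cex = 0.7, title = "clone")
  ex <- exclusive_ccf(x$tree)
  scale_t <- x$timeline$alc_per_ul * x$timeline$purity * x$blood_volume_ul
  obs <- sweep(ex, 2, scale_t, "*")
  pos <- obs[obs > 0]
  matplot(days, t(pmax(obs, min(pos) / 10)), type = "p", pch = 1, log = "y",
          xlab = "day", ylab = "circulating cells",
          main = "clone kinetics")
  dd <- seq(min(days), max(days), length.out = 50)
  pr <- predict(x, data.frame(day = dd))
  for (i in seq_len(nrow(pr))) lines(dd, pr[i, ], col = i)
  invisible(x)
}

#' Posterior-predictive read counts from a fitted patient
#'
#' Draws new force-called alt counts at the observed depths from the
#' consensus cluster CCFs (binomial, diploid heterozygous model), e.g.
#' for parametric-bootstrap checks.
#'
#' @param object A `clonefit`.
#' @param nsim Number of replicate tables.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` mutation tables.
#' @export
simulate.clonefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cl <- object$clusters
  assign <- cl$assignment
  ccf <- as_ccf_matrix(cl)
  tl <- object$timeline
  muts <- object$clusters$cm$mutation_id
  lapply(seq_len(nsim), function(s) {
    do.call(rbind, lapply(seq_len(nrow(tl)), function(ti) {
      depth <- rnbinom(length(muts), mu = 107, size = 72)
      ev <- expected_vaf(ccf[assign[muts], ti], tl$purity[ti], 1, 2)
      alt <- rbinom(length(muts), depth, ev)
      data.frame(patient_id = object$patient_id,
                 sample_id = tl$sample_id[ti], mutation_id = muts,
                 t_alt_count = alt, t_ref_count = depth - alt)
    }))
  })
}

#' Fit the cohort-level analysis
#'
#' Fits every patient with [clone_fit()], pools the per-patient shift
#' tests into one Benjamini-Hochberg family, classifies evolved
#' patients, and (when outcomes are supplied) tests the association of
#' early clonal shifts with progression (Fisher exact) and
#' time-to-progression (Kaplan-Meier / log-rank).
#'
#' @param patients Either a list of `clonefit` objects or a `sim_cohort`
#'   (whose patients are then fitted).
#' @param outcomes Optional outcome table ([read_outcomes()]).
#' @param tau,q_cut Shift-call thresholds (|dCCF| > 0.1, q < 0.1).
#' @param seed Seed used when fitting from raw tables.
#' @param ... Passed on to [clone_fit()].
#' @return Object of class `cohortfit`: `fits`, `shifts` (test table),
#'   `patients` (evolved flags), `association`, `clusters`/`kinetics`
#'   tables, `seed`.
#' @export
cohort_fit <- function(patients, outcomes = NULL, tau = 0.1, q_cut = 0.1,
                       seed = 1, ...) {
  if (inherits(patients, "sim_cohort")) {
    if (is.null(outcomes)) outcomes <- patients$outcomes
    fits <- lapply(seq_along(patients$patients), function(i) {
      p <- patients$patients[[i]]
      clone_fit(p$mutations, p$timeline, p$segments,
                seed = (seed + 31L * i) %% .Machine$integer.max, ...)
    })
  } else {
    fits <- patients
  }
  tests <- do.call(rbind, lapply(fits, `[[`, "shift_tests"))
  cls <- classify_cohort(tests, tau = tau, q_cut = q_cut)
  # patients with no testable window are non-evolved by definition
  all_ids <- vapply(fits, `[[`, character(1), "patient_id")
  missing <- setdiff(all_ids, cls$patients$patient_id)
  if (length(missing)) {
    cls$patients <- rbind(cls$patients,
                          data.frame(patient_id = missing, evolved = FALSE,
                                     max_shift = NA_real_))
  }
  assoc <- if (!is.null(outcomes)) outcome_association(cls$patients, outcomes)
  structure(list(
    fits = fits, shifts = cls$tests, patients = cls$patients,
    association = assoc,
    clusters = do.call(rbind, lapply(fits, function(f)
      cluster_table(f$clusters, f$patient_id))),
    kinetics = do.call(rbind, lapply(fits, kinetics_table)),
    seed = seed),
    class = "cohortfit")
}

#' @export
print.cohortfit <- function(x, ...) {
  n <- nrow(x$patients)
  ne <- sum(x$patients$evolved)
  cat(sprintf("Cohort fit: %d patients, %d evolved (%.0f%%)\n",
              n, ne, 100 * ne / n))
  if (!is.null(x$association)) {
    cat(sprintf("Fisher exact (evolved x progressed): p = %.3g\n",
                x$association$fisher_p))
    print(x$association$km)
  }
  invisible(x)
}

#' Run the full pipeline from interchange tables
#'
#' Reads the four input tables, fits every patient, classifies the
#' cohort and writes the report tables.
#'
#' @param config List with `mutations`, `timeline`, `outcomes` paths
#'   (and optionally `segments`, `out_dir`, `seed`, `tau`, `q_cut`,
#'   `blood_volume_ul`, `n_iter`, `burn_in`, `mcmc_iter`).
#' @return The `cohortfit`, invisibly; report files written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  need <- c("mutations", "timeline")
  miss <- need[!vapply(need, function(f)
    !is.null(config[[f]]) && file.exists(config[[f]]), logical(1))]
  if (length(miss)) {
    stop("missing input file(s): ",
         paste(vapply(miss, function(f)
           paste0(f, " (", if (is.null(config[[f]])) "unset"
                  else config[[f]], ")"), character(1)), collapse = ", "))
  }
  muts <- read_mutation_table(config$mutations)
  tl <- read_timeline(config$timeline)
  segs <- if (!is.null(config$segments)) read_segments(config$segments)
  outc <- if (!is.null(config$outcomes)) read_outcomes(config$outcomes)
  getd <- function(nm, d) if (is.null(config[[nm]])) d else config[[nm]]
  seed <- getd("seed", 1L)
  fits <- list()
  for (pid in unique(tl$patient_id)) {
    fits[[pid]] <- clone_fit(
      muts[muts$patient_id == pid, ], tl[tl$patient_id == pid, ], segs,
      n_iter = getd("n_iter", 1000), burn_in = getd("burn_in", 500),
      mcmc_iter = getd("mcmc_iter", 10000),
      seed = (seed + 31L * match(pid, unique(tl$patient_id))) %%
        .Machine$integer.max,
      blood_volume_ul = getd("blood_volume_ul", 5e6))
  }
  cf <- cohort_fit(fits, outcomes = outc, tau = getd("tau", 0.1),
                   q_cut = getd("q_cut", 0.1), seed = seed)
  cf$seed <- seed
  if (!is.null(config$out_dir)) write_report(cf, config$out_dir)
  invisible(cf)
}
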