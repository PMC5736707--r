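# sample() that never treats a length-1 vector as 1:n
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# Synthetic longitudinal cohorts with known ground truth, emulating the
# structure of serially sampled CLL under targeted therapy: a truncal
# clone plus 1-5 subclones on a branched or linear topology, per-clone
# exponential kinetics, declining absolute lymphocyte counts, exome-scale
# mutation burdens force-called across 3-8 timepoints at ~x107 depth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: samples at days
#' 0/30/60/90/180/365, negative-binomial depth with mean 107 (quartiles
#' near 97-119), 2-6 clones per patient, a truncal cluster of ~20
#' mutations plus ~10 per subclone (an exome-scale burden of ~1 mutation
#' per megabase), per-clone exponential rates within a few percent per
#' day, declining ALC, and a 19/61 prevalence of true early shifts with
#' a 3-fold progression hazard for truly evolved patients.
#'
#' @param n_patients Number of patients (default 61).
#' @param days Sample days.
#' @param depth_mean,depth_size Negative-binomial sequencing depth
#'   parameters (mean 107, size 72 gives IQR close to 97-119).
#' @param n_clones_range Range of clones per patient (including trunk).
#' @param p_branched Probability that an evolved patient's shifting
#'   clones are siblings (branched) rather than parent-progeny (linear);
#'   default 15/19.
#' @param n_mut_trunk,muts_per_clone Mutations in the truncal cluster
#'   and (range) per subclone.
#' @param g_decline_range Per-day exponential rate range for clones
#'   under therapy (mostly declining).
#' @param g_shift Per-day rate of the designated shifting clone in
#'   evolved patients.
#' @param alc0_range Baseline ALC range, cells/µL.
#' @param normal_alc Non-tumor lymphocytes, cells/µL (constant).
#' @param blood_volume_ul Blood volume, µL.
#' @param shift_prevalence Fraction of patients with a true early shift.
#' @param hazard0 Baseline progression hazard per day.
#' @param hazard_multiplier Hazard multiplier for truly evolved patients.
#' @param followup_day Administrative censoring day.
#' @param relapse Logical: seed a resistant clone (see `relapse_n0`,
#'   `relapse_g`) and add late relapse-flagged samples.
#' @param relapse_n0,relapse_g Resistant clone size at day 0 (cells) and
#'   growth rate (per day).
#' @param cn_preset `"none"` or `"loh"` (a del(17p)-like single-copy
#'   region harboring part of the truncal mutations).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 61,
                       days = c(0, 30, 60, 90, 180, 365),
                       depth_mean = 107, depth_size = 72,
                       n_clones_range = c(2, 6),
                       p_branched = 15 / 19,
                       n_mut_trunk = 20, muts_per_clone = c(8, 14),
                       g_decline_range = c(-0.05, -0.005),
                       g_shift = 0.02,
                       alc0_range = c(3e4, 1.5e5),
                       normal_alc = 1500,
                       blood_volume_ul = 5e6,
                       shift_prevalence = 19 / 61,
                       hazard0 = 2.34e-4,
                       hazard_multiplier = 3,
                       followup_day = 900,
                       relapse = FALSE,
                       relapse_n0 = 1e3, relapse_g = 0.05,
                       cn_preset = c("none", "loh")) {
  cn_preset <- match.arg(cn_preset)
  stopifnot(n_patients >= 1, all(diff(days) > 0), depth_mean > 0,
            n_clones_range[1] >= 1, shift_prevalence >= 0,
            shift_prevalence <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one patient with known ground truth
#'
#' Samples a feasible clone tree, per-clone exponential trajectories of
#' clone-exclusive cell counts, derives true cluster CCFs (subtree cells
#' over total tumor cells, so the phylogeny constraints hold by
#' construction), the declining ALC and per-sample purity, and draws
#' force-called read counts binomially at negative-binomial depths.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param evolved Force the true-shift status (`NULL` = Bernoulli with
#'   the configured prevalence).
#' @param patient_id Patient label.
#' @return List of class `sim_patient`: `mutations`, `segments`,
#'   `timeline` data.frames (the [read_mutation_table()] /
#'   [read_segments()] / [read_timeline()] schemas) and `truth` (parent
#'   vector, per-clone `g`, `n0`, true CCF matrix, mutation assignment,
#'   `evolved`).
#' @export
simulate_patient <- function(config, seed, evolved = NULL,
                             patient_id = "P01") {
  set.seed(seed)
  cfg <- config
  days <- cfg$days
  if (cfg$relapse) {
    extra <- c(240, 300)
    days <- sort(unique(c(days, extra)))
  }
  Tn <- length(days)
  if (is.null(evolved)) evolved <- runif(1) < cfg$shift_prevalence

  K <- resample(seq(cfg$n_clones_range[1], cfg$n_clones_range[2]), 1)
  if (cfg$relapse) K <- max(K, 3)
  # topology: clone 1 is the trunk; subclones attach to the trunk
  # (branched siblings) or chain below an earlier subclone (linear)
  parent <- integer(K)
  parent[1] <- 0L
  branched <- runif(1) < cfg$p_branched
  if (K > 1) {
    for (k in 2:K) {
      parent[k] <- if (branched || k == 2) 1L else k - 1L
    }
  }

  # day-0 tumor mass partitioned among clone-exclusive compartments
  alc0 <- runif(1, cfg$alc0_range[1], cfg$alc0_range[2])
  tumor0 <- alc0 * cfg$blood_volume_ul *
    alc0 / (alc0 + cfg$normal_alc)  # consistent with purity at day 0
  w <- rgamma(K, shape = 2)
  w[1] <- w[1] + sum(w)  # trunk-exclusive keeps the majority
  w <- w / sum(w)
  n0 <- tumor0 * w
  shift_clone <- NA_integer_
  if (evolved && K > 1) {
    # heterogeneous decline plus one subclone rising against it
    g <- runif(K, cfg$g_decline_range[1], cfg$g_decline_range[2])
    shift_clone <- resample(2:K, 1)
    g[shift_clone] <- cfg$g_shift
    n0[shift_clone] <- tumor0 * runif(1, 0.1, 0.3)
  } else {
    # all clones share one rate: CCFs are exactly flat (null patient)
    g <- rep(runif(1, cfg$g_decline_range[1], cfg$g_decline_range[2]), K)
  }
  relapse_clone <- NA_integer_
  if (cfg$relapse) {
    relapse_clone <- K
    parent[K] <- 1L
    n0[K] <- cfg$relapse_n0
    g[K] <- cfg$relapse_g
  }

  # clone-exclusive trajectories and true subtree CCFs
  cells <- outer(n0, rep(1, Tn)) * exp(outer(g, days))
  total <- colSums(cells)
  subtree <- function(k) {
    kids <- which(parent == k)
    Reduce(`+`, lapply(kids, subtree), cells[k, ])
  }
  ccf_true <- t(vapply(seq_len(K), subtree, numeric(Tn)))
  ccf_true <- sweep(ccf_true, 2, total, "/")

  alc <- (total + cfg$normal_alc * cfg$blood_volume_ul) / cfg$blood_volume_ul
  purity <- total / (total + cfg$normal_alc * cfg$blood_volume_ul)

  timeline <- data.frame(
    patient_id = patient_id,
    sample_id = sprintf("%s_S%02d", patient_id, seq_len(Tn)),
    day = days, alc_per_ul = alc, purity = purity,
    is_relapse = if (cfg$relapse) days >= 240 else rep(FALSE, Tn))

  # mutations: counts per clone, positions, local copy number
  n_mut <- c(cfg$n_mut_trunk,
             if (K > 1) resample(seq(cfg$muts_per_clone[1],
                                     cfg$muts_per_clone[2]), K - 1,
                                 replace = TRUE))
  assign_clone <- rep(seq_len(K), n_mut)
  n_total <- length(assign_clone)
  chrom <- rep("1", n_total)
  loh <- rep(FALSE, n_total)
  if (cfg$cn_preset == "loh") {
    # a del(17p)-like region: single copy, mutations there at q_t = 1
    idx <- which(assign_clone == 1)[seq_len(min(5, n_mut[1]))]
    chrom[idx] <- "17"
    loh[idx] <- TRUE
  }
  pos <- sample(1e6:2e8, n_total)
  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, n_total, replace = TRUE)
  altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1), "x")

  mutations <- do.call(rbind, lapply(seq_len(Tn), function(ti) {
    depth <- rnbinom(n_total, mu = cfg$depth_mean, size = cfg$depth_size)
    ev <- expected_vaf(pmin(ccf_true[assign_clone, ti], 1),
                       purity[ti], m = 1, q_t = 2)
    if (any(loh)) {
      ev[loh] <- expected_vaf(pmin(ccf_true[assign_clone[loh], ti], 1),
                              purity[ti], m = 1, q_t = 1)
    }
    alt <- rbinom(n_total, depth, ev)
    data.frame(patient_id = patient_id,
               sample_id = timeline$sample_id[ti],
               chrom = chrom, pos = pos, ref = refb, alt = altb,
               t_alt_count = alt, t_ref_count = depth - alt,
               gene = NA_character_, is_driver = FALSE)
  }))
  rownames(mutations) <- NULL

  segments <- do.call(rbind, lapply(timeline$sample_id, function(s) {
    segs <- data.frame(sample_id = s, chrom = "1", start = 1, end = 3e8,
                       total_cn = 2, major_cn = 1, minor_cn = 1)
    if (cfg$cn_preset == "loh") {
      segs <- rbind(segs, data.frame(sample_id = s, chrom = "17", start = 1,
                                     end = 3e8, total_cn = 1, major_cn = 1,
                                     minor_cn = 0))
    }
    segs
  }))

  structure(list(
    mutations = mutations, segments = segments, timeline = timeline,
    truth = list(parent = parent, g = g, n0 = n0, ccf = ccf_true,
                 cells = cells, assignment = assign_clone,
                 evolved = evolved, shift_clone = shift_clone,
                 relapse_clone = relapse_clone, days = days)),
    class = "sim_patient")
}

#' Simulate a longitudinal cohort
#'
#' Independent patients via per-patient seeds derived from the master
#' seed; progression times exponential with the hazard multiplied for
#' truly evolved patients, censored administratively.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return List of class `sim_cohort`: `patients` (list of
#'   `sim_patient`), `outcomes` data.frame, `evolved_truth`, `config`.
#' @export
simulate_cohort <- function(config, seed) {
  set.seed(seed)
  n <- config$n_patients
  evolved <- runif(n) < config$shift_prevalence
  ids <- sprintf("P%02d", seq_len(n))
  patients <- lapply(seq_len(n), function(i) {
    simulate_patient(config, seed = (seed + 7919L * i) %% .Machine$integer.max,
                     evolved = evolved[i], patient_id = ids[i])
  })
  outcomes <- sim_outcomes(evolved, config,
                           seed = (seed + 104729L) %% .Machine$integer.max,
                           patient_id = ids)
  structure(list(patients = patients, outcomes = outcomes,
                 evolved_truth = evolved, config = config, seed = seed),
            class = "sim_cohort")
}

#' Simulate progression outcomes for a cohort
#'
#' Exponential progression times with the baseline hazard multiplied by
#' `hazard_multiplier` for truly evolved patients, censored at the
#' configured follow-up day.
#'
#' @param evolved Logical vector of true evolved status.
#' @param config A [sim_config()] (uses `hazard0`, `hazard_multiplier`,
#'   `followup_day`).
#' @param seed Integer seed.
#' @param patient_id Patient labels.
#' @return Outcome data.frame (schema of [read_outcomes()]).
#' @export
sim_outcomes <- function(evolved, config, seed,
                         patient_id = sprintf("P%02d", seq_along(evolved))) {
  set.seed(seed)
  n <- length(evolved)
  hz <- config$hazard0 * ifelse(evolved, config$hazard_multiplier, 1)
  t_event <- rexp(n, hz)
  data.frame(patient_id = patient_id,
             followup_day = pmin(ceiling(t_event), config$followup_day),
             progressed = t_event <= config$followup_day)
}

#' Write a simulated cohort to the interchange tables
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the paths of `mutations.tsv`, `segments.tsv`,
#'   `timeline.tsv`, `outcomes.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    mutations = do.call(rbind, lapply(cohort$patients, `[[`, "mutations")),
    segments = do.call(rbind, lapply(cohort$patients, `[[`, "segments")),
    timeline = do.call(rbind, lapply(cohort$patients, `[[`, "timeline")),
    outcomes = cohort$outcomes)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tabs[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
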