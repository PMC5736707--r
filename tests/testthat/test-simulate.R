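# Synthetic-cohort generator: determinism, ground-truth invariants, and
# the links between truth and the observable tables.

test_that("identical seeds reproduce identical tables", {
  cfg <- sim_config(n_clones_range = c(2, 4))
  a <- simulate_patient(cfg, seed = 77)
  b <- simulate_patient(cfg, seed = 77)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$timeline, b$timeline)
  expect_identical(a$truth, b$truth)
  co1 <- simulate_cohort(sim_config(n_patients = 3), seed = 5)
  co2 <- simulate_cohort(sim_config(n_patients = 3), seed = 5)
  expect_identical(co1$outcomes, co2$outcomes)
  expect_identical(co1$patients[[2]]$mutations, co2$patients[[2]]$mutations)
})

test_that("a single neutral clone gives VAFs around purity/2 and CCF 1", {
  cfg <- sim_config(n_clones_range = c(1, 1),
                    g_decline_range = c(0, 0))
  sp <- simulate_patient(cfg, seed = 12, evolved = FALSE)
  expect_true(all(sp$truth$ccf == 1))
  m <- sp$mutations
  vaf <- m$t_alt_count / (m$t_alt_count + m$t_ref_count)
  alpha <- sp$timeline$purity[match(m$sample_id, sp$timeline$sample_id)]
  expect_lt(abs(mean(vaf - alpha / 2)), 0.02)
})

test_that("ground truth respects the phylogeny constraints by construction", {
  for (s in 1:5) {
    sp <- simulate_patient(sim_config(), seed = 100 + s)
    tr <- sp$truth
    K <- length(tr$parent)
    for (k in seq_len(K)) {
      p <- tr$parent[k]
      if (p != 0) expect_true(all(tr$ccf[p, ] >= tr$ccf[k, ] - 1e-9))
    }
    for (p in unique(tr$parent)) {
      kids <- which(tr$parent == p)
      if (!length(kids)) next
      cap <- if (p == 0) 1 else tr$ccf[p, ]
      expect_true(all(colSums(tr$ccf[kids, , drop = FALSE]) <= cap + 1e-9))
    }
    # trunk is clonal everywhere; CCF = subtree cells / total
    expect_true(all(abs(tr$ccf[1, ] - 1) < 1e-12))
    expect_true(all(colSums(tr$cells) > 0))
  }
})

test_that("depth emulates the targeted coverage distribution", {
  cfg <- sim_config(n_patients = 1, n_clones_range = c(4, 4))
  sp <- simulate_patient(cfg, seed = 8)
  depth <- sp$mutations$t_alt_count + sp$mutations$t_ref_count
  expect_gt(length(depth), 100)
  expect_lt(abs(median(depth) - 107), 10)
  iqr <- quantile(depth, c(0.25, 0.75))
  expect_lt(abs(iqr[1] - 97), 10)
  expect_lt(abs(iqr[2] - 119), 12)
})

test_that("null patients are exactly flat and evolved patients truly shift", {
  flat <- simulate_patient(sim_config(n_clones_range = c(3, 3)), seed = 5,
                           evolved = FALSE)
  expect_true(all(abs(flat$truth$ccf - flat$truth$ccf[, 1]) < 1e-12))
  ev <- simulate_patient(sim_config(n_clones_range = c(3, 3)), seed = 5,
                         evolved = TRUE)
  pre <- ev$truth$days <= 365
  shift <- max(abs(ev$truth$ccf[, max(which(pre))] - ev$truth$ccf[, 1]))
  expect_gt(shift, 0.1)
})

test_that("LOH preset places truncal mutations on a single-copy segment", {
  cfg <- sim_config(cn_preset = "loh", n_clones_range = c(2, 2))
  sp <- simulate_patient(cfg, seed = 3)
  expect_true(any(sp$segments$total_cn == 1))
  loh_muts <- sp$mutations[sp$mutations$chrom == "17", ]
  expect_gt(nrow(loh_muts), 0)
  # hemizygous truncal VAF ~ purity / (2 - purity), above the diploid 1/2
  tl <- sp$timeline
  v <- loh_muts$t_alt_count / (loh_muts$t_alt_count + loh_muts$t_ref_count)
  alpha <- tl$purity[match(loh_muts$sample_id, tl$sample_id)]
  expect_lt(abs(mean(v - alpha / (2 - alpha * 1))), 0.04)
  # the CCF model undoes the copy-number effect
  cm <- patient_ccf_matrix(sp$mutations, sp$segments, sp$timeline)
  j <- match(paste0("17:", loh_muts$pos[1], ":", loh_muts$ref[1], ">",
                    loh_muts$alt[1]), cm$mutation_id)
  mode1 <- grid[which.max(cm$prob[j, 1:101])]
  expect_gt(mode1, 0.9)
})

test_that("null hazard gives uniform log-rank p-values across cohorts", {
  cfg <- sim_config(hazard_multiplier = 1)
  ps <- vapply(1:200, function(s) {
    evolved <- rep(c(TRUE, FALSE), c(19, 42))
    oc <- sim_outcomes(evolved, cfg, seed = 3000 + s)
    if (sum(oc$progressed) < 2) return(NA_real_)
    km_logrank(oc$followup_day, oc$progressed, evolved)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a threefold hazard yields the expected HR range across cohorts", {
  cfg <- sim_config(hazard_multiplier = 3)
  hrs <- vapply(1:100, function(s) {
    evolved <- rep(c(TRUE, FALSE), c(19, 42))
    oc <- sim_outcomes(evolved, cfg, seed = 6000 + s)
    km_logrank(oc$followup_day, oc$progressed, evolved)$hr
  }, numeric(1))
  expect_gt(median(hrs, na.rm = TRUE), 2)
  expect_lt(median(hrs, na.rm = TRUE), 4.5)
})
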