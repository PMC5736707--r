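# Growth kinetics: cell counts, exponential fits, reassignment MCMC,
# back-extrapolation and CCF rate statistics.

test_that("clone cell counts are the four-factor product", {
  expect_equal(clone_cell_count(0.5, 1e4, 0.9, 5e6), 2.25e10)
  expect_equal(clone_cell_count(0, 1e4, 0.9, 5e6), 0)
  expect_equal(clone_cell_count(0.3, 1e4, 0.9, 1e7),
               2 * clone_cell_count(0.3, 1e4, 0.9, 5e6))
})

test_that("noiseless exponentials are recovered exactly", {
  days <- c(0, 30, 60)
  counts <- 1000 * exp(0.02 * days)
  f <- fit_exponential(counts, days)
  expect_equal(f$g, 0.02, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_equal(f$n0, 1000, tolerance = 1e-6)
  expect_false(f$two_point)
})

test_that("two-point fits are exact and flagged", {
  f <- fit_exponential(c(100, 1000), c(0, 50))
  expect_true(f$two_point)
  expect_equal(f$r2, 1)
  expect_equal(f$g, log(10) / 50)
})

test_that("zero counts are excluded with a warning; lone points give no fit", {
  expect_warning(f <- fit_exponential(c(0, 100, 200), c(0, 30, 60)),
                 "zero count")
  expect_equal(f$n_points, 2)
  f2 <- suppressWarnings(fit_exponential(c(0, 0, 100), c(0, 30, 60)))
  expect_true(is.na(f2$g))
  expect_equal(f2$n_points, 1)
})

test_that("rate estimates are unbiased under lognormal noise", {
  set.seed(77)
  days <- c(0, 30, 90, 180)
  g_hat <- replicate(500, {
    counts <- 1e9 * exp(0.01 * days) * exp(rnorm(4, 0, 0.2))
    fit_exponential(counts, days)$g
  })
  expect_lt(abs(mean(g_hat) - 0.01), 0.001)
})

test_that("back-extrapolation inverts forward growth to machine precision", {
  f0 <- list(g = 0, ci_low = 0, ci_high = 0)
  expect_equal(back_extrapolate(f0, 200, 5e6)$n0, 5e6)
  f1 <- list(g = 0.01, ci_low = 0.008, ci_high = 0.012)
  expect_equal(back_extrapolate(f1, 300, 100 * exp(3))$n0, 100,
               tolerance = 1e-12)
  # forward-then-back identity
  n0 <- 12345.6789; g <- 0.0173; t <- 250
  fwd <- n0 * exp(g * t)
  expect_equal(back_extrapolate(list(g = g, ci_low = g, ci_high = g),
                                t, fwd)$n0, n0, tolerance = 1e-12)
  expect_lte(back_extrapolate(f1, 300, 1e5)$ci_low,
             back_extrapolate(f1, 300, 1e5)$ci_high)
})

test_that("degenerate posteriors make a one-iteration chain equal the deterministic fit", {
  days <- c(0, 50, 100, 150)
  ccfs <- list(rep(1, 4), c(0.5, 0.4, 0.3, 0.2))
  cl <- make_clusters(ccfs, n_members = 6)
  # attach a cm consistent with the point masses
  posts <- lapply(seq_len(12), function(j) {
    k <- (j - 1) %/% 6 + 1
    lapply(ccfs[[k]], point_mass_posterior)
  })
  names(posts) <- unlist(lapply(cl$clusters, `[[`, "members"))
  cl$cm <- ccf_matrix(posts, cl$sample_id)
  ccfm <- rbind(`1` = ccfs[[1]], `2` = ccfs[[2]])
  tree <- feasible_trees(ccfm)[[1]]
  tl <- data.frame(day = days, alc_per_ul = 5e4, purity = 0.9)
  fits <- kinetics_mcmc(cl, tree, tl, n_iter = 1, seed = 3)
  scale_t <- 5e4 * 0.9 * 5e6
  ex <- exclusive_ccf(tree)
  for (k in 1:2) {
    det <- fit_exponential(ex[k, ] * scale_t, days, quiet = TRUE)
    expect_equal(fits[[as.character(k)]]$g, det$g, tolerance = 1e-10)
  }
})

test_that("identical seeds reproduce the kinetics chain exactly", {
  sp <- simulate_patient(sim_config(n_clones_range = c(3, 3)), seed = 9,
                         evolved = TRUE)
  tc <- true_clusters(sp)
  tl <- sp$timeline
  f1 <- kinetics_mcmc(tc$clusters, tc$tree, tl, n_iter = 300, seed = 42)
  f2 <- kinetics_mcmc(tc$clusters, tc$tree, tl, n_iter = 300, seed = 42)
  expect_identical(f1, f2)
})

test_that("clones below the CCF floor are excluded with a note", {
  days <- c(0, 60)
  cl <- make_clusters(list(c(1, 1), c(0.05, 0.08)), n_members = 4)
  posts <- lapply(seq_len(8), function(j) {
    k <- (j - 1) %/% 4 + 1
    lapply(cl$clusters[[k]]$ccf_point, point_mass_posterior)
  })
  names(posts) <- unlist(lapply(cl$clusters, `[[`, "members"))
  cl$cm <- ccf_matrix(posts, cl$sample_id)
  tree <- feasible_trees(rbind(`1` = c(1, 1), `2` = c(0.05, 0.08)))[[1]]
  tl <- data.frame(day = days, alc_per_ul = 5e4, purity = 0.9)
  expect_message(fits <- kinetics_mcmc(cl, tree, tl, n_iter = 50, seed = 1),
                 "max CCF < 0.1")
  expect_false("2" %in% names(fits))
  expect_true("1" %in% names(fits))
})

test_that("singleton clusters fall back to deterministic regression", {
  days <- c(0, 60, 120)
  cl <- make_clusters(list(c(1, 1, 1)), n_members = 10)
  singleton <- make_clusters(list(c(0.4, 0.3, 0.2)), n_members = 1)
  singleton$clusters[[1]]$cluster_id <- 2L
  cl$clusters[[2]] <- singleton$clusters[[1]]
  members <- unlist(lapply(cl$clusters, `[[`, "members"))
  posts <- c(lapply(1:10, function(i) lapply(c(1, 1, 1), point_mass_posterior)),
             list(lapply(c(0.4, 0.3, 0.2), point_mass_posterior)))
  names(posts) <- members
  cl$cm <- ccf_matrix(posts, cl$sample_id)
  cl$assignment <- setNames(rep(c(1L, 2L), c(10, 1)), members)
  tree <- feasible_trees(rbind(`1` = c(1, 1, 1), `2` = c(0.4, 0.3, 0.2)))[[1]]
  tl <- data.frame(day = days, alc_per_ul = 4e4, purity = 0.95)
  fits <- kinetics_mcmc(cl, tree, tl, n_iter = 100, seed = 5)
  expect_equal(fits[["2"]]$method, "singleton_regression")
  det <- fit_exponential(c(0.4, 0.3, 0.2) * 4e4 * 0.95 * 5e6, days,
                         quiet = TRUE)
  expect_equal(fits[["2"]]$g, det$g)
})

test_that("rate statistics split periods at the day-30 boundary", {
  days <- c(0, 30, 90, 180)
  r <- ccf_rate_stats(c(0.50, 0.38, 0.30, 0.26), days)
  expect_equal(r$rate1, 0.004)
  expect_equal(r$rate2, abs(0.26 - 0.38) / 150)
  expect_true(r$concordant)
  # linear decline across both periods -> zero deceleration
  lin <- 0.5 - 0.001 * days
  r2 <- ccf_rate_stats(lin, days)
  expect_equal(r2$deceleration, 0, tolerance = 1e-12)
  # no day-30 sample: nearest sample is used, with a note
  expect_message(r3 <- ccf_rate_stats(c(0.5, 0.4, 0.3), c(0, 56, 180),
                                      boundary = 30),
                 "day 56")
  expect_equal(r3$rate1, 0.1 / 56)
  expect_equal(r3$boundary_day, 56)
})

test_that("relapse timepoints are used by kinetics but not by shift tests", {
  cfg <- sim_config(relapse = TRUE, n_clones_range = c(3, 3))
  sp <- simulate_patient(cfg, seed = 31, evolved = TRUE)
  expect_true(any(sp$timeline$is_relapse))
  tc <- true_clusters(sp)
  tests <- patient_shift_tests(tc$clusters, sp$timeline, patient_id = "P")
  expect_gte(nrow(tests), 1)
  expect_true(all(tests$t1_day <= 365))
  expect_true(all(tests$t1_day < min(sp$timeline$day[sp$timeline$is_relapse])))
})
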