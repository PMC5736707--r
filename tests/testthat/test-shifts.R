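# Clonal-shift detection and cohort FDR control.

test_that("largest rising and falling clones are identified with stated tie-breaks", {
  cl <- make_clusters(list(c(0.2, 0.5), c(0.5, 0.25), c(0.3, 0.3)))
  ms <- max_shift_clusters(cl, 1, 2)
  expect_equal(ms$rising, 1)
  expect_equal(ms$falling, 2)
  # single cluster is both candidates
  one <- make_clusters(list(c(0.4, 0.6)))
  ms1 <- max_shift_clusters(one, 1, 2)
  expect_equal(ms1$rising, 1)
  expect_equal(ms1$falling, 1)
  # ties -> smaller cluster id
  tie <- make_clusters(list(c(0.2, 0.5), c(0.3, 0.6), c(0.5, 0.2)))
  expect_equal(max_shift_clusters(tie, 1, 2)$rising, 1)
  # all rising -> no falling candidate
  allup <- make_clusters(list(c(0.2, 0.5), c(0.1, 0.3)))
  expect_true(is.na(max_shift_clusters(allup, 1, 2)$falling))
})

test_that("diagonal band probability matches brute-force double sums", {
  flat <- make_clusters(list(c(0.5, 0.5)))$clusters[[1]]
  expect_equal(band_probability(flat, 1, 2), 1)
  moved <- make_clusters(list(c(0.9, 0.3)))$clusters[[1]]
  expect_equal(band_probability(moved, 1, 2), 0)
  # uniform marginals: brute-force oracle over the 101-point grid
  unif <- matrix(1 / 101, 101, 2)
  oracle <- 0
  for (i in 1:101) for (j in 1:101) {
    if (abs(grid[i] - grid[j]) <= 0.1 + 1e-12) oracle <- oracle + (1 / 101)^2
  }
  expect_equal(band_probability(unif, 1, 2), oracle)
  # 2011 of the 101^2 grid pairs lie in the band; continuum value 0.19
  expect_equal(oracle, 2011 / 101^2)
  expect_lt(abs(oracle - (1 - 0.9^2)), 0.01)
})

test_that("band probability is symmetric in timepoints and monotone in delta", {
  set.seed(7)
  p1 <- vaf_to_ccf_posterior(30, 70, 0.9)$probs
  p2 <- vaf_to_ccf_posterior(55, 45, 0.9)$probs
  probs <- cbind(p1, p2)
  expect_equal(band_probability(probs, 1, 2), band_probability(probs, 2, 1))
  deltas <- c(0.3, 0.2, 0.1, 0.05, 0)
  ps <- vapply(deltas, function(d) band_probability(probs, 1, 2, d), 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BH adjustment reproduces the step-up procedure", {
  q <- bh_adjust(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(sum(q < 0.1), 3)          # thresholds 0.025/0.05/0.075/0.1
  expect_equal(bh_adjust(0.2), 0.2)      # single value unchanged
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
})

test_that("BH equals the brute-force rejection-set oracle for small families", {
  set.seed(31)
  for (rep in 1:12) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12,
                 info = paste("family:", paste(p, collapse = ",")))
  }
})

test_that("a strong true shift is called evolved after cohort FDR pooling", {
  set.seed(101)
  # one shifted patient (CCF 1->1 trunk, 0.7->0.2 subclone) among nulls
  mk_patient <- function(ccfs, pid) {
    n <- 30 * length(ccfs)
    ccf_true <- do.call(rbind, lapply(ccfs, function(cc)
      matrix(rep(cc, each = 30), 30, byrow = FALSE)))
    cm <- sim_cm(ccf_true, depth = 100, seed = sample.int(1e6, 1))
    cl <- consensus_clusters(gibbs_cluster(cm, 300, 150,
                                           seed = sample.int(1e6, 1)))
    tl <- data.frame(day = c(0, 120), is_relapse = c(FALSE, FALSE))
    patient_shift_tests(cl, tl, patient_id = pid)
  }
  tests <- rbind(
    mk_patient(list(c(1, 1), c(0.7, 0.2)), "shifted"),
    mk_patient(list(c(1, 1), c(0.5, 0.5)), "null1"),
    mk_patient(list(c(1, 1), c(0.35, 0.35)), "null2"))
  res <- classify_cohort(tests)
  pats <- res$patients
  expect_true(pats$evolved[pats$patient_id == "shifted"])
  expect_false(any(pats$evolved[pats$patient_id != "shifted"]))
  expect_true(all(res$tests$q_adj >= res$tests$band_prob))
})

test_that("the 0.05 CCF threshold flags a superset of the 0.1 threshold", {
  set.seed(55)
  tests <- data.frame(
    patient_id = sprintf("P%02d", 1:12),
    cluster_id = 1, direction = "rising",
    delta_ccf = runif(12, 0.02, 0.4) * sample(c(-1, 1), 12, TRUE),
    band_prob = runif(12, 0, 0.2))
  strict <- classify_cohort(tests, tau = 0.1)$patients
  loose <- classify_cohort(tests, tau = 0.05)$patients
  expect_true(all(strict$patient_id[strict$evolved] %in%
                  loose$patient_id[loose$evolved]))
})

test_that("relapse samples are excluded from the shift window", {
  cl <- make_clusters(list(c(1, 1, 1), c(0.5, 0.45, 0.05)))
  tl <- data.frame(day = c(0, 180, 400), is_relapse = c(FALSE, FALSE, TRUE))
  tests <- patient_shift_tests(cl, tl, patient_id = "P1")
  expect_true(all(tests$t1_day == 180))
  # no eligible post-baseline sample -> no tests
  tl2 <- data.frame(day = c(0, 400), is_relapse = c(FALSE, TRUE))
  expect_null(patient_shift_tests(cl, tl2[1:2, ], patient_id = "P1"))
})
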