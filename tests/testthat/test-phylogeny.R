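# Phylogeny enumeration and selection under CCF constraints.

test_that("trunk/A/B instance admits exactly the chain topology", {
  ccf <- rbind(`1` = c(1, 1), `2` = c(0.6, 0.6), `3` = c(0.5, 0.5))
  trees <- feasible_trees(ccf)
  expect_length(trees, 1)
  expect_equal(unname(trees[[1]]$parent), c(0L, 1L, 2L))
})

test_that("equal-CCF siblings admit the three classic topologies", {
  ccf <- rbind(`1` = c(1, 1), `2` = c(0.3, 0.3), `3` = c(0.3, 0.3))
  trees <- feasible_trees(ccf)
  expect_length(trees, 3)
  parents <- vapply(trees, function(t) paste(t$parent, collapse = ""),
                    character(1))
  expect_setequal(parents, c("011", "012", "031"))
})

test_that("a single cluster yields the single-node tree", {
  trees <- feasible_trees(matrix(c(1, 0.9), 1))
  expect_length(trees, 1)
  expect_equal(unname(trees[[1]]$parent), 0L)
})

test_that("enumeration matches brute force over all parent maps", {
  brute_force <- phylo_brute_force
  set.seed(17)
  for (rep in 1:8) {
    K <- sample(2:5, 1)
    ccf <- cbind(runif(K), runif(K))
    ccf[1, ] <- 1  # truncal clone
    expected <- sort(brute_force(ccf))
    rownames(ccf) <- seq_len(K)
    got <- tryCatch(
      sort(vapply(feasible_trees(ccf), function(t)
        paste(t$parent, collapse = ""), character(1))),
      error = function(e) character(0))
    expect_equal(got, unname(expected), info = paste("K =", K))
  }
})

test_that("every enumerated tree passes the independent constraint checker", {
  set.seed(23)
  ccf <- rbind(`1` = c(1, 1, 1), `2` = c(0.55, 0.4, 0.3),
               `3` = c(0.4, 0.35, 0.3), `4` = c(0.1, 0.2, 0.25))
  for (tr in feasible_trees(ccf)) expect_true(isTRUE(check_tree(tr)))
  expect_error(feasible_trees(rbind(`1` = c(0.5, 0.5), `2` = c(0.6, 0.4))),
               "eps")
})

test_that("a unique feasible tree is returned unchanged by selection", {
  ccf <- rbind(`1` = c(1, 1), `2` = c(0.6, 0.6), `3` = c(0.5, 0.5))
  trees <- feasible_trees(ccf)
  sel <- select_tree(trees, days = c(0, 100))
  expect_equal(sel$parent, trees[[1]]$parent)
})

test_that("equal goodness of fit falls back to the shallowest tree", {
  # perfectly flat clones: every topology fits equally (R2 degenerate)
  ccf <- rbind(`1` = c(1, 1, 1), `2` = c(0.3, 0.3, 0.3),
               `3` = c(0.3, 0.3, 0.3))
  trees <- feasible_trees(ccf)
  sel <- select_tree(trees, days = c(0, 50, 100), scale = rep(1e6, 3))
  expect_equal(sel$depth, min(vapply(trees, `[[`, 0L, "depth")))
  expect_equal(unname(sel$parent), c(0L, 1L, 1L))
})

test_that("nested growth is recognized against the sibling topology", {
  # truth: trunk -> A -> B with exponential exclusive compartments;
  # both the nested and the sibling tree are feasible, but only the
  # nested one makes all exclusive trajectories log-linear
  days <- c(0, 30, 60, 90, 135, 180)
  wins <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    nT <- 2e11 * exp(-0.010 * days)            # trunk-exclusive
    nA <- 8e10 * exp(-0.012 * days)            # A-exclusive
    nB <- 1e9 * exp(0.015 * days)              # B nested under A
    tot <- nT + nA + nB
    ccf <- rbind(`1` = rep(1, 6), `2` = (nA + nB) / tot, `3` = nB / tot)
    # observe CCF through binomial read counts at depth 300
    obs <- t(apply(ccf, 1, function(cc) {
      alt <- rbinom(length(cc), 300, cc / 2)
      round(pmin(2 * alt / 300, 1), 2)
    }))
    obs[1, ] <- 1
    rownames(obs) <- 1:3
    trees <- feasible_trees(obs, eps = 0.04)
    sel <- select_tree(trees, days, scale = tot)
    if (identical(unname(sel$parent), c(0L, 1L, 2L))) wins <- wins + 1
  }
  expect_gte(wins, 18)  # >= 90% of 20 seeds
})

test_that("newick export and parent table are consistent", {
  ccf <- rbind(`1` = c(1, 1), `2` = c(0.6, 0.6), `3` = c(0.5, 0.5))
  tr <- feasible_trees(ccf)[[1]]
  expect_equal(tree_newick(tr), "(((3)2)1)germline;")
  tt <- tree_table(tr)
  expect_equal(tt$parent_id, c(0L, 1L, 2L))
  # ape can parse the exported string (singleton internal nodes allowed)
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = tree_newick(tr))
  expect_false(is.null(ph))
})

test_that("clone-exclusive CCF subtracts children and clips at zero", {
  ccf <- rbind(`1` = c(1, 1), `2` = c(0.6, 0.8), `3` = c(0.5, 0.4))
  tr <- feasible_trees(ccf)[[1]]          # chain 1 -> 2 -> 3
  ex <- exclusive_ccf(tr)
  expect_equal(unname(ex["1", ]), c(0.4, 0.2))
  expect_equal(unname(ex["2", ]), c(0.1, 0.4))
  expect_equal(unname(ex["3", ]), c(0.5, 0.4))
  bad <- rbind(`1` = c(1, 0.5), `2` = c(0.98, 0.52))
  tr2 <- feasible_trees(bad, eps = 0.05)[[1]]
  expect_warning(ex2 <- exclusive_ccf(tr2), "clipped")
  expect_true(all(ex2 >= 0))
})
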