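# Shared fixture builders. Everything is generated in code; no stored
# binary fixtures.

grid <- clonedyn::ccf_grid()

# posterior object concentrated on a single grid point
point_mass_posterior <- function(ccf) {
  probs <- as.numeric(abs(grid - ccf) < 1e-9)
  structure(list(grid = grid, probs = probs / sum(probs), m = 1L,
                 point_estimate = grid[which.max(probs)],
                 alt = NA_integer_, depth = NA_integer_),
            class = "ccf_posterior")
}

# CCF matrix for n mutations with true per-timepoint CCFs, binomial
# counts at the given depth (purity 1, diploid het: VAF = CCF / 2)
sim_cm <- function(ccf_true, depth = 100, seed = 1) {
  set.seed(seed)
  n <- nrow(ccf_true); Tn <- ncol(ccf_true)
  posts <- lapply(seq_len(n), function(j) {
    lapply(seq_len(Tn), function(t) {
      alt <- rbinom(1, depth, ccf_true[j, t] / 2)
      vaf_to_ccf_posterior(alt, depth - alt, purity = 1)
    })
  })
  names(posts) <- sprintf("m%03d", seq_len(n))
  ccf_matrix(posts, sample_id = paste0("S", seq_len(Tn)))
}

# clone_clusters object built directly from per-cluster CCF trajectories
# (near point-mass posteriors); for shift/phylogeny unit tests
make_clusters <- function(ccf_point_list, n_members = 10) {
  Tn <- length(ccf_point_list[[1]])
  clusters <- lapply(seq_along(ccf_point_list), function(k) {
    probs <- vapply(ccf_point_list[[k]],
                    function(c) point_mass_posterior(c)$probs,
                    numeric(length(grid)))
    list(cluster_id = k,
         members = sprintf("c%d_m%02d", k, seq_len(n_members)),
         ccf_probs = probs, ccf_point = ccf_point_list[[k]],
         n_members = n_members, singleton = n_members == 1)
  })
  assignment <- setNames(rep(seq_along(clusters), each = n_members),
                         unlist(lapply(clusters, `[[`, "members")))
  structure(list(clusters = clusters, assignment = assignment,
                 sample_id = paste0("S", seq_len(Tn)), cm = NULL),
            class = "clone_clusters")
}

# ground-truth clusters + tree for a sim_patient (bypasses DP clustering
# so kinetics can be tested against known cluster membership)
true_clusters <- function(sp) {
  cm <- patient_ccf_matrix(sp$mutations, sp$segments, sp$timeline)
  z <- sp$truth$assignment
  G <- length(grid); Tn <- ncol(sp$truth$ccf)
  clusters <- lapply(sort(unique(z)), function(k) {
    rows <- which(z == k)
    probs <- clonedyn:::cluster_posterior(cm$logp, rows, G, Tn)
    list(cluster_id = k, members = cm$mutation_id[rows],
         ccf_probs = probs,
         ccf_point = grid[apply(probs, 2, which.max)],
         n_members = length(rows), singleton = length(rows) == 1)
  })
  assignment <- setNames(z, cm$mutation_id)
  cl <- structure(list(clusters = clusters, assignment = assignment,
                       sample_id = cm$sample_id, cm = cm),
                  class = "clone_clusters")
  ccf_est <- t(vapply(clusters, `[[`, numeric(Tn), "ccf_point"))
  rownames(ccf_est) <- seq_len(nrow(ccf_est))
  tree <- clonedyn:::new_clone_tree(sp$truth$parent, ccf_est)
  list(clusters = cl, tree = tree)
}

# partition agreement: fraction of mutation pairs on which two
# assignments agree (same/different cluster)
pair_accuracy <- function(z1, z2) {
  n <- length(z1)
  a <- outer(z1, z1, "==")
  b <- outer(z2, z2, "==")
  mean(a[upper.tri(a)] == b[upper.tri(b)])
}
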