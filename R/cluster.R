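# Multi-timepoint Dirichlet-process clustering of mutations into
# subclones. Mutations are represented by their per-timepoint CCF
# posteriors on the shared grid; a cluster's CCF posterior per timepoint
# is the normalized product of its members' posteriors, and a mutation's
# likelihood under a cluster is the per-timepoint grid dot product.

#' Assemble a patient's CCF posterior matrix
#'
#' Builds the n-mutation x (grid x timepoint) posterior matrix consumed
#' by [gibbs_cluster()] from a list of per-mutation posterior lists.
#'
#' @param posteriors List (one element per mutation, named by mutation
#'   id) of lists of [vaf_to_ccf_posterior()] objects, one per timepoint
#'   in timeline order.
#' @param sample_id Character vector of sample ids (timeline order).
#' @return List with `prob`, `logp` (n x G*T matrices), `mutation_id`,
#'   `sample_id`.
#' @export
ccf_matrix <- function(posteriors, sample_id) {
  stopifnot(length(posteriors) >= 1)
  Tn <- length(posteriors[[1]])
  stopifnot(Tn == length(sample_id),
            all(vapply(posteriors, length, 0L) == Tn))
  G <- length(ccf_grid())
  prob <- t(vapply(posteriors, function(pp) {
    unlist(lapply(pp, `[[`, "probs"))
  }, numeric(G * Tn)))
  ids <- names(posteriors)
  if (is.null(ids)) ids <- paste0("mut", seq_along(posteriors))
  rownames(prob) <- ids
  list(prob = prob, logp = log(pmax(prob, 1e-12)),
       mutation_id = ids, sample_id = sample_id)
}

#' Dirichlet-process Gibbs clustering across timepoints
#'
#' Collapsed Gibbs sampling of a Dirichlet-process mixture over the
#' joint multi-timepoint CCF posteriors, with the concentration
#' parameter resampled each sweep under a Gamma(1,1) prior, so the
#' number of clusters varies along the chain. Initialization places all
#' mutations in a single cluster.
#'
#' @param cm CCF matrix from [ccf_matrix()] or [patient_ccf_matrix()].
#' @param n_iter Total sweeps (default 1000).
#' @param burn_in Discarded sweeps (default 500); must be < `n_iter`.
#' @param seed Optional integer seed.
#' @return Object of class `clone_chain`: `assign` (n_iter x n
#'   assignment matrix), `cocluster` (posterior co-clustering frequency
#'   matrix over post-burn-in sweeps), `gamma` and `K` traces, plus the
#'   input matrices.
#' @export
gibbs_cluster <- function(cm, n_iter = 1000, burn_in = 500, seed = NULL) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  G <- length(ccf_grid())
  Tn <- length(cm$sample_id)
  res <- dp_gibbs_chain(cm$logp, G, Tn, as.integer(n_iter),
                        as.integer(burn_in))
  dimnames(res$cocluster) <- list(cm$mutation_id, cm$mutation_id)
  structure(
    list(assign = res$assign, cocluster = res$cocluster,
         gamma = res$gamma, K = res$K, cm = cm,
         n_iter = n_iter, burn_in = burn_in),
    class = "clone_chain"
  )
}

#' @export
print.clone_chain <- function(x, ...) {
  post <- x$K[(x$burn_in + 1):x$n_iter]
  cat(sprintf("DP clustering chain: %d mutations, %d timepoints, %d sweeps\n",
              nrow(x$cocluster), length(x$cm$sample_id), x$n_iter))
  cat("posterior K: ")
  print(table(post))
  invisible(x)
}

#' Consensus subclone clusters from a chain
#'
#' Cuts the posterior co-clustering matrix with average-linkage
#' hierarchical clustering at distance 0.5 (i.e. pairs co-clustered in
#' at least half the retained sweeps tend to share a cluster). Cluster
#' CCF posteriors are the normalized per-timepoint products of member
#' posteriors; clusters are ordered by descending mean CCF at baseline,
#' ties broken by the lexicographically smallest member mutation id.
#' Singleton clusters are retained but flagged low-confidence.
#'
#' @param chain A `clone_chain` from [gibbs_cluster()].
#' @return Object of class `clone_clusters`: list of clusters (each with
#'   `cluster_id`, `members`, `ccf_probs` G x T matrix, `ccf_point`,
#'   `n_members`, `singleton`), the assignment vector, `sample_id`.
#' @export
consensus_clusters <- function(chain) {
  cm <- chain$cm
  n <- nrow(cm$prob)
  if (n == 1) {
    memb <- setNames(1L, cm$mutation_id)
  } else {
    d <- stats::as.dist(1 - chain$cocluster)
    hc <- stats::hclust(d, method = "average")
    memb <- stats::cutree(hc, h = 0.5)
  }
  ids <- sort(unique(memb))
  G <- length(ccf_grid())
  Tn <- length(cm$sample_id)
  clusters <- lapply(ids, function(k) {
    rows <- which(memb == k)
    probs <- cluster_posterior(cm$logp, rows, G, Tn)
    list(members = cm$mutation_id[rows],
         ccf_probs = probs,
         ccf_point = ccf_grid()[apply(probs, 2, which.max)],
         n_members = length(rows),
         singleton = length(rows) == 1L)
  })
  # order by descending mean baseline CCF; ties by smallest member id
  base_mean <- vapply(clusters, function(cl) sum(ccf_grid() * cl$ccf_probs[, 1]),
                      numeric(1))
  first_id <- vapply(clusters, function(cl) min(cl$members), character(1))
  ord <- order(-base_mean, first_id)
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) clusters[[k]]$cluster_id <- k
  assignment <- setNames(integer(n), cm$mutation_id)
  for (cl in clusters) assignment[cl$members] <- cl$cluster_id
  structure(
    list(clusters = clusters, assignment = assignment,
         sample_id = cm$sample_id, cm = cm),
    class = "clone_clusters"
  )
}

#' Build clusters from a fixed assignment
#'
#' Constructs a `clone_clusters` object from a known mutation-to-clone
#' assignment (e.g. simulation ground truth, or an externally curated
#' clustering), with cluster CCF posteriors formed exactly as in
#' [consensus_clusters()]. Cluster ids follow the assignment labels.
#'
#' @param cm CCF matrix from [ccf_matrix()] or [patient_ccf_matrix()].
#' @param assignment Integer vector of clone labels, one per mutation
#'   (in `cm` row order).
#' @return A `clone_clusters` object.
#' @export
clusters_from_assignment <- function(cm, assignment) {
  stopifnot(length(assignment) == nrow(cm$prob))
  G <- length(ccf_grid())
  Tn <- length(cm$sample_id)
  clusters <- lapply(sort(unique(assignment)), function(k) {
    rows <- which(assignment == k)
    probs <- cluster_posterior(cm$logp, rows, G, Tn)
    list(cluster_id = as.integer(k), members = cm$mutation_id[rows],
         ccf_probs = probs,
         ccf_point = ccf_grid()[apply(probs, 2, which.max)],
         n_members = length(rows), singleton = length(rows) == 1L)
  })
  structure(list(clusters = clusters,
                 assignment = setNames(as.integer(assignment),
                                       cm$mutation_id),
                 sample_id = cm$sample_id, cm = cm),
            class = "clone_clusters")
}

# Normalized product of member posteriors, per timepoint block.
cluster_posterior <- function(logp, rows, G, Tn) {
  s <- colSums(logp[rows, , drop = FALSE])
  probs <- matrix(NA_real_, G, Tn)
  for (t in seq_len(Tn)) {
    blk <- s[((t - 1) * G + 1):(t * G)]
    w <- exp(blk - max(blk))
    probs[, t] <- w / sum(w)
  }
  probs
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("%d consensus subclones over %d timepoints\n",
              length(x$clusters), length(x$sample_id)))
  for (cl in x$clusters) {
    cat(sprintf("  clone %d (%d mutations%s): CCF %s\n", cl$cluster_id,
                cl$n_members, if (cl$singleton) ", singleton" else "",
                paste(sprintf("%.2f", cl$ccf_point), collapse = " -> ")))
  }
  invisible(x)
}

#' Cluster table for a set of consensus clusters
#'
#' @param x A `clone_clusters` object.
#' @param patient_id Optional patient label column.
#' @return Data.frame with one row per (cluster, timepoint).
#' @export
cluster_table <- function(x, patient_id = NA_character_) {
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(patient_id = patient_id, cluster_id = cl$cluster_id,
               n_mutations = cl$n_members,
               sample_id = x$sample_id,
               ccf = cl$ccf_point,
               singleton = cl$singleton,
               row.names = NULL)
  }))
}
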