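# Phylogeny enumeration under CCF constraints. Clone trees are parent
# maps over cluster ids rooted (possibly via a synthetic germline node,
# id 0, CCF 1 at all timepoints) and must satisfy, at every timepoint:
#   pigeonhole:   parent CCF >= child CCF - eps for every edge
#   sibling sum:  sum of children CCF <= parent CCF + eps
#                 (<= 1 + eps under the germline root)

#' Enumerate phylogenies consistent with the CCF constraints
#'
#' Exhaustively enumerates all parent maps over the clusters satisfying
#' the pigeonhole (parent-progeny ordering) and sibling-sum constraints
#' with tolerance `eps` on the CCF point estimates. A synthetic germline
#' node (id 0) with CCF 1 at all timepoints roots every tree; when a
#' truncal cluster is present the constraints force it to be the only
#' child of the germline node.
#'
#' @param ccf K x T matrix of cluster CCF point estimates (rows named or
#'   numbered by cluster id), or a `clone_clusters` object.
#' @param eps CCF tolerance on both constraints (default 0.02).
#' @param max_clusters Safety cap for exhaustive enumeration (default 8).
#' @return List of `clone_tree` objects, each a list with `parent`
#'   (integer vector, 0 = germline), `ccf`, `depth`.
#' @export
feasible_trees <- function(ccf, eps = 0.02, max_clusters = 8) {
  ccf <- as_ccf_matrix(ccf)
  K <- nrow(ccf)
  if (K > max_clusters) {
    stop("exhaustive enumeration supports at most ", max_clusters, " clusters")
  }
  if (K == 1) {
    return(list(new_clone_tree(c(`1` = 0L), ccf)))
  }
  Tn <- ncol(ccf)
  # candidate parents per cluster: germline (0) always; cluster j if
  # ccf[j, t] >= ccf[k, t] - eps at all timepoints
  cand <- lapply(seq_len(K), function(k) {
    ok <- vapply(seq_len(K), function(j) {
      j != k && all(ccf[j, ] >= ccf[k, ] - eps)
    }, logical(1))
    c(0L, which(ok))
  })
  trees <- list()
  parent <- integer(K)
  recurse <- function(k) {
    if (k > K) {
      if (is_acyclic(parent) && sum_rule_ok(parent, ccf, eps)) {
        trees[[length(trees) + 1]] <<- new_clone_tree(parent, ccf)
      }
      return(invisible())
    }
    for (p in cand[[k]]) {
      parent[k] <<- p
      recurse(k + 1)
    }
  }
  recurse(1L)
  if (!length(trees)) {
    stop("no feasible phylogeny at eps = ", eps,
         "; consider increasing the tolerance")
  }
  trees
}

as_ccf_matrix <- function(x) {
  if (inherits(x, "clone_clusters")) {
    m <- t(vapply(x$clusters, `[[`, numeric(length(x$sample_id)), "ccf_point"))
    rownames(m) <- vapply(x$clusters, `[[`, integer(1), "cluster_id")
    m
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
    m
  }
}

is_acyclic <- function(parent) {
  K <- length(parent)
  for (k in seq_len(K)) {
    seen <- integer(0)
    node <- k
    while (node != 0L) {
      if (node %in% seen) return(FALSE)
      seen <- c(seen, node)
      node <- parent[node]
    }
  }
  TRUE
}

sum_rule_ok <- function(parent, ccf, eps) {
  Tn <- ncol(ccf)
  for (p in unique(parent)) {
    kids <- which(parent == p)
    if (!length(kids)) next
    ksum <- colSums(ccf[kids, , drop = FALSE])
    cap <- if (p == 0L) rep(1, Tn) else ccf[p, ]
    if (any(ksum > cap + eps)) return(FALSE)
  }
  TRUE
}

#' Construct a clone tree from a parent map
#'
#' @param parent Integer vector: parent cluster id per cluster, 0 for
#'   the germline root.
#' @param ccf K x T matrix of cluster CCF point estimates.
#' @return A `clone_tree` (not validated; see [check_tree()]).
#' @export
clone_tree <- function(parent, ccf) {
  ccf <- as.matrix(ccf)
  if (is.null(rownames(ccf))) rownames(ccf) <- seq_len(nrow(ccf))
  stopifnot(length(parent) == nrow(ccf), is_acyclic(as.integer(parent)))
  new_clone_tree(parent, ccf)
}

new_clone_tree <- function(parent, ccf) {
  parent <- as.integer(parent)
  names(parent) <- rownames(ccf)
  depth <- vapply(seq_along(parent), function(k) {
    d <- 0L; node <- k
    while (node != 0L) { d <- d + 1L; node <- parent[node] }
    d
  }, integer(1))
  structure(list(parent = parent, ccf = ccf, depth = max(depth),
                 node_depth = depth),
            class = "clone_tree")
}

#' Verify a clone tree against the CCF constraints
#'
#' Independent re-check of acyclicity, single rooting, pigeonhole
#' ordering and sibling sums; used internally after enumeration and
#' available for external validation.
#'
#' @param tree A `clone_tree`.
#' @param eps Tolerance.
#' @return `TRUE` or a character vector of violated constraints.
#' @export
check_tree <- function(tree, eps = 0.02) {
  parent <- tree$parent; ccf <- tree$ccf
  bad <- character(0)
  if (!is_acyclic(parent)) bad <- c(bad, "cycle")
  for (k in seq_along(parent)) {
    p <- parent[k]
    if (p != 0L && any(ccf[p, ] < ccf[k, ] - eps)) {
      bad <- c(bad, sprintf("pigeonhole violated at edge %s -> %s",
                            rownames(ccf)[p], rownames(ccf)[k]))
    }
  }
  if (!sum_rule_ok(parent, ccf, eps)) bad <- c(bad, "sibling sum violated")
  if (length(bad)) bad else TRUE
}

#' Select the phylogeny maximizing exponential-fit goodness
#'
#' Scores each candidate tree by the summed R-squared of the per-clone
#' exponential fits of clone-exclusive cell counts under that topology
#' (a clone's exclusive CCF is its cluster CCF minus the sum of its
#' children's, clipped at 0). Ties go to the shallowest tree, then to
#' the lexicographically smallest parent vector.
#'
#' @param trees List of `clone_tree` objects (from [feasible_trees()]).
#' @param days Sample days.
#' @param scale Per-timepoint multiplier converting CCF to circulating
#'   cells (ALC x purity x blood volume); defaults to 1 (fits on CCF).
#' @return The selected `clone_tree`, with attributes `score` and `fits`.
#' @export
select_tree <- function(trees, days, scale = rep(1, ncol(trees[[1]]$ccf))) {
  stopifnot(length(trees) >= 1)
  if (length(trees) == 1) {
    tr <- trees[[1]]
    attr(tr, "fits") <- topology_fits(tr, days, scale)
    attr(tr, "score") <- sum(vapply(attr(tr, "fits"), function(f)
      if (is.na(f$r2)) 0 else f$r2, numeric(1)))
    return(tr)
  }
  scored <- lapply(trees, function(tr) {
    fits <- topology_fits(tr, days, scale)
    r2 <- vapply(fits, function(f) if (is.na(f$r2)) 0 else f$r2, numeric(1))
    list(tree = tr, fits = fits, score = sum(r2))
  })
  score <- vapply(scored, `[[`, numeric(1), "score")
  depth <- vapply(scored, function(s) s$tree$depth, integer(1))
  lex <- vapply(scored, function(s)
    paste(sprintf("%02d", s$tree$parent), collapse = ""), character(1))
  best <- order(-score, depth, lex)[1]
  tr <- scored[[best]]$tree
  attr(tr, "fits") <- scored[[best]]$fits
  attr(tr, "score") <- scored[[best]]$score
  tr
}

# Deterministic per-clone exponential fits of exclusive counts under a
# topology.
topology_fits <- function(tree, days, scale) {
  ccf_ex <- exclusive_ccf(tree)
  lapply(seq_len(nrow(ccf_ex)), function(k) {
    fit_exponential(ccf_ex[k, ] * scale, days, quiet = TRUE)
  })
}

#' Clone-exclusive CCF under a topology
#'
#' @param tree A `clone_tree`.
#' @return K x T matrix of cluster CCF minus the summed CCF of direct
#'   children, clipped at 0 (a warning is raised when clipping occurs).
#' @export
exclusive_ccf <- function(tree) {
  ccf <- tree$ccf
  ex <- ccf
  for (k in seq_along(tree$parent)) {
    p <- tree$parent[k]
    if (p != 0L) ex[p, ] <- ex[p, ] - ccf[k, ]
  }
  if (any(ex < -1e-9)) {
    warning("negative clone-exclusive CCF clipped to 0", call. = FALSE)
  }
  pmax(ex, 0)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone tree (0 = germline):\n")
  for (k in seq_along(x$parent)) {
    cat(sprintf("  %s -> %s\n", x$parent[k], names(x$parent)[k]))
  }
  invisible(x)
}

#' Newick string for a clone tree
#'
#' Cluster ids label both internal nodes and leaves; the synthetic
#' germline node is labelled `germline`.
#'
#' @param tree A `clone_tree`.
#' @return Single Newick string, semicolon-terminated.
#' @export
tree_newick <- function(tree) {
  labs <- names(tree$parent)
  kids_of <- function(p) which(tree$parent == p)
  render <- function(node) {
    kids <- kids_of(node)
    lab <- if (node == 0L) "germline" else labs[node]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(sort(kids), render, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(render(0L), ";")
}

#' Parent-list table for a clone tree
#' @param tree A `clone_tree`.
#' @return Data.frame with `cluster_id` and `parent_id` (0 = germline).
#' @export
tree_table <- function(tree) {
  data.frame(cluster_id = names(tree$parent),
             parent_id = unname(tree$parent), row.names = NULL)
}
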