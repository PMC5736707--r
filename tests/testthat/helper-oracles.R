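# Independent oracles, kept deliberately separate from the package
# implementations they check.

# BH adjusted value of hypothesis i = smallest level at which the
# step-up rule rejects i, searched over all candidate levels.
bh_oracle <- function(p) {
  m <- length(p)
  cand <- sort(unique(c(p * m / rep(1:m, each = length(p)), 1)))
  vapply(seq_len(m), function(i) {
    rejected_at <- vapply(cand, function(a) {
      o <- order(p)
      k <- which(p[o] <= (1:m) * a / m + 1e-12)
      if (!length(k)) return(FALSE)
      i %in% o[seq_len(max(k))]
    }, logical(1))
    min(cand[rejected_at])
  }, numeric(1))
}

# All feasible parent maps by literal filtering of every parent vector:
# acyclicity, pigeonhole ordering and sibling sums from first principles.
phylo_brute_force <- function(ccf, eps = 0.02) {
  K <- nrow(ccf)
  opts <- lapply(seq_len(K), function(k) setdiff(0:K, k))
  combos <- do.call(expand.grid, opts)
  ok <- apply(combos, 1, function(par) {
    par <- as.integer(par)
    for (k in seq_len(K)) {
      seen <- integer(0); node <- k
      while (node != 0) {
        if (node %in% seen) return(FALSE)
        seen <- c(seen, node); node <- par[node]
      }
    }
    for (k in seq_len(K)) {
      p <- par[k]
      if (p != 0 && any(ccf[p, ] < ccf[k, ] - eps)) return(FALSE)
    }
    for (p in 0:K) {
      kids <- which(par == p)
      if (!length(kids)) next
      cap <- if (p == 0) rep(1, ncol(ccf)) else ccf[p, ]
      if (any(colSums(ccf[kids, , drop = FALSE]) > cap + eps)) return(FALSE)
    }
    TRUE
  })
  apply(combos[ok, , drop = FALSE], 1, paste, collapse = "")
}
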