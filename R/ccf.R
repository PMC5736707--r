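# CCF model: read counts -> posterior over cancer cell fraction.
#
# The generative model is the standard allele-fraction transformation: a
# mutation present at multiplicity m (mutant copies per carrying tumor
# cell) in a fraction `ccf` of tumor cells, in a sample of purity `alpha`
# with local tumor copy number q_t and normal copy number q_n, yields an
# expected variant allele fraction
#   f = alpha * m * ccf / (alpha * q_t + (1 - alpha) * q_n).
# The posterior over CCF is computed on a fixed 101-point grid under a
# uniform prior with a binomial read-count likelihood.

#' The CCF grid
#'
#' All posteriors in the package live on this fixed grid of 101 equally
#' spaced cancer cell fractions, 0 to 1 in steps of 0.01 (matching the
#' two-decimal reporting resolution of CCF estimates).
#'
#' @return Numeric vector `seq(0, 1, by = 0.01)`.
#' @export
ccf_grid <- function() seq(0, 1, by = 0.01)

#' Expected variant allele fraction for a given CCF
#'
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param purity Sample purity (tumor cell fraction) in (0, 1\].
#' @param m Mutation multiplicity (mutant copies per carrying cell),
#'   positive integer no larger than the local tumor copy number.
#' @param q_t Local total copy number in tumor cells.
#' @param q_n Local copy number in normal cells (2 for autosomes).
#' @return Expected VAF, clipped to \[1e-6, 1 - 1e-6\] so it is always a
#'   valid binomial success probability.
#' @examples
#' expected_vaf(1, 1, 1, 2)    # clonal heterozygous diploid: 0.5
#' expected_vaf(0.625, 0.8, 1, 2)
#' @export
expected_vaf <- function(ccf, purity, m, q_t, q_n = 2) {
  stopifnot(all(ccf >= 0), all(ccf <= 1), purity > 0, purity <= 1,
            q_t > 0, q_n > 0, m >= 1)
  if (m > q_t) {
    stop("multiplicity m (", m, ") exceeds tumor copy number q_t (", q_t, ")")
  }
  f <- purity * m * ccf / (purity * q_t + (1 - purity) * q_n)
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' Choose mutation multiplicity by marginal likelihood
#'
#' Selects `m` in `1..major_cn` maximizing the binomial likelihood of the
#' observed counts integrated over a uniform CCF grid; ties broken toward
#' the smallest `m`.
#'
#' @param alt,ref Alt and ref read counts.
#' @param purity Sample purity.
#' @param q_t Local total tumor copy number.
#' @param major_cn Major allele copy number (upper bound for `m`).
#' @param q_n Normal copy number.
#' @return Integer multiplicity.
#' @export
choose_multiplicity <- function(alt, ref, purity, q_t, major_cn, q_n = 2) {
  stopifnot(major_cn >= 1)
  m_max <- max(1L, min(as.integer(major_cn), as.integer(floor(q_t))))
  if (m_max == 1L) return(1L)
  grid <- ccf_grid()
  n <- alt + ref
  marg <- vapply(seq_len(m_max), function(m) {
    mean(dbinom(alt, n, expected_vaf(grid, purity, m, q_t, q_n)))
  }, numeric(1))
  which.max(marg)  # which.max returns the first (smallest) maximizer
}

#' CCF posterior from read counts
#'
#' Computes the posterior distribution of the cancer cell fraction on the
#' 101-point grid under a uniform prior: `probs[i]` is proportional to
#' `Binomial(alt | alt + ref, expected_vaf(grid[i], ...))`. Zero-alt
#' inputs are first-class (force-called mutations absent from a sample
#' get posteriors concentrated near 0). CCFs whose closed-form inversion
#' would exceed 1 are not clipped; their posterior mass piles up at 1.
#'
#' @inheritParams choose_multiplicity
#' @param m Multiplicity; `NULL` (default) selects it with
#'   [choose_multiplicity()].
#' @return Object of class `ccf_posterior`: list with `grid`, `probs`
#'   (normalized), `m`, `point_estimate` (posterior mode, ties toward the
#'   smaller CCF), `alt`, `depth`.
#' @examples
#' p <- vaf_to_ccf_posterior(25, 75, purity = 0.8)
#' p$point_estimate  # closed-form inversion 0.625, rounded onto the grid
#' @export
vaf_to_ccf_posterior <- function(alt, ref, purity, q_t = 2, major_cn = 1,
                                 q_n = 2, m = NULL) {
  stopifnot(alt >= 0, ref >= 0)
  grid <- ccf_grid()
  n <- alt + ref
  if (n < 1) {
    warning("mutation with zero depth: returning uniform CCF posterior")
    probs <- rep(1 / length(grid), length(grid))
    return(new_ccf_posterior(grid, probs, 1L, alt, n))
  }
  if (is.null(m)) m <- choose_multiplicity(alt, ref, purity, q_t, major_cn, q_n)
  ll <- dbinom(alt, n, expected_vaf(grid, purity, m, q_t, q_n), log = TRUE)
  probs <- exp(ll - max(ll))
  probs <- probs / sum(probs)
  new_ccf_posterior(grid, probs, m, alt, n)
}

new_ccf_posterior <- function(grid, probs, m, alt, depth) {
  structure(
    list(grid = grid, probs = probs, m = as.integer(m),
         point_estimate = grid[which.max(probs)],
         alt = alt, depth = depth),
    class = "ccf_posterior"
  )
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf("CCF posterior: mode %.2f (alt %d / depth %d, m = %d)\n",
              x$point_estimate, x$alt, x$depth, x$m))
  invisible(x)
}

# Posterior mean and sd on the grid (used for diagnostics and tests).
ccf_posterior_mean <- function(p) sum(p$grid * p$probs)
ccf_posterior_sd <- function(p) {
  mu <- sum(p$grid * p$probs)
  sqrt(max(0, sum(p$grid^2 * p$probs) - mu^2))
}

#' Per-mutation CCF posterior matrix for one patient
#'
#' Computes [vaf_to_ccf_posterior()] for every mutation at every
#' timepoint of a patient, using each sample's purity and the covering
#' copy-number segment, and assembles the matrices consumed by
#' [gibbs_cluster()].
#'
#' @param mutations One patient's mutation table (schema of
#'   [read_mutation_table()]).
#' @param segments Segment table or `NULL` (diploid assumed).
#' @param timeline The patient's timeline, sorted by day.
#' @return List with `prob` and `logp` (n x G*T matrices, timepoint
#'   blocks of normalized posteriors; log scale floored at `log(1e-12)`),
#'   `mutation_id`, `sample_id`, and the multiplicity matrix `m`.
#' @export
patient_ccf_matrix <- function(mutations, segments, timeline) {
  mutations <- normalize_mutation_table(mutations)
  samples <- timeline$sample_id
  muts <- unique(mutations$mutation_id)
  G <- length(ccf_grid())
  Tn <- length(samples)
  prob <- matrix(NA_real_, length(muts), G * Tn,
                 dimnames = list(muts, NULL))
  mmat <- matrix(1L, length(muts), Tn, dimnames = list(muts, samples))
  for (ti in seq_len(Tn)) {
    s <- samples[ti]
    alpha <- timeline$purity[ti]
    rows <- mutations[mutations$sample_id == s, , drop = FALSE]
    rows <- rows[match(muts, rows$mutation_id), , drop = FALSE]
    if (anyNA(rows$mutation_id)) {
      stop("sample ", s, " is missing force-called counts for some mutations")
    }
    for (j in seq_along(muts)) {
      seg <- lookup_segment(segments, s, rows$chrom[j], rows$pos[j])
      p <- vaf_to_ccf_posterior(rows$alt_count[j], rows$ref_count[j], alpha,
                                q_t = seg$total_cn, major_cn = seg$major_cn)
      prob[j, ((ti - 1) * G + 1):(ti * G)] <- p$probs
      mmat[j, ti] <- p$m
    }
  }
  list(prob = prob, logp = log(pmax(prob, 1e-12)),
       mutation_id = muts, sample_id = samples, m = mmat)
}
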