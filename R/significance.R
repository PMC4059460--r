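# One pass of the identification pipeline on an already-transformed matrix:
# refit per-base models for the given design, moderate, re-fit the mixture,
# rebuild the HMM (pi0 and the expressed mask depend only on coverage and
# are passed in fixed), decode, and extract regions.
identify_pass <- function(y, cov, design, pi0, cutoff, delta, retain_prob,
                          stat_mode, d0 = NULL, s02 = NULL) {
  fit <- fit_base_models(y, design)
  bs <- moderate_statistics(fit, cov, cutoff = cutoff, d0 = d0, s02 = s02)
  if (!any(bs$expressed)) {
    path <- rep(0L, length(bs$statistic))
    regions <- extract_regions(path, cov$positions, bs$statistic,
                               chrom = cov$chrom, stat_mode = stat_mode,
                               kind = bs$kind)
    return(list(fit = fit, stats = bs, mixture = NULL, hmm = NULL,
                path = path, regions = regions))
  }
  mix <- fit_mixture(bs$statistic[bs$expressed])
  hmm <- build_hmm(pi0, mix, delta = delta, retain_prob = retain_prob)
  path <- viterbi_decode(bs$statistic, hmm)
  regions <- extract_regions(path, cov$positions, bs$statistic,
                             chrom = cov$chrom, stat_mode = stat_mode,
                             kind = bs$kind)
  list(fit = fit, stats = bs, mixture = mix, hmm = hmm,
       path = path, regions = regions)
}

#' Permutation null distribution of region statistics
#'
#' For each of B permutations: permute the group labels across samples
#' (uniformly, with replacement over labelings, so a permutation may equal
#' the observed one), re-compute the per-base moderated statistics under the
#' permuted design, re-fit the mixture, re-run the HMM, and record the
#' region-level statistics of the resulting null state-2 regions. The
#' unexpressed fraction pi0 and the expressed mask depend only on coverage
#' and are not recomputed. Confounders (including library size) stay
#' attached to their samples; only the covariate of interest is permuted.
#'
#' @param cov a [coverage_matrix()].
#' @param design a [der_design()] with exactly two groups and no confounders
#'   beyond library size (the simple case-control permutation design).
#' @param B number of permutations (>= 1, default 50).
#' @param seed integer seed; the pool is reproducible given (inputs, seed).
#' @param offset,cutoff,delta,retain_prob,stat_mode pipeline parameters,
#'   matching the observed-data pass (see [derfind()]).
#' @return An object of class `null_pool`: list with `stats` (list of
#'   per-permutation null region statistics), `P_b` (null DER count per
#'   permutation), `B`, `seed`.
#' @export
permutation_null <- function(cov, design, B = 50L, seed = 1L,
                             offset = 0.5, cutoff = 5, delta = 1e-4,
                             retain_prob = 0.999,
                             stat_mode = c("mean", "sum")) {
  stat_mode <- match.arg(stat_mode)
  if (B < 1L) stop("B must be at least 1")
  if (any(table(design$groups) < 2L))
    stop("permutation null requires at least 2 samples per group")
  y <- coverage_transform(cov, offset)
  pi0 <- estimate_pi0(cov, cutoff)
  set.seed(seed)
  stats_list <- vector("list", B)
  for (b in seq_len(B)) {
    gp <- sample(design$groups)
    design_b <- design
    design_b$groups <- gp
    pass <- suppressWarnings(identify_pass(
      y, cov, design_b, pi0, cutoff, delta, retain_prob, stat_mode))
    rg <- pass$regions
    stats_list[[b]] <- rg$mean_stat[rg$state == 2L]
  }
  structure(list(stats = stats_list,
                 P_b = vapply(stats_list, length, 0L),
                 B = B, seed = seed),
            class = "null_pool")
}

#' @export
print.null_pool <- function(x, ...) {
  cat(sprintf("null_pool: %d permutations, %d null DERs total (seed %d)\n",
              x$B, sum(x$P_b), x$seed))
  invisible(x)
}

#' Empirical p-values for candidate regions
#'
#' Compares each candidate region's statistic with the pooled null region
#' statistics from all permutations. The default is two-sided with a
#' pseudocount, p = (1 + #\{|null| >= |obs|\}) / (1 + pool size), which is a
#' valid permutation p-value (always positive) and catches both directions.
#' `mode = "paper-exact"` instead returns the plain pooled fraction
#' #\{null > obs\} / pool size (combined with `sided = "one"` this is the
#' one-sided, pseudocount-free historical form, which can be exactly 0).
#'
#' @param observed numeric vector of candidate-region statistics.
#' @param pool a [permutation_null()] object.
#' @param mode `"pseudocount"` (default) or `"paper-exact"`.
#' @param sided `"two"` (default; compares absolute values) or `"one"`.
#' @return data.frame with columns `stat`, `n_null_ge`, `p`.
#' @export
empirical_pvalues <- function(observed, pool,
                              mode = c("pseudocount", "paper-exact"),
                              sided = c("two", "one")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  null_stats <- unlist(pool$stats, use.names = FALSE)
  N <- length(null_stats)
  if (N == 0L) {
    if (mode == "paper-exact")
      stop("empty null pool: cannot form paper-exact p-values")
    warning("empty null pool; all p-values set to 1")
    return(data.frame(stat = observed,
                      n_null_ge = rep(0L, length(observed)),
                      p = rep(1, length(observed))))
  }
  cnt <- vapply(observed, function(o) {
    if (sided == "two") sum(abs(null_stats) >= abs(o))
    else if (mode == "paper-exact") sum(null_stats > o)
    else sum(null_stats >= o)
  }, 0L)
  p <- if (mode == "pseudocount") (1 + cnt) / (1 + N) else cnt / N
  data.frame(stat = observed, n_null_ge = cnt, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity,
#' capped at 1 (the standard BH procedure, via [stats::p.adjust()]). The
#' output column is conventionally called q; regions with q below a chosen
#' threshold (0.05 by default elsewhere in the package) are reported
#' significant.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values, same length.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
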