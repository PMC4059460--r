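#' Canonical simulation scenarios
#'
#' Pre-specified study conditions used throughout the package's validation
#' (and reusable as templates). All return a [sim_config()]; run them with
#' [simulate_experiment()].
#'
#' * `scenario_planted()`: 100 kb genome, 20 expressed 500-bp regions with
#'   mean coverage 30, NB dispersion 0.1, n = 5+5. Ten regions are
#'   differentially expressed at |log2 FC| = 2 (five up, five down,
#'   alternating with the ten non-DE regions so the statistic track carries
#'   a genuine expressed null). Measures recovery of planted signal.
#' * `scenario_null()`: 20 kb genome, 8 expressed 500-bp regions, no
#'   differential expression, n = 5+5. Measures p-value calibration under
#'   the global null.
#' * `scenario_group_specific()`: 20 kb genome, six regions expressed only
#'   in group 1 (`log2fc = -Inf`: zero mean in group 2) plus three regions
#'   expressed equally in both groups — a one-chromosome analogue of a
#'   sex-chromosome comparison with n = 9 expressing vs 6 non-expressing
#'   samples (the classic male/female brain design), where the shared
#'   regions play the role of the pseudoautosomal part. Every
#'   group-specific region should be recovered as significant and
#'   directional; re-splitting the expressing group 5-vs-4 against itself
#'   should yield nothing. The unbalanced 9+6 design also keeps the
#'   permutation space large (5005 labelings), so the null pool is not
#'   dominated by re-draws of the observed labeling.
#'
#' @param seed integer seed passed to [sim_config()].
#' @return A `sim_config`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_planted <- function(seed = 1L) {
  k <- 0:19
  fc <- rep(0, 20)
  fc[k %% 2L == 1L] <- rep(c(2, -2), 5)
  sim_config(genome_length = 100000L, n_per_group = c(5L, 5L),
             regions = data.frame(start = 2250L + 5000L * k,
                                  end = 2750L + 5000L * k,
                                  mu = 30, log2fc = fc),
             dispersion = 0.1, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_null <- function(seed = 1L) {
  k <- 0:7
  sim_config(genome_length = 20000L, n_per_group = c(5L, 5L),
             regions = data.frame(start = 1250L + 2500L * k,
                                  end = 1750L + 2500L * k,
                                  mu = 30, log2fc = 0),
             dispersion = 0.1, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_group_specific <- function(seed = 1L) {
  k <- 0:8
  fc <- rep(c(-Inf, -Inf, 0), 3)
  sim_config(genome_length = 20000L, n_per_group = c(9L, 6L),
             regions = data.frame(start = 1100L + 2100L * k,
                                  end = 1600L + 2100L * k,
                                  mu = 30, log2fc = fc),
             dispersion = 0.1, seed = seed)
}
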