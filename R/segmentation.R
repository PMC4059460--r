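#' Prior probability of the unexpressed state
#'
#' Estimates pi0, the prior probability that a base is in the "not
#' expressed" hidden state, as the fraction of analyzed bases whose
#' across-sample average raw coverage is below the threshold c.
#'
#' @param cov a [coverage_matrix()].
#' @param cutoff average-coverage threshold c (> 0).
#' @return A number in \[0, 1\].
#' @export
estimate_pi0 <- function(cov, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  mean(rowMeans(cov$counts) < cutoff)
}

#' Two-groups normal mixture of base statistics
#'
#' Fits f(s) = pi1* f1(s) + pi2* f2(s), two normal components, by EM to the
#' statistics of expressed bases. Component 1 plays the empirical null
#' (equally-expressed state); component 2 the "interesting" component.
#' Initialization is robust: mu1 = median, sd1 = 1.4826 * MAD, pi1* = 0.95,
#' component 2 centered on the heavier tail with four times the null
#' variance. After convergence the labels are constrained so component 1 is
#' the narrower one (var2 >= var1).
#'
#' @param s numeric vector of statistics at expressed bases (>= 50 values).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param var_floor lower bound applied to component variances.
#' @param prop_floor lower bound applied to mixing proportions, so the
#'   downstream HMM always has a usable differential state.
#' @details
#' A free two-component EM can mislabel tracks whose "interesting" mass
#' sits in well-separated clusters on both sides of zero: the narrow
#' component then locks onto one signal cluster instead of the null. When
#' the free fit's null component lands away from the empirical-null center
#' (further than one robust SD from the median), the fit is redone with the
#' null component anchored at the empirical null — mean and variance fixed
#' at the median and squared MAD of the statistics — and EM updating only
#' the interesting component and the mixing proportion. The `anchored`
#' field records which route produced the returned fit.
#' @return An object of class `mixture_fit` with fields `pi1_star`,
#'   `pi2_star`, `mu1`, `var1`, `mu2`, `var2`, `loglik`, `n_iter`,
#'   `converged`, `anchored`.
#' @export
fit_mixture <- function(s, max_iter = 500L, tol = 1e-8,
                        var_floor = 1e-8, prop_floor = 1e-4) {
  s <- as.numeric(s)
  if (length(s) < 50L)
    stop("need at least 50 expressed-base statistics to fit the mixture")
  en <- empirical_null(s)
  scale0 <- stats::mad(s)           # already scaled by 1.4826
  if (scale0 < sqrt(var_floor)) scale0 <- max(stats::sd(s), sqrt(var_floor))
  fit <- mixture_em(s, stats::median(s), scale0, anchor = FALSE,
                    max_iter = max_iter, tol = tol,
                    var_floor = var_floor, prop_floor = prop_floor)
  if (abs(fit$mu1 - en$center) > max(en$scale, sqrt(var_floor))) {
    fit <- mixture_em(s, en$center, max(en$scale, sqrt(var_floor)),
                      anchor = TRUE, max_iter = max_iter, tol = tol,
                      var_floor = var_floor, prop_floor = prop_floor)
  }
  # On a pure-null sample the two-component likelihood surface is an
  # unidentifiable manifold and EM stalls at an arbitrary split. If two
  # components do not beat a single normal by a BIC-sized margin (3 extra
  # parameters), return the boundary fit: everything null, the mixing
  # proportion at its floor, and a vestigial wide alternative.
  m0 <- mean(s); v0 <- stats::var(s)
  ll_single <- sum(stats::dnorm(s, m0, sqrt(v0), log = TRUE))
  if (2 * (fit$loglik - ll_single) < 3 * log(length(s))) {
    fit <- structure(list(pi1_star = 1 - prop_floor, pi2_star = prop_floor,
                          mu1 = m0, var1 = v0, mu2 = m0, var2 = 4 * v0,
                          loglik = ll_single, n_iter = fit$n_iter,
                          converged = TRUE, anchored = fit$anchored,
                          prop_floored = TRUE, collapsed = TRUE),
                     class = "mixture_fit")
  }
  fit
}

# Empirical-null location/scale for a moderated-t track. Under no
# differential expression the statistic is approximately t-distributed:
# centered near 0 with scale near 1, with modest real-data drift. The
# estimate therefore comes from the points in a fixed central window
# (|s| <= window), which excludes well-separated signal clusters that
# break the MAD when they carry an appreciable share of the mass, and fits
# a truncated normal by maximum likelihood on that window. If essentially
# nothing is central (an all-signal track), the theoretical null (0, 1)
# is returned.
empirical_null <- function(s, window = 2.5) {
  core <- s[abs(s) <= window]
  m <- length(core)
  if (m < max(50, 0.05 * length(s)))
    return(list(center = 0, scale = 1))
  nll <- function(par) {
    mu <- par[1L]; sg <- exp(par[2L])
    mass <- stats::pnorm((window - mu) / sg) -
      stats::pnorm((-window - mu) / sg)
    -sum(stats::dnorm(core, mu, sg, log = TRUE)) + m * log(max(mass, 1e-12))
  }
  init <- c(stats::median(core), log(max(stats::sd(core), 0.05)))
  o <- tryCatch(stats::optim(init, nll), error = function(e) NULL)
  if (is.null(o) || !is.finite(o$value))
    return(list(center = stats::median(core),
                scale = max(stats::sd(core), 0.05)))
  list(center = o$par[1L], scale = min(exp(o$par[2L]), 2 * window))
}

# EM core. anchor = TRUE holds component 1 at the empirical null
# N(center, scale^2) and updates only (pi2, mu2, var2).
mixture_em <- function(s, center, scale, anchor, max_iter, tol,
                       var_floor, prop_floor) {
  mu1 <- center; sd1 <- scale
  v1 <- sd1^2; v2 <- 4 * v1
  lo <- s < mu1 - 2 * sd1; hi <- s > mu1 + 2 * sd1
  if (anchor && sum(lo | hi) >= 10L) {
    # the alternative must absorb everything non-null, possibly clusters in
    # both tails: start it on the moments of the out-of-band points so EM
    # does not lock onto a single tail
    out <- s[lo | hi]
    mu2 <- mean(out)
    v2 <- max(stats::var(out), v2)
  } else {
    mu2 <- if (sum(hi) >= sum(lo) && sum(hi) > 0) mean(s[hi])
           else if (sum(lo) > 0) mean(s[lo])
           else mu1 + 2 * sd1
  }
  pi2 <- 0.05
  ll_old <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- (1 - pi2) * stats::dnorm(s, mu1, sqrt(v1))
    d2 <- pi2 * stats::dnorm(s, mu2, sqrt(v2))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    pi2 <- mean(r2)
    if (pi2 < prop_floor) { pi2 <- prop_floor; floored <- TRUE }
    if (pi2 > 1 - prop_floor) pi2 <- 1 - prop_floor
    w1 <- sum(1 - r2); w2 <- sum(r2)
    if (!anchor) {
      mu1 <- sum((1 - r2) * s) / w1
      v1 <- sum((1 - r2) * (s - mu1)^2) / w1
    }
    mu2 <- sum(r2 * s) / w2
    v2 <- sum(r2 * (s - mu2)^2) / w2
    if (v1 < var_floor || v2 < var_floor) {
      warning("degenerate mixture component variance; flooring at ",
              var_floor)
      v1 <- max(v1, var_floor); v2 <- max(v2, var_floor)
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("mixture EM did not converge in ", max_iter, " iterations")
  if (!anchor && v2 < v1) {
    # label constraint: component 1 is the narrower (null) one
    tmp <- c(mu1, v1); mu1 <- mu2; v1 <- v2; mu2 <- tmp[1]; v2 <- tmp[2]
    pi2 <- 1 - pi2
  }
  structure(list(pi1_star = 1 - pi2, pi2_star = pi2,
                 mu1 = mu1, var1 = v1, mu2 = mu2, var2 = v2,
                 loglik = ll, n_iter = it, converged = converged,
                 anchored = anchor, prop_floored = floored),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("two-groups mixture: %.3f x N(%.3f, %.3f) + %.3f x N(%.3f, %.3f)\n",
              x$pi1_star, x$mu1, x$var1, x$pi2_star, x$mu2, x$var2))
  cat(sprintf("loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Assemble the three-state HMM
#'
#' Builds the hidden Markov model over states 0 (not expressed), 1
#' (expressed, not differential) and 2 (differentially expressed). State
#' priors scale the mixture proportions by the unexpressed fraction:
#' pi = (pi0, (1-pi0) pi1*, (1-pi0) pi2*). The transition matrix is fixed,
#' with `retain_prob` on the diagonal and the remainder split evenly, so
#' decoded segments are long at gene scale. Emissions are state 0 ~
#' N(0, delta) with delta a very small variance, state 1 ~ N(mu1, var1),
#' state 2 ~ N(mu2, var2) from the mixture fit.
#'
#' @param pi0 unexpressed-state prior from [estimate_pi0()].
#' @param mix a [fit_mixture()] result.
#' @param delta variance of the state-0 emission (default 1e-4).
#' @param retain_prob diagonal of the transition matrix (default 0.999).
#' @return An object of class `hmm_params`: `state_priors`, `transition`,
#'   `means`, `vars`.
#' @export
build_hmm <- function(pi0, mix, delta = 1e-4, retain_prob = 0.999) {
  if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
  if (retain_prob <= 0 || retain_prob >= 1)
    stop("retain_prob must be in (0, 1)")
  if (delta <= 0) stop("delta must be positive")
  priors <- c(pi0, (1 - pi0) * mix$pi1_star, (1 - pi0) * mix$pi2_star)
  off <- (1 - retain_prob) / 2
  A <- matrix(off, 3L, 3L)
  diag(A) <- retain_prob
  structure(list(state_priors = priors, transition = A,
                 means = c(0, mix$mu1, mix$mu2),
                 vars = c(delta, mix$var1, mix$var2)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params: priors", sprintf("%.4f", x$state_priors), "\n")
  cat("emissions: ",
      paste(sprintf("N(%.3f, %.4g)", x$means, x$vars), collapse = "  "), "\n")
  cat("retain probability:", x$transition[1, 1], "\n")
  invisible(x)
}

#' Viterbi decoding of the statistic track
#'
#' Computes the jointly most probable hidden-state path given the per-base
#' statistics, in log space. Ties are broken toward the lower-numbered
#' state (the conservative choice: prefer "not expressed" over "expressed"
#' over "differential").
#'
#' @param s numeric statistic track.
#' @param params an [build_hmm()] object.
#' @return Integer vector of states in \{0, 1, 2\}, one per base.
#' @export
viterbi_decode <- function(s, params) {
  bad <- which(!is.finite(s))
  if (length(bad))
    stop("non-finite statistic at track position ", bad[1L])
  n <- length(s)
  if (n == 0L) stop("empty statistic track")
  sdv <- sqrt(params$vars)
  le <- cbind(stats::dnorm(s, params$means[1L], sdv[1L], log = TRUE),
              stats::dnorm(s, params$means[2L], sdv[2L], log = TRUE),
              stats::dnorm(s, params$means[3L], sdv[3L], log = TRUE))
  lp <- log(pmax(params$state_priors, 1e-300))
  lA <- log(pmax(params$transition, 1e-300))
  tlA <- t(lA)
  bp <- matrix(0L, n, 3L)
  v <- lp + le[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      cand <- tlA + rep(v, each = 3L)   # cand[k, j] = v[j] + lA[j, k]
      j <- max.col(cand, ties.method = "first")
      v <- cand[cbind(1:3, j)] + le[t, ]
      bp[t, ] <- j
    }
  }
  states <- integer(n)
  states[n] <- which.max(v)             # first max -> lower state on ties
  if (n > 1L)
    for (t in (n - 1L):1L)
      states[t] <- bp[t + 1L, states[t + 1L]]
  states - 1L
}

#' Extract contiguous same-state regions
#'
#' Collapses the decoded state path into maximal runs of equal state; the
#' resulting regions partition the analyzed span. Each region carries its
#' region-level statistic: the mean (default) or the sum of the base
#' statistics it spans, and a direction read from the statistic's sign.
#' State-2 regions are the candidate differentially expressed regions.
#'
#' @param path integer state path from [viterbi_decode()].
#' @param positions 0-based base coordinates aligned with `path`.
#' @param s base statistic track aligned with `path`.
#' @param chrom chromosome name carried into the output.
#' @param stat_mode `"mean"` (default; comparable across region lengths) or
#'   `"sum"` of base statistics.
#' @param kind `"t"` for a signed track (directions from sign) or `"F"`
#'   (directions reported "mixed").
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   state, length, mean_stat, direction.
#' @export
extract_regions <- function(path, positions, s, chrom = "chr",
                            stat_mode = c("mean", "sum"), kind = "t") {
  stat_mode <- match.arg(stat_mode)
  if (length(path) != length(positions) || length(path) != length(s))
    stop("path, positions and statistics must be aligned")
  r <- rle(path)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  agg <- vapply(seq_along(r$values), function(k) {
    x <- s[starts_i[k]:ends_i[k]]
    if (stat_mode == "mean") mean(x) else sum(x)
  }, 0)
  dir <- if (kind == "F") rep("mixed", length(agg)) else
    ifelse(agg > 0, "up", ifelse(agg < 0, "down", "mixed"))
  data.frame(chrom = chrom,
             start = positions[starts_i],
             end = positions[ends_i] + 1L,
             state = r$values,
             length = r$lengths,
             mean_stat = agg,
             direction = dir,
             stringsAsFactors = FALSE)
}

#' Write regions as BED6 and a full table
#'
#' @param regions region data.frame from [extract_regions()] (optionally
#'   with p/q columns).
#' @param bed_path output BED6 path (name = state, score = |mean_stat|
#'   clamped to \[0, 1000\]); `NULL` to skip.
#' @param table_path output tab-separated table path; `NULL` to skip.
#' @return Invisibly, the region data.frame.
#' @export
write_regions <- function(regions, bed_path = NULL, table_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom, start = regions$start,
                      end = regions$end,
                      name = paste0("state", regions$state),
                      score = pmin(round(abs(regions$mean_stat) * 100), 1000),
                      strand = ".")
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  if (!is.null(table_path))
    data.table::fwrite(regions, table_path, sep = "\t")
  invisible(regions)
}
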