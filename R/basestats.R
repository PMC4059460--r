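#' Log-transform a coverage matrix
#'
#' Applies the variance-stabilizing transform g(y) = log2(y + offset)
#' elementwise, the Box-Cox-style transform under which the per-base linear
#' model's coefficient for a two-group contrast is a log2 fold change.
#'
#' @param cov a [coverage_matrix()] or a plain numeric matrix.
#' @param offset positive constant added before the log (default 0.5).
#' @return Numeric matrix, same shape as the input counts.
#' @export
coverage_transform <- function(cov, offset = 0.5) {
  if (offset <= 0) stop("offset must be positive")
  y <- if (inherits(cov, "coverage_matrix")) cov$counts else as.matrix(cov)
  log2(y + offset)
}

# model matrix: intercept | group indicators (ref dropped) | confounders
build_design_matrix <- function(design, n) {
  g <- design$groups
  X <- stats::model.matrix(~g)
  colnames(X) <- c("(Intercept)",
                   paste0("group_", levels(g)[-1L]))
  if (!is.null(design$confounders))
    X <- cbind(X, design$confounders)
  X
}

#' Fit the per-base linear model
#'
#' Ordinary least squares of transformed coverage on group indicators and
#' optional confounders, fit to every base (row) of the matrix at once via
#' the shared hat matrix. Returns per-base coefficients, residual variances
#' with their degrees of freedom, and the variance multiplier of the tested
#' group contrast.
#'
#' @param y transformed coverage matrix (bases x samples), e.g. from
#'   [coverage_transform()].
#' @param design a [der_design()].
#' @return An object of class `base_fit`: list with `coefficients`
#'   (bases x p), `resid_var`, `df` (residual degrees of freedom),
#'   `contrast_scale` (v, the diagonal of the group block of (X'X)^-1),
#'   `group_cols` (column indices of group coefficients), and `design_matrix`.
#' @export
fit_base_models <- function(y, design) {
  y <- as.matrix(y)
  n <- ncol(y)
  if (length(design$groups) != n)
    stop("design has ", length(design$groups), " samples but matrix has ",
         n, " columns")
  X <- build_design_matrix(design, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  p <- ncol(X)
  if (n < p + 1L) stop("need at least rank+1 samples to estimate variance")
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- y %*% X %*% XtXinv                    # bases x p coefficients
  fitted <- B %*% t(X)
  resid <- y - fitted
  df <- n - p
  s2 <- rowSums(resid^2) / df
  s2[s2 < 0] <- 0                            # guard tiny negative round-off
  group_cols <- 2L:(1L + nlevels(design$groups) - 1L)
  colnames(B) <- colnames(X)
  structure(list(coefficients = B, resid_var = s2, df = df,
                 contrast_scale = diag(XtXinv)[group_cols],
                 vcov_unscaled = XtXinv,
                 group_cols = group_cols, design_matrix = X),
            class = "base_fit")
}

# Newton inversion of the trigamma function (solve trigamma(y) = x).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-matching estimate of the inverse-chi-square prior (d0, s02) from
# log residual variances: E[log s2] and Var[log s2] of a scaled chi^2_d
# involve digamma/trigamma; the excess variance over trigamma(d/2)
# identifies d0 by trigamma inversion.
estimate_shrink_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L)
    stop("need at least 10 expressed bases with positive residual variance ",
         "to estimate shrinkage hyperparameters")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0)) {
      warning("prior df estimate non-finite; using fully pooled variance")
      d0 <- Inf
    }
  } else {
    d0 <- Inf
  }
  s02 <- if (is.finite(d0))
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated statistics per base
#'
#' Shrinks each base's residual variance toward a prior variance shared
#' across bases and forms the moderated test statistic for the group
#' contrast. The prior (d0, s02) is estimated by moment matching on the log
#' residual variances of expressed bases (trigamma inversion for d0); the
#' posterior variance is s2_tilde = (d0*s02 + d*s2) / (d0 + d). For two
#' groups the statistic is the signed moderated t, beta_hat /
#' sqrt(s2_tilde * v); for more groups it is the analogous moderated F,
#' which is direction-free.
#'
#' Bases whose average raw coverage falls below `cutoff` are considered
#' unexpressed: their statistic is set exactly to 0 so the segmentation
#' step's null state (a tight normal at 0) sees them at its mode and the
#' genome track stays contiguous.
#'
#' @param fit a `base_fit` from [fit_base_models()].
#' @param cov the raw [coverage_matrix()] (used for the expressed mask).
#' @param cutoff average-coverage threshold c below which a base is treated
#'   as unexpressed (default 5).
#' @param d0,s02 optional fixed hyperparameters; when `NULL` (default) they
#'   are estimated from the data. `d0 = 0` gives the ordinary unmoderated
#'   statistic, `d0 = Inf` the fully pooled one.
#' @return An object of class `base_stats`: list with `statistic` (per-base
#'   track s(l)), `expressed` (logical mask), `d0`, `s02`, `posterior_var`,
#'   `kind` ("t" or "F"), and `positions`/`chrom` copied from `cov`.
#' @export
moderate_statistics <- function(fit, cov, cutoff = 5, d0 = NULL, s02 = NULL) {
  expressed <- rowMeans(cov$counts) >= cutoff
  if (!any(expressed)) {
    return(structure(list(statistic = numeric(nrow(cov$counts)),
                          expressed = expressed, d0 = Inf, s02 = NA_real_,
                          posterior_var = fit$resid_var, kind = "t",
                          chrom = cov$chrom, positions = cov$positions),
                     class = "base_stats"))
  }
  if (is.null(d0) || is.null(s02)) {
    pr <- estimate_shrink_prior(fit$resid_var[expressed], fit$df)
    if (is.null(d0)) d0 <- pr$d0
    if (is.null(s02)) s02 <- pr$s02
  }
  s2 <- fit$resid_var
  post_var <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + fit$df * s2) / (d0 + fit$df)
  gcols <- fit$group_cols
  if (length(gcols) == 1L) {
    stat <- fit$coefficients[, gcols] /
      sqrt(post_var * fit$contrast_scale)
    kind <- "t"
  } else {
    Vinv <- chol2inv(chol(fit$vcov_unscaled[gcols, gcols, drop = FALSE]))
    Bg <- fit$coefficients[, gcols, drop = FALSE]
    quad <- rowSums((Bg %*% Vinv) * Bg)
    stat <- quad / (length(gcols) * post_var)
    kind <- "F"
  }
  stat[!expressed] <- 0
  stat[expressed & !is.finite(stat)] <- 0   # 0/0 at constant expressed rows
  structure(list(statistic = as.numeric(stat), expressed = expressed,
                 d0 = d0, s02 = s02, posterior_var = post_var, kind = kind,
                 chrom = cov$chrom, positions = cov$positions),
            class = "base_stats")
}

#' @export
print.base_stats <- function(x, ...) {
  cat(sprintf("base_stats (%s): %d bases, %d expressed (%.1f%%)\n",
              x$kind, length(x$statistic), sum(x$expressed),
              100 * mean(x$expressed)))
  cat(sprintf("shrinkage prior: d0 = %.4g, s02 = %.4g\n", x$d0, x$s02))
  invisible(x)
}

#' Write / read a base-statistic track
#'
#' Tab-separated `chrom position statistic expressed` with full double
#' precision, so a round trip is bit-exact.
#'
#' @param stats a `base_stats` object.
#' @param path output file.
#' @return `write_base_stats` invisibly returns `path`; `read_base_stats`
#'   returns a data.frame with columns chrom, position, statistic, expressed.
#' @export
write_base_stats <- function(stats, path) {
  df <- data.frame(chrom = stats$chrom, position = stats$positions,
                   statistic = sprintf("%.17g", stats$statistic),
                   expressed = as.integer(stats$expressed))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_base_stats
#' @export
read_base_stats <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  df$statistic <- as.numeric(df$statistic)
  df$expressed <- as.logical(df$expressed)
  df
}
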