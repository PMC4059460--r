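#' Find differentially expressed regions from per-base coverage
#'
#' The package's central fitting function. Runs the full
#' identify-then-annotate model on a coverage matrix: (1) log-transform the
#' counts and fit a per-base linear model of transformed coverage on group
#' membership and optional confounders; (2) shrink per-base residual
#' variances toward a common prior and form the moderated statistic track
#' s(l); (3) fit a two-groups normal mixture to the expressed-base
#' statistics and assemble a three-state HMM (not expressed / expressed,
#' equal / differential) whose most likely state path is decoded by
#' Viterbi; (4) collapse the path into regions and assign candidate
#' (state 2) regions permutation-based empirical p-values with BH-adjusted
#' q-values. Annotation against a feature reference is a separate step
#' ([annotate_regions()]).
#'
#' @param cov a [coverage_matrix()] (see [read_coverage()]).
#' @param design a [der_design()]; for two groups the statistic is a signed
#'   moderated t for (non-reference minus reference), so "up" regions are
#'   overexpressed in the non-reference group.
#' @param offset positive constant of the log2(y + offset) transform
#'   (default 0.5).
#' @param cutoff average-coverage threshold c separating expressed from
#'   unexpressed bases (default 5).
#' @param delta variance of the unexpressed-state emission N(0, delta)
#'   (default 1e-4).
#' @param retain_prob diagonal of the fixed HMM transition matrix (default
#'   0.999; expected segment length ~1000 bases).
#' @param libsize library-size handling: `"median"` (default) or `"q75"`
#'   add the log2 per-sample coverage summary as a confounder column;
#'   `"none"` for equal-depth data. A summary that is constant across
#'   samples carries no information and is dropped with a message.
#' @param B number of permutations for the null pool (default 50; `B = 0`
#'   skips significance, leaving p and q `NA`).
#' @param seed integer seed for the permutations.
#' @param p_mode,sided empirical p-value mode and sidedness (see
#'   [empirical_pvalues()]).
#' @param stat_mode region statistic: `"mean"` (default) or `"sum"` of base
#'   statistics.
#' @return An object of class `derfit`; see [print.derfit()],
#'   [summary.derfit()], [plot.derfit()], [candidate_regions()],
#'   [coef.derfit()].
#' @examples
#' regs <- data.frame(start = c(200, 600), end = c(400, 800),
#'                    mu = 30, log2fc = c(0, 2))
#' sim <- simulate_experiment(sim_config(1000, c(3, 3), regs, seed = 7))
#' fit <- derfind(sim$coverage, sim$design, libsize = "none", B = 10,
#'                seed = 7)
#' fit
#' candidate_regions(fit)
#' @export
derfind <- function(cov, design, offset = 0.5, cutoff = 5, delta = 1e-4,
                    retain_prob = 0.999,
                    libsize = c("median", "q75", "none"),
                    B = 50L, seed = 1L,
                    p_mode = c("pseudocount", "paper-exact"),
                    sided = c("two", "one"),
                    stat_mode = c("mean", "sum")) {
  cl <- match.call()
  libsize <- match.arg(libsize)
  p_mode <- match.arg(p_mode)
  sided <- match.arg(sided)
  stat_mode <- match.arg(stat_mode)
  lib <- NULL
  if (libsize != "none") {
    lib <- library_size(cov, method = libsize)
    w <- log2(lib)
    if (stats::sd(w) > 0) {
      design$confounders <- cbind(design$confounders,
                                  libsize = w - mean(w))
    } else {
      message("library-size summary is constant across samples; ",
              "dropping the normalization column")
    }
  }
  y <- coverage_transform(cov, offset)
  pi0 <- estimate_pi0(cov, cutoff)
  obs <- identify_pass(y, cov, design, pi0, cutoff, delta, retain_prob,
                       stat_mode)
  regions <- obs$regions
  cand_idx <- which(regions$state == 2L)
  regions$p <- NA_real_
  regions$q <- NA_real_
  pool <- NULL
  if (B > 0L && length(cand_idx) > 0L) {
    pool <- permutation_null(cov, design, B = B, seed = seed,
                             offset = offset, cutoff = cutoff,
                             delta = delta, retain_prob = retain_prob,
                             stat_mode = stat_mode)
    pv <- empirical_pvalues(regions$mean_stat[cand_idx], pool,
                            mode = p_mode, sided = sided)
    regions$p[cand_idx] <- pv$p
    regions$q[cand_idx] <- adjust_fdr(pv$p)
  }
  structure(list(call = cl,
                 regions = regions,
                 candidates = regions[cand_idx, , drop = FALSE],
                 base_stats = obs$stats,
                 coefficients = obs$fit$coefficients,
                 mixture = obs$mixture,
                 hmm = obs$hmm,
                 path = obs$path,
                 pi0 = pi0,
                 null_pool = pool,
                 library_size = lib,
                 design = design,
                 config = list(offset = offset, cutoff = cutoff,
                               delta = delta, retain_prob = retain_prob,
                               libsize = libsize, B = B, seed = seed,
                               p_mode = p_mode, sided = sided,
                               stat_mode = stat_mode),
                 chrom = cov$chrom,
                 n_bases = length(cov$positions)),
            class = "derfit")
}

#' Candidate differentially expressed regions of a fit
#'
#' @param fit a [derfind()] result.
#' @param q optional q-value cutoff; `NULL` (default) returns all
#'   candidates.
#' @return data.frame of state-2 regions with p and q columns.
#' @export
candidate_regions <- function(fit, q = NULL) {
  out <- fit$candidates
  if (!is.null(q)) out <- out[!is.na(out$q) & out$q < q, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn derfind compact display of the fitted segmentation.
#' @param x,object a `derfit` object.
#' @param ... unused.
#' @export
print.derfit <- function(x, ...) {
  cat("Differentially expressed region fit\n")
  cat(sprintf("  %s: %d bases analyzed, pi0 = %.3f\n",
              x$chrom, x$n_bases, x$pi0))
  tb <- table(factor(x$regions$state, levels = 0:2))
  cat(sprintf("  regions: %d not expressed, %d equally expressed, %d candidate DERs\n",
              tb[1L], tb[2L], tb[3L]))
  if (!is.null(x$null_pool)) {
    nsig <- sum(x$candidates$q < 0.05, na.rm = TRUE)
    cat(sprintf("  significance: B = %d permutations, %d null DERs pooled, %d DERs at q < 0.05\n",
                x$null_pool$B, sum(x$null_pool$P_b), nsig))
  }
  invisible(x)
}

#' @describeIn derfind fuller summary: mixture, HMM and significant
#'   regions.
#' @export
summary.derfit <- function(object, ...) {
  print(object)
  if (!is.null(object$mixture)) {
    cat("\n"); print(object$mixture)
  }
  if (!is.null(object$hmm)) print(object$hmm)
  sig <- candidate_regions(object, q = 0.05)
  if (nrow(sig)) {
    cat("\nsignificant regions (q < 0.05):\n")
    print(sig[, c("chrom", "start", "end", "length", "mean_stat",
                  "direction", "p", "q")], row.names = FALSE)
  }
  invisible(object)
}

#' @describeIn derfind per-base linear-model coefficients (bases x terms).
#' @export
coef.derfit <- function(object, ...) object$coefficients

#' @describeIn derfind plot the statistic track coloured by decoded state.
#' @param xlim optional position window to display.
#' @export
plot.derfit <- function(x, xlim = NULL, ...) {
  pos <- x$base_stats$positions
  s <- x$base_stats$statistic
  keep <- if (is.null(xlim)) rep(TRUE, length(pos)) else
    pos >= xlim[1L] & pos <= xlim[2L]
  cols <- c("grey70", "grey30", "firebrick")[x$path + 1L]
  graphics::plot(pos[keep], s[keep], col = cols[keep], pch = 16,
                 cex = 0.4, xlab = paste0(x$chrom, " position"),
                 ylab = "moderated statistic s(l)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright",
                   legend = c("not expressed", "expressed", "candidate DER"),
                   col = c("grey70", "grey30", "firebrick"), pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}
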