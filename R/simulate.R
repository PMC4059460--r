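#' Configure a synthetic two-group coverage experiment
#'
#' Describes a synthetic genome with contiguous expressed regions, a subset
#' of which are differentially expressed between two sample groups.
#' Per-base counts are negative binomial around a region mean that ramps up
#' linearly over a fixed 20-base window at each region edge (emulating the
#' blurred boundaries real read pileups produce); bases outside expressed
#' regions have zero coverage.
#'
#' The region table gives, per expressed region, the baseline mean coverage
#' `mu` (> 0, the group-1 mean) and `log2fc`, the log2 fold change applied
#' to group 2 (0 = expressed but not differential; `-Inf` = absent from
#' group 2, the "group-specific chromosome" case).
#'
#' @param genome_length span of the simulated chromosome, bases.
#' @param n_per_group integer of length 2, samples per group (default
#'   c(5, 5)).
#' @param regions data.frame with columns start, end (0-based half-open),
#'   mu, log2fc; regions must not overlap.
#' @param dispersion negative-binomial dispersion phi (default 0.1;
#'   0 = Poisson).
#' @param lib_factors per-sample depth multipliers; `NULL` (default) draws
#'   them Uniform(0.85, 1.15) from the seed.
#' @param seed integer seed fully determining the draw.
#' @param chrom chromosome name (default "chrS").
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length, n_per_group = c(5L, 5L), regions,
                       dispersion = 0.1, lib_factors = NULL, seed = 1L,
                       chrom = "chrS") {
  regions <- as.data.frame(regions)
  stopifnot(all(c("start", "end", "mu", "log2fc") %in% names(regions)))
  if (any(regions$start < 0) || any(regions$end > genome_length))
    stop("regions must lie within the genome")
  if (any(regions$end <= regions$start)) stop("region end must exceed start")
  if (any(regions$mu <= 0)) stop("region mean mu must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] < regions$end[-nrow(regions)]))
    stop("expressed regions must not overlap (truth would be ambiguous)")
  structure(list(genome_length = as.integer(genome_length),
                 n_per_group = as.integer(n_per_group),
                 regions = regions, dispersion = dispersion,
                 lib_factors = lib_factors, seed = as.integer(seed),
                 chrom = chrom),
            class = "sim_config")
}

# linear 20-base edge ramp; short regions get proportionally steeper ramps
edge_ramp <- function(len, w = 20L) {
  idx <- seq_len(len)
  pmin(1, idx / w, (len - idx + 1L) / w)
}

#' Simulate a two-group per-base coverage experiment
#'
#' Draws the coverage matrix described by a [sim_config()] and returns it
#' together with the ground truth. Fully determined by the config seed.
#' When `dir` is given, standard pipeline inputs are also written there:
#' one bedGraph per sample, a tab-separated sample sheet, and truth tables
#' (BED of DE regions plus a full table with fold changes), so the complete
#' pipeline including file I/O can be exercised end-to-end.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return list with `coverage` (a [coverage_matrix()]), `design` (a
#'   [der_design()]; group levels "g1", "g2" with "g1" the reference), and
#'   `truth` (class `sim_truth`: the region table with `is_de`, `direction`,
#'   plus `lib_factors` and `seed`).
#' @export
simulate_experiment <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  n1 <- cfg$n_per_group[1L]; n2 <- cfg$n_per_group[2L]
  n <- n1 + n2
  groups <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  lib <- cfg$lib_factors
  if (is.null(lib)) lib <- stats::runif(n, 0.85, 1.15)
  counts <- matrix(0, nrow = cfg$genome_length, ncol = n)
  for (k in seq_len(nrow(cfg$regions))) {
    r <- cfg$regions[k, ]
    len <- r$end - r$start
    ramp <- edge_ramp(len)
    rows <- (r$start + 1L):r$end
    for (i in seq_len(n)) {
      fc_mult <- if (groups[i] == "g2") 2^r$log2fc else 1
      m <- r$mu * ramp * lib[i] * fc_mult
      counts[rows, i] <- if (cfg$dispersion > 0)
        stats::rnbinom(len, mu = m, size = 1 / cfg$dispersion)
      else stats::rpois(len, m)
    }
  }
  sample_ids <- sprintf("%s_%d", as.character(groups),
                        as.integer(ave(seq_len(n), groups, FUN = seq_along)))
  cov <- coverage_matrix(cfg$chrom, 0:(cfg$genome_length - 1L), counts,
                         sample_ids)
  truth_regions <- cfg$regions
  truth_regions$is_de <- truth_regions$log2fc != 0
  truth_regions$direction <- ifelse(!truth_regions$is_de, "none",
                                    ifelse(truth_regions$log2fc > 0,
                                           "up", "down"))
  truth <- structure(list(regions = truth_regions, lib_factors = lib,
                          chrom = cfg$chrom, seed = cfg$seed,
                          genome_length = cfg$genome_length),
                     class = "sim_truth")
  design <- der_design(groups)
  out <- list(coverage = cov, design = design, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_coverage(cov, dir)
    sheet <- data.frame(sample_id = sample_ids, file = basename(paths),
                        group = as.character(groups))
    data.table::fwrite(sheet, file.path(dir, "samples.tsv"), sep = "\t")
    de <- truth_regions[truth_regions$is_de, , drop = FALSE]
    data.table::fwrite(
      data.frame(chrom = cfg$chrom, start = de$start, end = de$end,
                 name = de$direction),
      file.path(dir, "truth_de.bed"), sep = "\t", col.names = FALSE)
    data.table::fwrite(cbind(chrom = cfg$chrom, truth_regions),
                       file.path(dir, "truth_regions.tsv"), sep = "\t")
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d bp genome, %d expressed regions (%d DE)\n",
              x$genome_length, nrow(x$regions), sum(x$regions$is_de)))
  invisible(x)
}

#' Score called regions against simulation truth
#'
#' Sensitivity is the fraction of true DE regions matched by a significant
#' call; precision is the fraction of significant calls matching a true DE
#' region. Matching is either any 1-bp overlap (default) or pairwise
#' Jaccard >= 0.5. A base-level Jaccard index between the union of
#' significant calls and the union of true DE regions is also reported.
#' With no significant calls, precision is undefined and reported as 1 with
#' `no_calls = TRUE`.
#'
#' @param calls data.frame of called regions with start, end and `q`.
#' @param truth a `sim_truth` from [simulate_experiment()].
#' @param q_threshold significance cutoff (default 0.05).
#' @param match_rule `"1bp"` or `"jaccard0.5"`.
#' @return list with `sensitivity`, `precision`, `base_jaccard`,
#'   `n_true_de`, `n_calls`, `no_calls`.
#' @export
evaluate_calls <- function(calls, truth, q_threshold = 0.05,
                           match_rule = c("1bp", "jaccard0.5")) {
  match_rule <- match.arg(match_rule)
  de <- truth$regions[truth$regions$is_de, , drop = FALSE]
  sig <- calls[!is.na(calls$q) & calls$q < q_threshold, , drop = FALSE]
  overlap_len <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))
  pair_match <- function(s1, e1, s2, e2) {
    ov <- overlap_len(s1, e1, s2, e2)
    if (match_rule == "1bp") ov >= 1
    else ov / (pmax(e1, e2) - pmin(s1, s2)) >= 0.5
  }
  truth_hit <- vapply(seq_len(nrow(de)), function(i)
    nrow(sig) > 0 && any(pair_match(de$start[i], de$end[i],
                                    sig$start, sig$end)), TRUE)
  call_hit <- vapply(seq_len(nrow(sig)), function(j)
    nrow(de) > 0 && any(pair_match(sig$start[j], sig$end[j],
                                   de$start, de$end)), TRUE)
  mask_from <- function(st, en) {
    m <- logical(truth$genome_length)
    for (k in seq_along(st)) m[(st[k] + 1L):en[k]] <- TRUE
    m
  }
  mt <- mask_from(de$start, de$end)
  mc <- mask_from(sig$start, sig$end)
  uni <- sum(mt | mc)
  jac <- if (uni == 0L) 1 else sum(mt & mc) / uni
  no_calls <- nrow(sig) == 0L
  list(sensitivity = if (nrow(de)) mean(truth_hit) else NA_real_,
       precision = if (no_calls) 1 else mean(call_hit),
       base_jaccard = jac,
       n_true_de = nrow(de), n_calls = nrow(sig), no_calls = no_calls)
}
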