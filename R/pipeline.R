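#' Read a pipeline run configuration
#'
#' Accepts a YAML file or a flat `key = value` / `key: value` text file and
#' merges it over the documented defaults. Recognised keys: `samples`
#' (sample sheet path, required for [run_pipeline()]), `chrom` (required),
#' `features` (optional GTF/BED), `out` (output directory), and the
#' [derfind()] / [feature_rollup()] parameters `offset`, `cutoff`, `delta`,
#' `retain_prob`, `libsize`, `B`, `seed`, `p_mode`, `sided`, `stat_mode`,
#' `q_threshold`, `exon_frac_threshold`.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list of values taking precedence over the file.
#' @return A named list of run parameters.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(samples = NULL, chrom = NULL, features = NULL,
                   out = "derseg_run", offset = 0.5, cutoff = 5,
                   delta = 1e-4, retain_prob = 0.999, libsize = "median",
                   B = 50L, seed = 1L, p_mode = "pseudocount",
                   sided = "two", stat_mode = "mean",
                   q_threshold = 0.05, exon_frac_threshold = 0.2)
  from_file <- list()
  if (!is.null(path)) {
    from_file <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
    if (is.null(from_file) || !is.list(from_file)) {
      ln <- readLines(path, warn = FALSE)
      ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
      kv <- strsplit(ln, "\\s*[:=]\\s*")
      from_file <- stats::setNames(
        lapply(kv, function(x) utils::type.convert(x[2L], as.is = TRUE)),
        vapply(kv, `[`, "", 1L))
    }
  }
  cfg <- utils::modifyList(defaults, from_file)
  cfg <- utils::modifyList(cfg, overrides)
  num <- c("offset", "cutoff", "delta", "retain_prob", "B", "seed",
           "q_threshold", "exon_frac_threshold")
  for (k in num) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$B <- as.integer(cfg$B); cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full identification pipeline from files to result tables
#'
#' Orchestrates coverage assembly, per-base statistics, segmentation,
#' permutation significance and (when a feature file is configured)
#' annotation, writing all result tables plus a metadata file that records
#' every parameter, the seed and the package version — sufficient to
#' reproduce the run bit-for-bit from the same inputs.
#'
#' Outputs under `cfg$out`: `regions.tsv` (all decoded regions),
#' `regions.bed` (BED6), `significance.tsv` (candidate DERs with p and q),
#' and with annotation `annotated.tsv`, `exons.tsv`, `genes.tsv`,
#' `novel.bed` (significant intergenic DERs); `metadata.yaml` always.
#'
#' @param cfg a [read_run_config()] list (or path to a config file).
#' @return Invisibly, a list with the `derfit`, the output directory, and
#'   the annotation rollup (if any).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$samples) || is.null(cfg$chrom))
    stop("config must provide 'samples' (sample sheet) and 'chrom'")
  t0 <- Sys.time()
  sheet <- read_sample_sheet(cfg$samples)
  message(sprintf("[coverage] %d samples, chromosome %s",
                  nrow(sheet), cfg$chrom))
  cov <- read_coverage(sheet$file, cfg$chrom, sample_ids = sheet$sample_id)
  extra <- setdiff(names(sheet), c("sample_id", "file", "group"))
  design <- der_design(sheet$group,
                       confounders = if (length(extra))
                         as.matrix(sheet[, extra, drop = FALSE]) else NULL)
  message(sprintf("[coverage] %d bases analyzed", length(cov$positions)))
  fit <- derfind(cov, design, offset = cfg$offset, cutoff = cfg$cutoff,
                 delta = cfg$delta, retain_prob = cfg$retain_prob,
                 libsize = cfg$libsize, B = cfg$B, seed = cfg$seed,
                 p_mode = cfg$p_mode, sided = cfg$sided,
                 stat_mode = cfg$stat_mode)
  tb <- table(factor(fit$regions$state, levels = 0:2))
  message(sprintf("[segmentation] regions per state: %d / %d / %d",
                  tb[1L], tb[2L], tb[3L]))
  if (!is.null(fit$null_pool))
    message(sprintf("[significance] null pool size %d over B = %d",
                    sum(fit$null_pool$P_b), fit$null_pool$B))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  write_regions(fit$regions, bed_path = file.path(cfg$out, "regions.bed"),
                table_path = file.path(cfg$out, "regions.tsv"))
  data.table::fwrite(fit$candidates, file.path(cfg$out, "significance.tsv"),
                     sep = "\t")
  rollup <- NULL
  if (!is.null(cfg$features)) {
    feats <- read_features(cfg$features)
    ann <- annotate_regions(fit$candidates, feats)
    rollup <- feature_rollup(ann, q_threshold = cfg$q_threshold,
                             exon_frac_threshold = cfg$exon_frac_threshold)
    data.table::fwrite(ann, file.path(cfg$out, "annotated.tsv"), sep = "\t")
    data.table::fwrite(rollup$exons, file.path(cfg$out, "exons.tsv"),
                       sep = "\t")
    data.table::fwrite(rollup$genes, file.path(cfg$out, "genes.tsv"),
                       sep = "\t")
    novel <- ann[ann$class == "intergenic" & !is.na(ann$q) &
                   ann$q < cfg$q_threshold, , drop = FALSE]
    data.table::fwrite(novel[, c("chrom", "start", "end", "direction")],
                       file.path(cfg$out, "novel.bed"), sep = "\t",
                       col.names = FALSE)
    message(sprintf("[annotation] %d exons, %d genes called",
                    rollup$n_exons_called, rollup$n_genes_called))
  }
  meta <- c(cfg, list(package_version = as.character(
    utils::packageVersion("derseg")),
    n_bases = fit$n_bases, pi0 = fit$pi0,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  yaml::write_yaml(meta, file.path(cfg$out, "metadata.yaml"))
  message(sprintf("[done] outputs in %s (%.1f s)", cfg$out,
                  meta$elapsed_sec))
  invisible(list(fit = fit, out = cfg$out, rollup = rollup))
}
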