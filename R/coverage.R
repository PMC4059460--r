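#' Base-by-sample coverage matrix
#'
#' Container for per-base read coverage over one contiguous chromosome span:
#' a bases x samples matrix of non-negative integer counts together with the
#' 0-based genomic positions of its rows. All coordinates in the package are
#' 0-based half-open (bedGraph/BED convention).
#'
#' @param chrom chromosome name.
#' @param positions integer vector of 0-based base coordinates, strictly
#'   increasing and contiguous (one row per base of the analyzed span).
#' @param counts numeric matrix, `length(positions)` rows, one column per
#'   sample; entries must be non-negative and integral.
#' @param sample_ids character vector of column names.
#' @return An object of class `coverage_matrix`.
#' @seealso [read_coverage()], [write_coverage()], [library_size()]
#' @export
coverage_matrix <- function(chrom, positions, counts, sample_ids) {
  counts <- as.matrix(counts)
  positions <- as.integer(positions)
  if (length(positions) != nrow(counts))
    stop("positions and counts rows disagree")
  if (ncol(counts) != length(sample_ids))
    stop("number of counts columns must equal number of sample_ids")
  if (length(positions) > 1L && any(diff(positions) != 1L))
    stop("positions must be contiguous and strictly increasing")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-6))
    stop("counts must be non-negative integers")
  counts <- round(counts)
  storage.mode(counts) <- "double"
  colnames(counts) <- sample_ids
  structure(
    list(chrom = as.character(chrom), positions = positions,
         counts = counts, sample_ids = as.character(sample_ids)),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %s:%d-%d (%d bases x %d samples)\n",
              x$chrom, x$positions[1L],
              x$positions[length(x$positions)] + 1L,
              length(x$positions), ncol(x$counts)))
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$counts)

# Read and validate one bedGraph file. Returns a data.frame with columns
# chrom, start, end, value. Errors name the file and (1-based) line.
read_bedgraph <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  if (file.size(file) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  dt <- data.table::fread(file, header = FALSE, colClasses = "character",
                          fill = TRUE, showProgress = FALSE,
                          blank.lines.skip = TRUE)
  # track/browser/comment header lines are legal bedGraph furniture
  keep <- !grepl("^(track|browser|#)", dt[[1L]])
  line_no <- which(keep)
  dt <- dt[keep, ]
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  if (ncol(dt) < 4L)
    stop(sprintf("malformed bedGraph (fewer than 4 columns): %s", file))
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end   <- suppressWarnings(as.numeric(dt[[3L]]))
  value <- suppressWarnings(as.numeric(dt[[4L]]))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value) |
                 start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("malformed line %d in %s", line_no[bad[1L]], file))
  bad_val <- which(abs(value - round(value)) > 1e-6)
  if (length(bad_val))
    stop(sprintf("non-integral coverage value at line %d in %s",
                 line_no[bad_val[1L]], file))
  out <- data.frame(chrom = dt[[1L]], start = as.integer(start),
                    end = as.integer(end), value = round(value))
  # overlapping intervals within one file are ambiguous coverage
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    o <- order(sub$start)
    if (nrow(sub) > 1L && any(sub$end[o][-nrow(sub)] > sub$start[o][-1L]))
      stop(sprintf("overlapping intervals on %s in %s", ch, file))
  }
  out
}

#' Read per-sample bedGraph coverage into a coverage matrix
#'
#' Assembles the bases x samples coverage matrix for one chromosome from one
#' bedGraph file per sample. Bases not covered by any interval in a sample are
#' explicit zeros; the analyzed span is the union of covered intervals across
#' samples, padded to contiguity, so the segmentation step sees one unbroken
#' track.
#'
#' @param files character vector of bedGraph paths, one per sample; column
#'   order follows this vector.
#' @param chrom chromosome to extract.
#' @param span `"auto"` (union span across samples) or an integer pair
#'   `c(start, end)`, 0-based half-open.
#' @param sample_ids optional sample names; defaults to file base names.
#' @return A [coverage_matrix()].
#' @export
read_coverage <- function(files, chrom, span = "auto", sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.(bedgraph|bedGraph|bg|txt)$", "", basename(files))
  recs <- lapply(files, function(f) {
    bg <- read_bedgraph(f)
    bg[bg$chrom == chrom, , drop = FALSE]
  })
  if (all(vapply(recs, nrow, 0L) == 0L))
    stop(sprintf("chromosome '%s' absent from all input files (empty matrix)",
                 chrom))
  if (identical(span, "auto")) {
    lo <- min(vapply(recs[vapply(recs, nrow, 0L) > 0L],
                     function(r) min(r$start), 0L))
    hi <- max(vapply(recs[vapply(recs, nrow, 0L) > 0L],
                     function(r) max(r$end), 0L))
  } else {
    lo <- as.integer(span[1L]); hi <- as.integer(span[2L])
    if (hi <= lo) stop("span end must exceed span start")
  }
  n_base <- hi - lo
  counts <- matrix(0, nrow = n_base, ncol = length(files))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (nrow(r) == 0L) next
    s <- pmax(r$start, lo); e <- pmin(r$end, hi)
    ok <- which(e > s)
    for (k in ok)
      counts[(s[k] - lo + 1L):(e[k] - lo), i] <- r$value[k]
  }
  coverage_matrix(chrom, lo:(hi - 1L), counts, sample_ids)
}

#' Write a coverage matrix back to bedGraph
#'
#' Run-length encodes each sample's column (equal consecutive values become
#' one interval) and writes one 4-column bedGraph per sample. Zero runs are
#' omitted, the bedGraph convention; re-reading with the original span
#' reproduces the matrix exactly.
#'
#' @param cov a [coverage_matrix()].
#' @param dir output directory (created if needed).
#' @param sample_ids optional file stems; defaults to `cov$sample_ids`.
#' @return Invisibly, the written file paths.
#' @export
write_coverage <- function(cov, dir, sample_ids = cov$sample_ids) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(sample_ids, ".bedgraph"))
  lo <- cov$positions[1L]
  for (i in seq_along(sample_ids)) {
    r <- rle(cov$counts[, i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    df <- data.frame(chrom = cov$chrom, start = lo + starts[keep],
                     end = lo + ends[keep], value = r$values[keep])
    data.table::fwrite(df, paths[i], sep = "\t", col.names = FALSE)
    if (!any(keep)) cat("", file = paths[i])  # ensure file exists
  }
  invisible(paths)
}

#' Per-sample library-size summaries
#'
#' Summarizes each sample's coverage depth over all analyzed bases (zeros
#' included) as either the median or the 75th percentile; intended as the
#' library-size covariate of the per-base linear model or as a normalization
#' offset. Percentiles use the linear-interpolation definition
#' (`stats::quantile` type 7) so the value is reproducible across tools.
#'
#' An all-zero sample would get a summary of 0; since a zero library size is
#' unusable downstream (and permutation re-runs must not abort on degenerate
#' resamples), such samples get the smallest positive summary among samples
#' (or 1 if none), with a warning.
#'
#' @param cov a [coverage_matrix()].
#' @param method `"median"` or `"q75"`.
#' @return Named numeric vector, one value per sample.
#' @export
library_size <- function(cov, method = c("median", "q75")) {
  method <- match.arg(method)
  p <- if (method == "median") 0.5 else 0.75
  vals <- apply(cov$counts, 2L, stats::quantile, probs = p,
                names = FALSE, type = 7)
  if (any(vals == 0)) {
    pos <- vals[vals > 0]
    sub <- if (length(pos)) min(pos) else 1
    warning(sprintf(
      "%d sample(s) have a zero %s coverage summary; substituting %g",
      sum(vals == 0), method, sub))
    vals[vals == 0] <- sub
  }
  names(vals) <- cov$sample_ids
  vals
}

#' Read a tab-separated sample sheet
#'
#' Expected columns (header required): `sample_id`, `file`, `group`, then any
#' number of numeric covariate columns. Relative file paths are resolved
#' against the sheet's directory.
#'
#' @param path sample sheet path.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("sample_id", "file", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have header columns: ",
         paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$file)
  df$file[rel] <- file.path(dirname(path), df$file[rel])
  df
}

#' Experimental design for the per-base model
#'
#' Bundles the group factor (first level = reference category), optional
#' numeric confounders, and optional library sizes for a set of samples.
#'
#' @param groups factor or character vector of group labels, one per sample;
#'   the first factor level is the reference category.
#' @param confounders optional numeric matrix/data.frame of per-sample
#'   covariates (columns named).
#' @param library_size optional positive per-sample normalization values.
#' @return An object of class `der_design`.
#' @export
der_design <- function(groups, confounders = NULL, library_size = NULL) {
  groups <- as.factor(groups)
  n <- length(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples for model fitting")
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    if (nrow(confounders) != n)
      stop("confounders must have one row per sample")
    if (is.null(colnames(confounders)))
      colnames(confounders) <- paste0("W", seq_len(ncol(confounders)))
  }
  if (!is.null(library_size)) {
    if (length(library_size) != n) stop("one library size per sample")
    if (any(library_size <= 0)) stop("library_size must be positive")
  }
  structure(list(groups = groups, confounders = confounders,
                 library_size = library_size),
            class = "der_design")
}

#' @export
print.der_design <- function(x, ...) {
  cat("der_design:", length(x$groups), "samples,",
      nlevels(x$groups), "groups (reference:", levels(x$groups)[1L], ")\n")
  print(table(x$groups))
  if (!is.null(x$confounders))
    cat("confounders:", paste(colnames(x$confounders), collapse = ", "), "\n")
  invisible(x)
}
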