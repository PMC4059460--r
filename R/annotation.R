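#' Read a gene-feature reference (GTF or BED)
#'
#' Loads exon features and derives per-gene spans. GTF input (1-based
#' inclusive, Ensembl-style attributes) is parsed with
#' \code{rtracklayer::import} and converted to the package's 0-based
#' half-open convention; only rows of type "exon" are kept and each must
#' carry a gene_id. BED input is already 0-based half-open; the name column
#' becomes the exon_id, and, lacking gene information, also the gene_id.
#' Duplicate identical exon records are collapsed.
#'
#' @param path feature file; format is guessed from the extension
#'   (.gtf/.gff/.gff3 vs .bed) unless given.
#' @param format `"auto"`, `"gtf"` or `"bed"`.
#' @return An object of class `feature_set`: list with `exons` (data.frame
#'   chrom, start, end, exon_id, gene_id, strand) and `genes` (data.frame
#'   gene_id, chrom, start, end — min-start/max-end span over the gene's
#'   exons).
#' @export
read_features <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- as.data.frame(S4Vectors::mcols(gr))
    if ("type" %in% names(md)) {
      keep <- md$type == "exon"
      gr <- gr[keep]; md <- md[keep, , drop = FALSE]
    }
    if (length(gr) == 0L) stop("no exon records in ", path)
    if (!"gene_id" %in% names(md) || anyNA(md$gene_id))
      stop("GTF exon without gene_id attribute in ", path)
    exon_id <- if ("exon_id" %in% names(md) && !anyNA(md$exon_id))
      as.character(md$exon_id)
    else sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    exons <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      exon_id = exon_id,
      gene_id = as.character(md$gene_id),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(data.table::fread(path, header = FALSE))
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    exons <- data.frame(
      chrom = as.character(df[[1L]]),
      start = as.integer(df[[2L]]),
      end = as.integer(df[[3L]]),
      exon_id = if (ncol(df) >= 4L) as.character(df[[4L]])
                else sprintf("%s:%s-%s", df[[1L]], df[[2L]], df[[3L]]),
      strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "*",
      stringsAsFactors = FALSE)
    exons$gene_id <- exons$exon_id   # BED carries no gene structure
    exons <- exons[, c("chrom", "start", "end", "exon_id", "gene_id",
                       "strand")]
  }
  if (any(exons$end <= exons$start)) stop("exon with end <= start in ", path)
  exons <- unique(exons)
  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d exons in %d genes on %d chromosome(s)\n",
              nrow(x$exons), nrow(x$genes), length(unique(x$exons$chrom))))
  invisible(x)
}

#' Annotate regions against a feature reference
#'
#' Classifies each region as exonic (any exon overlap), intronic (no exon
#' overlap but inside a gene span), or intergenic, and reports the best
#' overlapping exon (most overlapping bases; ties broken toward the smaller
#' exon start). `overlap_bases` and the overlap fractions refer to the best
#' exon. Strand is ignored for overlap (coverage is unstranded) and carried
#' through for reporting only. A long per-(region, exon) hit table is
#' attached as attribute `"exon_hits"` for feature-level rollups.
#'
#' @param regions data.frame of regions with chrom, start, end (0-based
#'   half-open), e.g. candidate DERs from [extract_regions()] or
#'   [candidate_regions()].
#' @param features a [read_features()] object.
#' @return The input data.frame with added columns class, best_exon_id,
#'   overlap_bases, frac_region, frac_exon, gene_ids.
#' @export
annotate_regions <- function(regions, features) {
  n <- nrow(regions)
  out <- regions
  out$class <- rep("intergenic", n)
  out$best_exon_id <- rep(NA_character_, n)
  out$overlap_bases <- rep(0L, n)
  out$frac_region <- rep(0, n)
  out$frac_exon <- rep(0, n)
  out$gene_ids <- rep("", n)
  hits_all <- list()
  if (n > 0L) {
    ex <- features$exons
    gn <- features$genes
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      exi <- which(ex$chrom == ch)
      gni <- which(gn$chrom == ch)
      rr <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
      if (length(exi)) {
        er <- IRanges::IRanges(ex$start[exi] + 1L, ex$end[exi])
        ov <- IRanges::findOverlaps(rr, er)
        if (length(ov)) {
          qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
          w <- pmin(regions$end[ri][qi], ex$end[exi][si]) -
               pmax(regions$start[ri][qi], ex$start[exi][si])
          hits <- data.frame(
            region = ri[qi],
            exon_id = ex$exon_id[exi][si],
            gene_id = ex$gene_id[exi][si],
            exon_start = ex$start[exi][si],
            exon_len = ex$end[exi][si] - ex$start[exi][si],
            overlap = w, stringsAsFactors = FALSE)
          hits$frac_exon <- hits$overlap / hits$exon_len
          hits_all[[length(hits_all) + 1L]] <- hits
          for (r in unique(hits$region)) {
            h <- hits[hits$region == r, , drop = FALSE]
            h <- h[order(-h$overlap, h$exon_start), , drop = FALSE]
            out$class[r] <- "exonic"
            out$best_exon_id[r] <- h$exon_id[1L]
            out$overlap_bases[r] <- h$overlap[1L]
            rl <- regions$end[r] - regions$start[r]
            out$frac_region[r] <- h$overlap[1L] / rl
            out$frac_exon[r] <- h$frac_exon[1L]
            out$gene_ids[r] <- paste(unique(h$gene_id), collapse = ",")
          }
        }
      }
      if (length(gni)) {
        gn_r <- IRanges::IRanges(gn$start[gni] + 1L, gn$end[gni])
        ovg <- IRanges::findOverlaps(rr, gn_r)
        if (length(ovg)) {
          for (k in seq_along(ovg)) {
            r <- ri[S4Vectors::queryHits(ovg)[k]]
            if (out$class[r] == "intergenic") {
              out$class[r] <- "intronic"
              gg <- strsplit(out$gene_ids[r], ",")[[1L]]
              gg <- gg[nzchar(gg)]
              out$gene_ids[r] <- paste(
                unique(c(gg, gn$gene_id[gni][S4Vectors::subjectHits(ovg)[k]])),
                collapse = ",")
            }
          }
        }
      }
    }
  }
  attr(out, "exon_hits") <- if (length(hits_all))
    do.call(rbind, hits_all)
  else data.frame(region = integer(), exon_id = character(),
                  gene_id = character(), exon_start = integer(),
                  exon_len = integer(), overlap = integer(),
                  frac_exon = numeric())
  out
}

#' Roll region calls up to exons and genes
#'
#' An exon is called differentially expressed when some region with
#' q < `q_threshold` covers at least `exon_frac_threshold` of it; called
#' genes are the distinct gene_ids of called exons. The thresholds are
#' deliberately configurable: exon-calling criteria vary between references
#' and studies.
#'
#' @param annotated output of [annotate_regions()] carrying a `q` column.
#' @param q_threshold significance cutoff on region q-values (default 0.05).
#' @param exon_frac_threshold minimum fraction of the exon covered by one
#'   significant region (default 0.2).
#' @return list with `exons` (data.frame exon_id, gene_id, best_q,
#'   max_frac, called), `genes` (data.frame gene_id, n_called_exons),
#'   `n_exons_called`, `n_genes_called`.
#' @export
feature_rollup <- function(annotated, q_threshold = 0.05,
                           exon_frac_threshold = 0.2) {
  if (!"q" %in% names(annotated))
    stop("annotated regions must carry a q column")
  hits <- attr(annotated, "exon_hits")
  if (is.null(hits)) stop("annotated regions lack the exon_hits attribute; ",
                          "run annotate_regions() first")
  empty <- list(
    exons = data.frame(exon_id = character(), gene_id = character(),
                       best_q = numeric(), max_frac = numeric(),
                       called = logical()),
    genes = data.frame(gene_id = character(), n_called_exons = integer()),
    n_exons_called = 0L, n_genes_called = 0L)
  if (nrow(hits) == 0L) return(empty)
  hits$q <- annotated$q[hits$region]
  ex <- do.call(rbind, lapply(split(hits, hits$exon_id), function(h)
    data.frame(exon_id = h$exon_id[1L], gene_id = h$gene_id[1L],
               best_q = min(h$q), max_frac = max(h$frac_exon),
               called = any(h$q < q_threshold &
                              h$frac_exon >= exon_frac_threshold),
               stringsAsFactors = FALSE)))
  rownames(ex) <- NULL
  called <- ex[ex$called, , drop = FALSE]
  genes <- if (nrow(called)) {
    tb <- table(called$gene_id)
    data.frame(gene_id = names(tb), n_called_exons = as.integer(tb),
               stringsAsFactors = FALSE)
  } else empty$genes
  list(exons = ex, genes = genes,
       n_exons_called = nrow(called),
       n_genes_called = nrow(genes))
}
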