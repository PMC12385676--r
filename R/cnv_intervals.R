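#' @name cnv_intervals
#' @title Interval algebra over CNV loss and gain calls
#'
#' @description
#' All coordinates in this package are BED convention: 0-based, half-open
#' `[start, end)`. Region sets are plain data.frames with columns `chrom`,
#' `start`, `end` plus a `label` attribute, kept sorted by (chrom, start)
#' with no two intervals on the same chromosome overlapping or abutting
#' after merging. GenomicRanges does the set arithmetic internally; the
#' BED/GRanges conversion is confined to the two helpers below.
NULL

.bed_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

.gr_to_bed <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a region set
#'
#' Validates and normalizes a BED-style table into a labelled region set:
#' intervals must satisfy `start < end`; the table is sorted by
#' (chrom, start).
#'
#' @param df Data.frame with columns `chrom`, `start`, `end`.
#' @param label One of `merged_loss`, `merged_gain`, `shared`, `unique_loss`,
#'   `unique_gain`, or a free-text label.
#' @return The sorted data.frame with class `region_set` and a `label`
#'   attribute.
#' @export
region_set <- function(df, label = "regions") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df <- df[, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(df)) {
    if (any(!nzchar(df$chrom))) stop("empty chromosome name in region set")
    if (any(df$start >= df$end)) {
      bad <- which(df$start >= df$end)[1]
      stop("interval with start >= end at row ", bad)
    }
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", attr(x, "label"), "-", nrow(x), "intervals,",
      if (nrow(x)) sum(x$end - x$start) else 0, "bp\n")
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

.check_calls <- function(calls) {
  req <- c("chrom", "start", "end", "cnv_type", "sample_id")
  miss <- setdiff(req, names(calls))
  if (length(miss)) stop("calls table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !calls$cnv_type %in% c("loss", "gain")
  if (any(bad)) stop("unknown cnv_type at row(s) ",
                     paste(head(which(bad), 5), collapse = ", "))
  if (any(calls$start >= calls$end)) stop("call with start >= end")
  invisible(calls)
}

#' Merge all CNV calls of one type into a region set
#'
#' Pools the intervals of the requested CNV type across all samples and
#' coalesces overlapping *and book-ended* intervals (MergeBED default
#' behavior), dropping per-sample provenance.
#'
#' @param calls Data.frame of CNV calls (`chrom`, `start`, `end`, `cnv_type`,
#'   `sample_id`), BED coordinates.
#' @param cnv_type `"loss"` or `"gain"`.
#' @return A [region_set()] labelled `merged_loss` or `merged_gain`.
#' @export
#' @examples
#' calls <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 300),
#'                     cnv_type = "loss", sample_id = c("a", "b"))
#' merge_same_type(calls, "loss")
merge_same_type <- function(calls, cnv_type) {
  if (!is.character(cnv_type) || length(cnv_type) != 1L ||
      !cnv_type %in% c("loss", "gain")) {
    stop("cnv_type must be \"loss\" or \"gain\"")
  }
  .check_calls(calls)
  sub <- calls[calls$cnv_type == cnv_type, , drop = FALSE]
  if (!nrow(sub)) {
    return(region_set(sub[, c("chrom", "start", "end")],
                      label = paste0("merged_", cnv_type)))
  }
  gr <- GenomicRanges::reduce(.bed_to_gr(sub))  # merges abutting by default
  region_set(.gr_to_bed(gr), label = paste0("merged_", cnv_type))
}

#' Regions detected as both loss and gain
#'
#' Per-base intersection of a merged loss set with a merged gain set.
#'
#' @param loss,gain Merged [region_set()]s.
#' @return A [region_set()] labelled `shared`.
#' @export
shared_regions <- function(loss, gain) {
  if (!nrow(loss) || !nrow(gain)) {
    return(region_set(loss[0, , drop = FALSE], label = "shared"))
  }
  gr <- GenomicRanges::intersect(.bed_to_gr(loss), .bed_to_gr(gain),
                                 ignore.strand = TRUE)
  region_set(.gr_to_bed(gr), label = "shared")
}

#' Regions unique to loss and unique to gain
#'
#' Per-base set differences: `unique_loss = loss \ gain` and
#' `unique_gain = gain \ loss`. Together with [shared_regions()] these
#' partition the union of the two input sets.
#'
#' @param loss,gain Merged [region_set()]s.
#' @return A list with `unique_loss` and `unique_gain` [region_set()]s.
#' @export
unique_regions <- function(loss, gain) {
  gl <- .bed_to_gr(loss)
  gg <- .bed_to_gr(gain)
  ul <- GenomicRanges::setdiff(gl, gg, ignore.strand = TRUE)
  ug <- GenomicRanges::setdiff(gg, gl, ignore.strand = TRUE)
  list(unique_loss = region_set(.gr_to_bed(ul), label = "unique_loss"),
       unique_gain = region_set(.gr_to_bed(ug), label = "unique_gain"))
}

.check_gene_models <- function(gene_models) {
  req <- c("chrom", "start", "end", "symbol", "gene_type")
  miss <- setdiff(req, names(gene_models))
  if (length(miss)) stop("gene-model table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!nzchar(gene_models$chrom) | !nzchar(gene_models$symbol) |
                 !is.finite(gene_models$start) | !is.finite(gene_models$end) |
                 gene_models$start >= gene_models$end)
  if (length(bad)) stop("malformed gene-model row at line ", bad[1])
  invisible(gene_models)
}

#' Annotate regions with overlapping genes
#'
#' A gene is reported for a region when their intervals overlap by at least
#' 1 bp (half-open adjacency is not an overlap). Optionally restricts to one
#' gene type, mirroring a "Gene type: lncRNA"-style retrieval.
#'
#' @param regions A [region_set()] or BED-style data.frame.
#' @param gene_models Gene-model table (`chrom`, `start`, `end`, `symbol`,
#'   `gene_type`).
#' @param gene_type_filter Optional `"protein_coding"` or `"lncRNA"`.
#' @return A list with `per_region` (list of character vectors of symbols,
#'   one per input region, in input order) and `genes` (deduplicated sorted
#'   union).
#' @export
#' @examples
#' gm <- data.frame(chrom = "chr1", start = 150, end = 160,
#'                  symbol = "A", gene_type = "protein_coding")
#' rs <- region_set(data.frame(chrom = "chr1", start = 100, end = 200))
#' annotate_genes(rs, gm)$genes
annotate_genes <- function(regions, gene_models, gene_type_filter = NULL) {
  .check_gene_models(gene_models)
  if (!is.null(gene_type_filter)) {
    if (!gene_type_filter %in% c("protein_coding", "lncRNA")) {
      stop("gene_type_filter must be \"protein_coding\" or \"lncRNA\"")
    }
    gene_models <- gene_models[gene_models$gene_type == gene_type_filter, ,
                               drop = FALSE]
  }
  if (!nrow(regions) || !nrow(gene_models)) {
    return(list(per_region = rep(list(character()), nrow(regions)),
                genes = character()))
  }
  hits <- GenomicRanges::findOverlaps(.bed_to_gr(regions),
                                      .bed_to_gr(gene_models),
                                      minoverlap = 1L)
  per_region <- split(gene_models$symbol[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(regions))))
  per_region <- lapply(per_region, function(x) sort(unique(x)))
  names(per_region) <- NULL
  list(per_region = per_region,
       genes = sort(unique(unlist(per_region))))
}

#' Read CNV calls from a BED file
#'
#' Expects BED3 plus two extra columns: `cnv_type` (`loss`/`gain`) and
#' `sample_id`. Input is interpreted as 0-based half-open; pass
#' `one_based = TRUE` for 1-based inclusive coordinates (as quoted in
#' clinical tables), which are converted on read.
#'
#' @param path Path to the BED file.
#' @param one_based Logical; convert from 1-based inclusive coordinates.
#' @return Data.frame of calls in BED convention.
#' @export
read_cnv_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "cnv_type",
                                 "sample_id"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character"))
  if (one_based) df$start <- df$start - 1
  .check_calls(df)
}

#' Read gene models from a BED-like file
#'
#' Expects five tab-separated columns: `chrom`, `start`, `end`, `symbol`,
#' `gene_type`.
#'
#' @inheritParams read_cnv_bed
#' @return Gene-model data.frame in BED convention.
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "symbol",
                                 "gene_type"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character"))
  if (one_based) df$start <- df$start - 1
  .check_gene_models(df)
}

#' Write a region set as BED
#'
#' @param rs A [region_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_region_bed <- function(rs, path) {
  write.table(as.data.frame(rs)[, c("chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
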