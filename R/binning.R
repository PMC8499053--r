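#' Gene region descriptor
#'
#' A gene region is the genomic span of a gene row in the annotation,
#' held 0-based half-open internally (GTF input is converted on read).
#' The region is tiled into `bin_size`-bp bins; the last bin may be
#' partial and covers fewer bases.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open genomic coordinates, `end > start`.
#' @param strand one of `"+"`, `"-"`, `"*"`; ignored for binning
#'   (coverage tracks are unstranded).
#' @param bin_size bin width in bp (default 100).
#' @return An `odegr_region` list with fields `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `bin_size`, `n_bins = ceiling((end - start)/bin_size)`.
#' @export
gene_region <- function(gene_id, chrom, start, end, strand = "*",
                        bin_size = 100L) {
  start <- as.integer(start); end <- as.integer(end)
  bin_size <- as.integer(bin_size)
  if (end <= start) stop(sprintf("gene %s: end (%d) must exceed start (%d)",
                                 gene_id, end, start))
  if (bin_size < 1L) stop("bin_size must be >= 1")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 start = start, end = end, strand = strand,
                 bin_size = bin_size,
                 n_bins = as.integer(ceiling((end - start) / bin_size))),
            class = "odegr_region")
}

#' @export
print.odegr_region <- function(x, ...) {
  cat(sprintf("%s %s:%d-%d(%s)  %d bins of %d bp\n", x$gene_id, x$chrom,
              x$start, x$end, x$strand, x$n_bins, x$bin_size))
  invisible(x)
}

# 1-based IRanges of the region's bins on its chromosome.
.bin_ranges <- function(region) {
  bs <- region$bin_size
  starts0 <- region$start + bs * (seq_len(region$n_bins) - 1L)
  ends0 <- pmin(starts0 + bs, region$end)
  IRanges::IRanges(start = starts0 + 1L, end = ends0)
}

#' Read a coverage or mappability track into per-chromosome run-length vectors
#'
#' Accepts bigWig or bedGraph (format sniffed from the extension by
#' rtracklayer). Positions absent from the track are implicitly zero.
#'
#' @param path path to a bigWig (`.bw`/`.bigWig`) or bedGraph file.
#' @return A named `RleList`, one run-length numeric vector per chromosome.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop(sprintf("coverage file not found: %s", path))
  gr <- rtracklayer::import(path)
  GenomicRanges::coverage(gr, weight = "score")
}

#' @rdname read_coverage
#' @export
read_mappability <- function(path) {
  cov <- read_coverage(path)
  rng <- range(unlist(lapply(cov, function(r) range(S4Vectors::runValue(r)))))
  if (rng[1] < 0 || rng[2] > 1)
    stop("mappability values must lie in [0, 1]")
  cov
}

# Per-bin aggregate of a per-base track over a region. Bases beyond the
# recorded track length count as `fill` (0 for coverage). `fun` is viewSums
# for binning and viewMins for the mappability mask.
.bin_aggregate <- function(track, region, fun, fill = 0) {
  if (!region$chrom %in% names(track)) {
    stop(sprintf("chromosome %s absent from track", region$chrom))
  }
  rle <- track[[region$chrom]]
  n <- length(rle)
  br <- .bin_ranges(region)
  out <- numeric(length(br))
  inside <- IRanges::restrict(br, start = 1L, end = n,
                              keep.all.ranges = TRUE)
  ok <- IRanges::width(inside) > 0L
  if (any(ok)) {
    v <- IRanges::Views(rle, inside[ok])
    out[ok] <- as.numeric(fun(v))
  }
  # bins (or bin tails) falling beyond the track: aggregate with `fill`
  short <- IRanges::width(inside) < IRanges::width(br)
  if (any(short)) {
    if (identical(fun, IRanges::viewMins)) {
      out[short & ok] <- pmin(out[short & ok], fill)
      out[short & !ok] <- fill
    } else {
      out[short] <- out[short] + fill * (IRanges::width(br) -
                                           IRanges::width(inside))[short]
    }
  }
  out
}

#' Sum per-base coverage of one cell into the bins of a gene region
#'
#' Bin `b` holds the sum of coverage over bases
#' `[start + b * bin_size, min(start + (b + 1) * bin_size, end))`; the last
#' bin may span fewer bases. Summation preserves count semantics: the total
#' over all bins equals the total per-base coverage of the region.
#'
#' @param coverage an `RleList` as returned by [read_coverage()].
#' @param region an `odegr_region`.
#' @param bin_size optional override of the region's bin size.
#' @return numeric vector of length `region$n_bins`.
#' @export
bin_region <- function(coverage, region, bin_size = NULL) {
  if (!is.null(bin_size)) {
    region <- gene_region(region$gene_id, region$chrom, region$start,
                          region$end, region$strand, bin_size)
  }
  .bin_aggregate(coverage, region, IRanges::viewSums, fill = 0)
}

#' Per-bin keep/drop mask from gene overlap and mappability
#'
#' A bin is dropped when (a) its interval intersects any other gene region
#' (differential expression of an overlapping gene would masquerade as a
#' local DE signal of this gene), or (b) the minimum per-base multi-read
#' mappability over the bin is `<= mappability_floor` (read misalignment in
#' such bins fakes DE). Bases missing from the mappability track count as
#' mappability 0, so their bins are dropped.
#'
#' @param region the target `odegr_region`.
#' @param all_regions list of `odegr_region` covering the gene set used for
#'   the overlap mask (the target itself is skipped by `gene_id`).
#' @param mappability `RleList` of per-base mappability in `[0, 1]`, or
#'   `NULL` to disable the mappability criterion.
#' @param mappability_floor bins with minimum mappability at or below this
#'   are dropped (default 0.5).
#' @param kmer k-mer length of the supplied mappability track, recorded for
#'   provenance only (default 24).
#' @return logical vector, `TRUE` = keep, length `region$n_bins`.
#' @export
build_bin_mask <- function(region, all_regions, mappability = NULL,
                           mappability_floor = 0.5, kmer = 24L) {
  br <- .bin_ranges(region)
  keep <- rep(TRUE, length(br))
  others <- Filter(function(r) r$gene_id != region$gene_id ||
                     r$chrom != region$chrom, all_regions)
  others <- Filter(function(r) r$chrom == region$chrom, others)
  if (length(others) > 0) {
    other_ir <- IRanges::IRanges(
      start = vapply(others, function(r) r$start + 1L, integer(1)),
      end = vapply(others, function(r) r$end, integer(1)))
    keep <- keep & (IRanges::countOverlaps(br, other_ir) == 0L)
  }
  if (!is.null(mappability)) {
    mins <- .bin_aggregate(mappability, region, IRanges::viewMins, fill = 0)
    keep <- keep & (mins > mappability_floor)
  }
  keep
}

#' Construct a per-gene binned coverage matrix
#'
#' @param region an `odegr_region`.
#' @param values cells x bins non-negative matrix.
#' @param cell_ids cell identifiers, one per row.
#' @param bin_mask logical keep flags (length = number of columns), or `NULL`.
#' @param transformed has `log10(x + 1)` already been applied?
#' @return An `odegr_matrix` object.
#' @export
binned_region_matrix <- function(region, values, cell_ids,
                                 bin_mask = NULL, transformed = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("binned values must be non-negative")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length must equal the number of rows")
  if (!is.null(bin_mask) && length(bin_mask) != ncol(values))
    stop("bin_mask length must equal the number of columns")
  rownames(values) <- cell_ids
  structure(list(gene = region, values = values,
                 bin_mask = bin_mask, cell_ids = as.character(cell_ids),
                 transformed = isTRUE(transformed)),
            class = "odegr_matrix")
}

#' @export
print.odegr_matrix <- function(x, ...) {
  cat(sprintf("binned coverage matrix for %s: %d cells x %d bins%s\n",
              x$gene$gene_id, nrow(x$values), ncol(x$values),
              if (x$transformed) " (log10(x+1))" else " (raw)"))
  invisible(x)
}

#' Bin the coverage of every cell over one gene region
#'
#' @param coverages named list of `RleList` coverage tracks, one per cell.
#' @param region an `odegr_region`.
#' @return raw (untransformed) `odegr_matrix`, cells in list order.
#' @export
build_gene_matrix <- function(coverages, region) {
  vals <- t(vapply(coverages, bin_region, numeric(region$n_bins),
                   region = region))
  binned_region_matrix(region, vals, names(coverages))
}

#' Apply the bin mask, the minimum-bin filter and the log transform
#'
#' Masked columns are removed; a gene retaining fewer than `min_bins` bins
#' is rejected (returned as `NULL` so callers can record the attrition);
#' otherwise every value `x` becomes `log10(x + 1)` and the matrix is
#' flagged transformed. Re-transforming is an error.
#'
#' @param raw an untransformed `odegr_matrix`.
#' @param mask logical keep flags, length `ncol(raw$values)`.
#' @param min_bins minimum kept-bin count, strict (default 100: a gene with
#'   99 kept bins is rejected, one with exactly 100 is retained).
#' @return transformed `odegr_matrix`, or `NULL` if the gene is rejected.
#' @export
finalize_gene_matrix <- function(raw, mask = raw$bin_mask, min_bins = 100L) {
  if (isTRUE(raw$transformed))
    stop("matrix already log-transformed; refusing to transform twice")
  if (is.null(mask)) mask <- rep(TRUE, ncol(raw$values))
  if (length(mask) != ncol(raw$values))
    stop("mask length must equal the column count")
  kept <- raw$values[, mask, drop = FALSE]
  if (ncol(kept) < min_bins) return(NULL)
  binned_region_matrix(raw$gene, log10(kept + 1), raw$cell_ids,
                       bin_mask = NULL, transformed = TRUE)
}

# Transform on the fly where a caller may hold raw counts.
.as_log <- function(x) {
  if (isTRUE(x$transformed)) return(x)
  binned_region_matrix(x$gene, log10(x$values + 1), x$cell_ids,
                       bin_mask = x$bin_mask, transformed = TRUE)
}

#' Read gene regions from a GENCODE-style GTF
#'
#' Keeps `type == "gene"` rows; coordinates converted from 1-based
#' inclusive GTF to 0-based half-open.
#'
#' @param path GTF file.
#' @param bin_size bin width attached to each region.
#' @return list with `regions` (named list of `odegr_region`), `gene_type`
#'   (named character), and `tx2gene` (data.frame transcript_id, gene_id)
#'   from transcript rows when present.
#' @export
read_gtf_genes <- function(path, bin_size = 100L) {
  if (!file.exists(path)) stop(sprintf("GTF file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  genes <- gr[meta$type == "gene"]
  gm <- S4Vectors::mcols(genes)
  regions <- lapply(seq_along(genes), function(i) {
    gene_region(gm$gene_id[i], as.character(GenomicRanges::seqnames(genes)[i]),
                GenomicRanges::start(genes)[i] - 1L,
                GenomicRanges::end(genes)[i],
                as.character(GenomicRanges::strand(genes)[i]), bin_size)
  })
  names(regions) <- gm$gene_id
  gtype <- if ("gene_type" %in% colnames(gm))
    setNames(as.character(gm$gene_type), gm$gene_id)
  else setNames(rep(NA_character_, length(genes)), gm$gene_id)
  tx <- gr[meta$type == "transcript"]
  tx2gene <- if (length(tx) > 0) {
    tm <- S4Vectors::mcols(tx)
    data.frame(transcript_id = as.character(tm$transcript_id),
               gene_id = as.character(tm$gene_id),
               stringsAsFactors = FALSE)
  } else data.frame(transcript_id = character(), gene_id = character())
  list(regions = regions, gene_type = gtype, tx2gene = tx2gene)
}
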