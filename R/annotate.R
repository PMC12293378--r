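#' Read gene models from BED or GFF3
#'
#' Loads gene intervals with symbols and biotypes from a BED file (0-based
#' half-open, `name` column used as the symbol) or a GFF3/GTF file (1-based
#' inclusive; `gene` records with `gene_name`/`gene_type` style attributes,
#' as in Gencode). The dialect is auto-detected from the file extension.
#' Coordinates are returned as a `GRanges` (1-based inclusive, the native R
#' convention); [rtracklayer::import()] performs the coordinate-dialect
#' conversion.
#'
#' @param path File path ending in `.bed`, `.gff`, `.gff3`, or `.gtf`.
#' @param biotype Default biotype assigned to records that carry none
#'   (e.g. BED input); default `"protein_coding"`.
#' @param feature_type For GFF input, the record type to keep (default
#'   `"gene"`).
#' @return `GRanges` with metadata columns `symbol` and `biotype`.
#' @export
read_gene_models <- function(path, biotype = "protein_coding",
                             feature_type = "gene") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED/GFF requires the rtracklayer package")
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (ext %in% c("gff", "gff3", "gtf")) {
    if ("type" %in% names(mc)) gr <- gr[as.character(mc$type) %in% feature_type]
    mc <- S4Vectors::mcols(gr)
    sym <- if ("gene_name" %in% names(mc)) mc$gene_name
           else if ("Name" %in% names(mc)) mc$Name
           else if ("gene_id" %in% names(mc)) mc$gene_id
           else stop("GFF input lacks gene_name/Name/gene_id attributes")
    bt <- if ("gene_type" %in% names(mc)) mc$gene_type
          else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
          else biotype
  } else {
    sym <- if ("name" %in% names(mc)) mc$name
           else stop("BED input lacks a name column")
    bt <- biotype
  }
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$symbol <- as.character(sym)
  S4Vectors::mcols(out)$biotype <- rep_len(as.character(bt), length(out))
  out
}

as_interval_df <- function(genes) {
  if (methods::is(genes, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               symbol = S4Vectors::mcols(genes)$symbol,
               biotype = if ("biotype" %in% names(S4Vectors::mcols(genes)))
                 S4Vectors::mcols(genes)$biotype else "protein_coding",
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end", "symbol") %in% names(genes)))
    if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
    as.data.frame(genes, stringsAsFactors = FALSE)
  }
}

#' Closest protein-coding genes to a marker interval
#'
#' Maps one marker interval to the three classes of closest protein-coding
#' loci: all genes overlapping the interval (`within`), the nearest
#' non-overlapping gene with smaller coordinates (`upstream`), and the
#' nearest non-overlapping gene with larger coordinates (`downstream`).
#' Coordinates are 1-based inclusive; the gap to a non-overlapping gene is
#' the number of bases strictly between the interval and the gene (0 for
#' adjacent features). Distance ties are broken by symbol, lexicographically.
#' Strand is ignored: upstream/downstream refer to the coordinate axis, not
#' transcription direction.
#'
#' @param ccm List or one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive), or a length-1 `GRanges`.
#' @param genes `GRanges` from [read_gene_models()] or a data frame with
#'   `chrom`, `start`, `end`, `symbol`, and optionally `biotype`. Records
#'   whose biotype is not `"protein_coding"` are excluded before the search.
#' @return List with `within` (data frame of overlapping genes), `upstream`
#'   and `downstream` (one-row data frames with `symbol` and `distance`, or
#'   NULL), and `found` flag (FALSE when the chromosome is absent from the
#'   annotation).
#' @export
closest_genes <- function(ccm, genes) {
  if (methods::is(ccm, "GRanges")) {
    stopifnot(length(ccm) == 1L)
    ccm <- list(chrom = as.character(GenomicRanges::seqnames(ccm)),
                start = GenomicRanges::start(ccm), end = GenomicRanges::end(ccm))
  }
  stopifnot(ccm$start <= ccm$end)
  g <- as_interval_df(genes)
  g <- g[g$biotype == "protein_coding", , drop = FALSE]
  g <- g[g$chrom == ccm$chrom, , drop = FALSE]
  if (!nrow(g))
    return(list(within = g[0, ], upstream = NULL, downstream = NULL, found = FALSE))

  overlaps <- g$end >= ccm$start & g$start <= ccm$end
  within <- g[overlaps, , drop = FALSE]
  within <- within[order(within$start, within$symbol), , drop = FALSE]

  pick_side <- function(mask, gap) {
    if (!any(mask)) return(NULL)
    cand <- g[mask, , drop = FALSE]
    cand$distance <- gap[mask]
    cand <- cand[order(cand$distance, cand$symbol), , drop = FALSE]
    cand[1L, c("symbol", "chrom", "start", "end", "distance"), drop = FALSE]
  }
  up <- pick_side(!overlaps & g$end < ccm$start, ccm$start - g$end - 1L)
  down <- pick_side(!overlaps & g$start > ccm$end, g$start - ccm$end - 1L)
  list(within = within, upstream = up, downstream = down, found = TRUE)
}

#' Validate the genomic span between two marker anchors
#'
#' A long-range interaction is plausible when its two anchor sites lie on the
#' same chromosome at least 10 kb and less than 300 kb apart. Distance is
#' measured midpoint-to-midpoint (the convention is recorded in the result).
#' Anchors on different chromosomes fail with a trans-interaction flag.
#'
#' @param anchor_a,anchor_b Lists with `chrom`, `start`, `end` (1-based
#'   inclusive) or length-1 `GRanges`.
#' @param min_span,max_span Bounds in bp: pass iff
#'   `min_span <= distance < max_span` (defaults 10000 and 300000).
#' @return List with `pass`, `distance` (bp, NA for trans), `trans` flag,
#'   `convention = "midpoint"`.
#' @export
validate_ccm_span <- function(anchor_a, anchor_b,
                              min_span = 1e4, max_span = 3e5) {
  to_list <- function(x) {
    if (methods::is(x, "GRanges"))
      list(chrom = as.character(GenomicRanges::seqnames(x)),
           start = GenomicRanges::start(x), end = GenomicRanges::end(x))
    else x
  }
  a <- to_list(anchor_a); b <- to_list(anchor_b)
  stopifnot(a$start <= a$end, b$start <= b$end)
  if (a$chrom != b$chrom)
    return(list(pass = FALSE, distance = NA_real_, trans = TRUE,
                convention = "midpoint"))
  d <- abs((a$start + a$end) / 2 - (b$start + b$end) / 2)
  list(pass = d >= min_span && d < max_span, distance = d, trans = FALSE,
       convention = "midpoint")
}

#' Multi-marker gene coverage
#'
#' Counts, for each gene in a marker-to-gene mapping, how many distinct
#' markers cover it, and reports the fraction of genes covered by more than
#' one marker (raw and rounded to integer percent).
#'
#' @param ccm_gene_map Data frame with columns `ccm_id` and `gene` (duplicate
#'   pairs are counted once).
#' @return List with `per_gene` (data frame `gene`, `n_ccms`), `n_genes`,
#'   `n_multi`, `fraction` (NA when the map is empty), `percent` (integer
#'   percent), `empty` flag.
#' @export
multi_coverage <- function(ccm_gene_map) {
  stopifnot(is.data.frame(ccm_gene_map),
            all(c("ccm_id", "gene") %in% names(ccm_gene_map)))
  map <- unique(ccm_gene_map[, c("ccm_id", "gene")])
  if (!nrow(map))
    return(list(per_gene = data.frame(gene = character(0), n_ccms = integer(0)),
                n_genes = 0L, n_multi = 0L, fraction = NA_real_,
                percent = NA_integer_, empty = TRUE))
  counts <- table(map$gene)
  per_gene <- data.frame(gene = names(counts), n_ccms = as.integer(counts),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$n_ccms, per_gene$gene), , drop = FALSE]
  n_multi <- sum(per_gene$n_ccms > 1L)
  fraction <- n_multi / nrow(per_gene)
  list(per_gene = per_gene, n_genes = nrow(per_gene), n_multi = n_multi,
       fraction = fraction, percent = as.integer(round(fraction * 100)),
       empty = FALSE)
}

#' Convert between file (1-based inclusive) and internal (0-based half-open)
#' interval coordinates
#'
#' @param start,end Interval coordinates.
#' @return A list with converted `start` and `end`.
#' @keywords internal
#' @export
coords_to_internal <- function(start, end) list(start = start - 1L, end = end)

#' @rdname coords_to_internal
#' @export
coords_to_file <- function(start, end) list(start = start + 1L, end = end)
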