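#' Build a genomic exclusion set
#'
#' Exclusion intervals are carried in 0-based half-open coordinates (BED
#' convention). Recognised categories mirror the region classes that are
#' removed from MRD panel design: known germline SNPs, common CHIP regions,
#' high GC content, high polymorphism rates, mapping difficulties, systematic
#' bias, short tandem repeats, low sequence complexity, and the HLA locus.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `category`.
#' @param category Default category applied when the data.frame lacks one.
#' @return A `GRanges` (1-based internally) with a `category` metadata column.
#' @export
exclusion_set <- function(intervals, category = "systematic_bias") {
  allowed <- c("germline_snp", "chip_region", "high_gc", "polymorphic",
               "mapping_difficulty", "systematic_bias", "short_tandem_repeat",
               "low_complexity", "hla")
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$category <- character(0)
    return(gr)
  }
  if (any(intervals$start < 0)) stop("interval starts must be >= 0")
  if (any(intervals$start >= intervals$end)) stop("intervals must have start < end")
  cat_col <- if ("category" %in% names(intervals)) intervals$category else category
  bad <- setdiff(unique(cat_col), allowed)
  if (length(bad)) stop("unknown exclusion category: ", paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  S4Vectors::mcols(gr)$category <- rep(cat_col, length.out = length(gr))
  gr
}

#' Convert a GRanges back to 0-based half-open intervals
#'
#' @param gr A `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and any
#'   metadata columns.
#' @export
granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

# 1-based point loci -> GRanges, for overlap queries against exclusion sets
loci_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}

# TRUE for loci overlapping any interval of the (possibly filtered) set
loci_overlap_any <- function(chrom, pos, exclusions) {
  if (is.null(exclusions) || length(exclusions) == 0)
    return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(loci_granges(chrom, pos), exclusions)
}
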