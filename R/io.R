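#' Write a bespoke panel to disk
#'
#' Emits the three-file panel representation: a BED of target loci
#' (`targets.bed`, 0-based half-open), a TSV manifest of MRD targets and QA
#' SNVs (`manifest.tsv`), and a JSON header (`panel.json`) with patient id,
#' cap, seed and predicted LOD.
#'
#' @param panel A `bespoke_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "bespoke_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- panel$targets
  bed <- data.frame(chrom = t$chrom, start = t$pos - 1L, end = t$pos,
                    name = t$target_id)
  utils::write.table(bed, file.path(dir, "targets.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- data.frame(chrom = t$chrom, pos = t$pos, ref = t$ref,
                         alt = t$alt, tumor_af = t$tumor_af,
                         error_rate = t$error_rate,
                         rank_score = t$rank_score, active = t$active,
                         type = "mrd", stringsAsFactors = FALSE)
  if (!is.null(panel$qa_snvs)) {
    q <- panel$qa_snvs
    manifest <- rbind(manifest,
                      data.frame(chrom = q$chrom, pos = q$pos, ref = q$ref,
                                 alt = q$alt,
                                 tumor_af = NA_real_,
                                 error_rate = NA_real_,
                                 rank_score = NA_real_, active = TRUE,
                                 type = "qa", stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  header <- list(patient_id = panel$patient_id,
                 panel_cap = panel$panel_cap,
                 seed = panel$seed,
                 n_targets = nrow(t),
                 n_qa_snvs = if (is.null(panel$qa_snvs)) 0L
                   else nrow(panel$qa_snvs),
                 predicted_lod_ppm = panel$predicted_lod_ppm)
  jsonlite::write_json(header, file.path(dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bespoke panel written by [write_panel()]
#'
#' @param dir Panel directory.
#' @return A `bespoke_panel`.
#' @export
read_panel <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "panel.json"),
                                simplifyVector = TRUE)
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  mrd <- manifest[manifest$type == "mrd", , drop = FALSE]
  qa <- manifest[manifest$type == "qa", , drop = FALSE]
  targets <- data.frame(
    target_id = paste0(mrd$chrom, ":", mrd$pos, ":", mrd$ref, ">", mrd$alt),
    chrom = mrd$chrom, pos = mrd$pos, ref = mrd$ref, alt = mrd$alt,
    tumor_af = mrd$tumor_af, error_rate = mrd$error_rate,
    rank_score = mrd$rank_score, active = mrd$active,
    stringsAsFactors = FALSE)
  rownames(targets) <- NULL
  qa_snvs <- if (nrow(qa)) {
    data.frame(chrom = qa$chrom, pos = qa$pos, ref = qa$ref, alt = qa$alt,
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(patient_id = header$patient_id,
                 targets = targets,
                 qa_snvs = qa_snvs,
                 predicted_lod_ppm = header$predicted_lod_ppm,
                 panel_cap = as.integer(header$panel_cap),
                 seed = as.integer(header$seed)),
            class = "bespoke_panel")
}

#' Read somatic SNV calls from a VCF
#'
#' Accepts bi-allelic SNV records; the tumor allele frequency is taken from
#' the INFO field named by `af_field`.
#'
#' @param path VCF path.
#' @param af_field INFO key holding the tumor allele fraction (default `AF`).
#' @return SNV call data.frame (see [filter_candidate_variants()]).
#' @export
read_somatic_vcf <- function(path, af_field = "AF") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, af_field)))
  if (all(is.na(af)))
    stop("INFO field '", af_field, "' absent or non-numeric in ", path)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!all(snv)) stop("non-SNV record(s) in ", path)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT, tumor_af = af,
             passed_caller_filters = fix$FILTER %in% c("PASS", ".", NA),
             stringsAsFactors = FALSE)
}

#' Write somatic SNV calls as a minimal VCF
#'
#' @param calls SNV call data.frame.
#' @param path Output path.
#' @param reference Optional `DNAStringSet` for contig header lines.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(calls, path, reference = NULL) {
  validate_snv_calls(calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumor allele fraction\">")
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          Biostrings::width(reference)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f",
                  calls$chrom, calls$pos, calls$ref, calls$alt, calls$tumor_af)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read exclusion intervals from BED files
#'
#' Either a 4-column BED whose name column carries the category, or a
#' directory of per-category BED files named `<category>.bed`.
#'
#' @param path BED file or directory of BED files.
#' @return `GRanges` exclusion set (see [exclusion_set()]).
#' @export
read_exclusion_bed <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.bed$", full.names = TRUE)
    if (!length(files)) stop("no .bed files under ", path)
    dfs <- lapply(files, function(f) {
      gr <- rtracklayer::import(f, format = "BED")
      d <- granges_to_intervals(gr)
      d$category <- sub("\\.bed$", "", basename(f))
      d[c("chrom", "start", "end", "category")]
    })
    return(exclusion_set(do.call(rbind, dfs)))
  }
  gr <- rtracklayer::import(path, format = "BED")
  d <- granges_to_intervals(gr)
  if (!"name" %in% names(d)) stop("category BED needs a 4th (name) column")
  d$category <- d$name
  exclusion_set(d[c("chrom", "start", "end", "category")])
}

#' Write aligned read pairs as SAM
#'
#' Each fragment is emitted as a properly paired mate pair whose two reads
#' both span the full fragment (the simulator's convention); the original
#' strand is encoded in the orientation flags (top = read1 forward, bottom =
#' read1 reverse). Records are coordinate sorted.
#'
#' @param pairs Read-pair data.frame (see
#'   [group_read_pairs_by_position()]).
#' @param path Output SAM path.
#' @param reference `DNAStringSet` for `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, reference) {
  validate_read_pairs(pairs)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  ord <- order(pairs$chrom, pairs$start, pairs$end, pairs$read_id)
  p <- pairs[ord, , drop = FALSE]
  L <- p$end - p$start
  pos1 <- p$start + 1L
  cigar <- paste0(L, "M")
  f1 <- ifelse(p$strand_tag == "top", 99L, 83L)
  f2 <- ifelse(p$strand_tag == "top", 147L, 163L)
  tlen1 <- ifelse(p$strand_tag == "top", L, -L)
  r1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                p$read_id, f1, p$chrom, pos1, cigar, pos1, tlen1,
                p$bases, p$quals)
  r2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                p$read_id, f2, p$chrom, pos1, cigar, pos1, -tlen1,
                p$bases, p$quals)
  writeLines(c(hdr, as.vector(rbind(r1, r2))), path)
  invisible(path)
}

#' Read plasma read pairs from a SAM/BAM file
#'
#' Reconstructs fragment-spanning read pairs from a coordinate-sorted,
#' paired SAM or BAM: mates are joined on the read name, the fragment spans
#' the outer coordinates, and where both mates cover a position the
#' higher-quality base is taken. The original-strand tag is derived from the
#' orientation of read 1 (forward = top, reverse = bottom). Reads that are
#' unmapped, have an unmapped or inter-chromosomal mate, or carry non-M
#' CIGAR operations are skipped and counted.
#'
#' @param path SAM or BAM path.
#' @return List with `pairs` (read-pair data.frame) and `skipped` (named
#'   counts of discarded records).
#' @export
read_plasma_sam <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mrnm", "mpos",
             "seq", "qual")))[[1]]
  flag <- res$flag
  skipped <- c(unmapped_or_mate = 0L, inter_chromosomal = 0L,
               non_matching_cigar = 0L)
  ok <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 8L)   # both mates mapped
  skipped["unmapped_or_mate"] <- sum(!ok)
  same <- ok & as.character(res$rname) == as.character(res$mrnm)
  skipped["inter_chromosomal"] <- sum(ok & !same)
  m_only <- grepl("^[0-9]+M$", res$cigar)
  skipped["non_matching_cigar"] <- sum(same & !m_only)
  use <- which(same & m_only)

  qname <- res$qname[use]
  first <- bitwAnd(flag[use], 64L) > 0L
  rev <- bitwAnd(flag[use], 16L) > 0L
  df <- data.frame(qname = qname,
                   chrom = as.character(res$rname)[use],
                   pos = res$pos[use],
                   len = as.integer(sub("M$", "", res$cigar[use])),
                   first = first, rev = rev,
                   seq = as.character(res$seq)[use],
                   qual = as.character(res$qual)[use],
                   stringsAsFactors = FALSE)
  sp <- split(df, df$qname)
  rows <- lapply(sp, function(d) {
    if (nrow(d) != 2L) return(NULL)
    start0 <- min(d$pos) - 1L
    end0 <- max(d$pos + d$len) - 1L
    L <- end0 - start0
    bases <- rep("N", L); quals <- rep(0L, L)
    for (j in 1:2) {
      b <- strsplit(d$seq[j], "", fixed = TRUE)[[1]]
      q <- phred_to_int(d$qual[j])
      at <- (d$pos[j] - 1L - start0) + seq_along(b)
      better <- q > quals[at]
      bases[at][better] <- b[better]
      quals[at][better] <- q[better]
    }
    r1rev <- d$rev[d$first][1]
    data.frame(chrom = d$chrom[1], start = start0, end = end0,
               strand_tag = if (r1rev) "bottom" else "top",
               bases = paste(bases, collapse = ""),
               quals = int_to_phred(quals),
               read_id = d$qname[1], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand_tag = character(0),
                        bases = character(0), quals = character(0),
                        read_id = character(0))
  rownames(pairs) <- NULL
  list(pairs = pairs, skipped = skipped)
}

#' Write per-sample detection results as JSON
#'
#' @param result A `sample_detection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detection_json <- function(result, path) {
  stopifnot(inherits(result, "sample_detection_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
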