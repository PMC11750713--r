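#' Group aligned read pairs by fragment position
#'
#' Read pairs sharing identical paired mapped positions — the (chrom, start,
#' end) outer coordinates of the sequenced fragment — form one initial
#' consensus group, the positional proxy for "same founding molecule".
#'
#' @param pairs data.frame of read pairs: `chrom`, `start`, `end` (0-based
#'   half-open fragment coordinates), `strand_tag` (`"top"`/`"bottom"`,
#'   the original-strand label derived from read orientation), `bases`
#'   (fragment-length base string), `quals` (Phred+33 string), `read_id`.
#' @return Named list of `consensus_group` objects (data.frames with a
#'   `split_index` attribute), keyed and ordered by `chrom:start-end`.
#' @export
group_read_pairs_by_position <- function(pairs) {
  validate_read_pairs(pairs)
  if (nrow(pairs) == 0) return(list())
  key <- sprintf("%s:%d-%d", pairs$chrom, pairs$start, pairs$end)
  groups <- split(pairs, key)
  groups <- groups[order(names(groups))]
  lapply(groups, function(g) {
    rownames(g) <- NULL
    attr(g, "split_index") <- 0L
    class(g) <- c("consensus_group", class(g))
    g
  })
}

validate_read_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("chrom", "start", "end", "strand_tag", "bases", "quals") %in%
                  names(pairs)))
  if (nrow(pairs) == 0) return(invisible(pairs))
  if (any(pairs$start < 0) || any(pairs$start >= pairs$end))
    stop("malformed fragment coordinates: need 0 <= start < end")
  len <- pairs$end - pairs$start
  if (any(nchar(pairs$bases) != len) || any(nchar(pairs$quals) != len))
    stop("bases and quals must both span the fragment (end - start)")
  if (!all(pairs$strand_tag %in% c("top", "bottom")))
    stop("strand_tag must be 'top' or 'bottom'")
  invisible(pairs)
}

# decode Phred+33 string to integer qualities
phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

# group df -> character matrix (reads x positions) with quality-based masking
group_base_matrix <- function(group, q_mask = 29L) {
  L <- group$end[1] - group$start[1]
  bm <- matrix(unlist(strsplit(group$bases, "", fixed = TRUE), use.names = FALSE),
               nrow = nrow(group), ncol = L, byrow = TRUE)
  qm <- matrix(unlist(lapply(group$quals, phred_to_int), use.names = FALSE),
               nrow = nrow(group), ncol = L, byrow = TRUE)
  bm[qm < q_mask] <- "N"
  bm
}

# per-column consensus over a base matrix; min_agreement = NULL gives the
# plain majority (ties to the alphabetically first base, order-independent)
column_consensus <- function(bm, min_agreement = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1L)
  cnt <- vapply(bases, function(b) colSums(bm == b), numeric(ncol(bm)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)  # single column input
  unmasked <- rowSums(cnt)
  top_idx <- max.col(cnt, ties.method = "first")
  top_cnt <- cnt[cbind(seq_len(nrow(cnt)), top_idx)]
  out <- bases[top_idx]
  out[unmasked == 0] <- "N"
  if (!is.null(min_agreement)) {
    frac <- ifelse(unmasked > 0, top_cnt / unmasked, 0)
    out[frac < min_agreement] <- "N"
  }
  out
}

#' Split consensus groups on alleles shared with other groups
#'
#' A positional grouping can merge distinct founding molecules that happen to
#' share fragment coordinates. A non-reference allele carried by only a strict
#' subset of a group's reads, and independently observed in at least
#' `min_other_groups` other consensus groups, is evidence of such a collision:
#' the group is split to isolate the allele-carrying reads in their own new
#' group. One split (the highest-frequency qualifying allele) is applied per
#' group per pass; passes repeat until no group splits. Reads are conserved.
#'
#' @param groups List of `consensus_group`s from
#'   [group_read_pairs_by_position()].
#' @param reference `DNAStringSet` defining the reference allele at each
#'   position.
#' @param min_other_groups Minimum number of *other* groups in which the
#'   allele must be observed, default 2.
#' @param q_mask Bases below this quality are ignored when detecting alleles.
#' @return List of `consensus_group`s; split descendants get suffixed names
#'   and an incremented `split_index`.
#' @export
split_groups_on_shared_alleles <- function(groups, reference,
                                           min_other_groups = 2L,
                                           q_mask = 29L) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  # reference as per-chromosome character vectors, built lazily once
  ref_chars <- new.env(parent = emptyenv())
  get_ref <- function(chrom) {
    if (is.null(ref_chars[[chrom]]))
      ref_chars[[chrom]] <- strsplit(as.character(reference[[chrom]]), "",
                                     fixed = TRUE)[[1]]
    ref_chars[[chrom]]
  }
  allele_cache <- list()
  repeat {
    todo <- setdiff(names(groups), names(allele_cache))
    for (nm in todo)
      allele_cache[[nm]] <- group_nonref_alleles(groups[[nm]], get_ref,
                                                 q_mask = q_mask)
    allele_cache <- allele_cache[names(groups)]
    # how many groups carry each (chrom, genomic pos, allele)?
    all_keys <- unlist(lapply(allele_cache, function(a) a$key),
                       use.names = FALSE)
    group_count <- table(all_keys)
    changed <- FALSE
    out <- list()
    for (nm in names(groups)) {
      g <- groups[[nm]]
      a <- allele_cache[[nm]]
      qual <- a[a$n_carriers >= 1 & a$n_carriers < nrow(g) &
                  (as.integer(group_count[a$key]) - 1L) >= min_other_groups, ,
                drop = FALSE]
      if (nrow(qual) == 0) { out[[nm]] <- g; next }
      qual <- qual[order(-qual$n_carriers, qual$pos, qual$allele), , drop = FALSE]
      pick <- qual[1, ]
      col <- pick$pos - g$start[1]  # genomic 1-based -> 1-based column
      bm <- group_base_matrix(g, q_mask)
      carrier <- bm[, col] == pick$allele
      g1 <- g[carrier, , drop = FALSE]; g2 <- g[!carrier, , drop = FALSE]
      si <- attr(g, "split_index") + 1L
      rownames(g1) <- NULL; rownames(g2) <- NULL
      attr(g1, "split_index") <- si; attr(g2, "split_index") <- si
      class(g1) <- class(g); class(g2) <- class(g)
      out[[paste0(nm, ".a")]] <- g1
      out[[paste0(nm, ".b")]] <- g2
      allele_cache[[nm]] <- NULL
      changed <- TRUE
    }
    groups <- out
    if (!changed) break
  }
  groups
}

# non-reference alleles observed in a group's unmasked bases:
# data.frame(pos, allele, n_carriers, key); pos is genomic 1-based.
# get_ref(chrom) returns the chromosome as a character vector.
group_nonref_alleles <- function(group, get_ref, q_mask = 29L) {
  none <- data.frame(pos = integer(0), allele = character(0),
                     n_carriers = integer(0), key = character(0),
                     stringsAsFactors = FALSE)
  bm <- group_base_matrix(group, q_mask)
  chrom <- group$chrom[1]; start0 <- group$start[1]
  L <- ncol(bm)
  refseg <- get_ref(chrom)[(start0 + 1L):(start0 + L)]
  hit <- bm != "N" & bm != matrix(refseg, nrow(bm), L, byrow = TRUE)
  if (!any(hit)) return(none)
  idx <- which(hit, arr.ind = TRUE)
  pos <- start0 + idx[, 2]
  allele <- bm[idx]
  k <- paste0(pos, ":", allele)
  u <- !duplicated(k)
  n_carriers <- tabulate(match(k, k[u]))
  data.frame(pos = pos[u], allele = allele[u],
             n_carriers = n_carriers,
             key = paste0(chrom, ":", k[u]),
             stringsAsFactors = FALSE)
}

#' Build a duplex consensus molecule from one consensus group
#'
#' Applies the noise-suppression rules in a fixed order: (1) bases with
#' quality below `q_mask` are masked; (2) reads with more than
#' `max_masked_fraction` of their bases masked are removed; (3) a provisional
#' majority consensus is formed; (4) reads whose unmasked bases differ from
#' the provisional consensus by more than `max_divergence` are removed; (5)
#' the per-position consensus is recomputed, masking positions with less than
#' `agreement` concordance among contributing unmasked bases; (6) the
#' molecule is accepted only with at least one surviving read from each
#' original DNA strand (the duplex requirement).
#'
#' @param group A `consensus_group`.
#' @param q_mask Phred threshold; bases with quality < `q_mask` are masked
#'   (default 29).
#' @param max_divergence Maximum tolerated mismatch fraction of a read versus
#'   the provisional consensus (default 0.025).
#' @param agreement Minimum per-position concordance; below it the position is
#'   masked (default 0.90).
#' @param max_masked_fraction Reads with a larger masked fraction are removed
#'   (default 0.20).
#' @return A `consensus_molecule` (list: `chrom`, `start`, `end`, `sequence`
#'   with `N` as the mask sentinel, `n_top`, `n_bottom`, `n_members`), or a
#'   `consensus_rejection` (list with `reason` in `"single_strand"`,
#'   `"all_reads_removed"`).
#' @export
build_consensus_molecule <- function(group, q_mask = 29L,
                                     max_divergence = 0.025,
                                     agreement = 0.90,
                                     max_masked_fraction = 0.20) {
  if (!is.data.frame(group) || nrow(group) == 0) stop("empty consensus group")
  bm <- group_base_matrix(group, q_mask)
  strands <- group$strand_tag

  masked_frac <- rowMeans(bm == "N")
  keep <- masked_frac <= max_masked_fraction
  if (!any(keep)) return(consensus_rejection("all_reads_removed"))
  bm <- bm[keep, , drop = FALSE]; strands <- strands[keep]

  provisional <- column_consensus(bm)
  provm <- matrix(provisional, nrow = nrow(bm), ncol = ncol(bm), byrow = TRUE)
  comparable <- bm != "N" & provm != "N"
  mism <- rowSums(bm != provm & comparable)
  denom <- rowSums(comparable)
  divergence <- ifelse(denom > 0, mism / denom, 0)
  keep <- divergence <= max_divergence
  if (!any(keep)) return(consensus_rejection("all_reads_removed"))
  bm <- bm[keep, , drop = FALSE]; strands <- strands[keep]

  n_top <- sum(strands == "top"); n_bottom <- sum(strands == "bottom")
  if (n_top < 1L || n_bottom < 1L) return(consensus_rejection("single_strand"))

  sequence <- paste(column_consensus(bm, min_agreement = agreement),
                    collapse = "")
  structure(list(chrom = group$chrom[1],
                 start = group$start[1],
                 end = group$end[1],
                 sequence = sequence,
                 n_top = n_top,
                 n_bottom = n_bottom,
                 n_members = n_top + n_bottom),
            class = "consensus_molecule")
}

consensus_rejection <- function(reason) {
  structure(list(reason = reason), class = "consensus_rejection")
}

#' Run the full molecular-consensus pipeline on aligned read pairs
#'
#' Positional grouping, allele-based group splitting, and per-group duplex
#' consensus (see [build_consensus_molecule()]), returning unique consensus
#' molecules plus a QC summary.
#'
#' @inheritParams group_read_pairs_by_position
#' @inheritParams build_consensus_molecule
#' @param reference `DNAStringSet`; required when `split = TRUE`.
#' @param split Apply [split_groups_on_shared_alleles()] before consensus?
#' @param min_other_groups Passed to the splitting step.
#' @return List with `molecules` (data.frame: `chrom`, `start`, `end`,
#'   `sequence`, `n_top`, `n_bottom`, `n_members`) and `qc` (list of
#'   counters: reads in, groups, splits, molecules, rejection counts).
#' @export
call_consensus_molecules <- function(pairs, reference = NULL, split = TRUE,
                                     q_mask = 29L, max_divergence = 0.025,
                                     agreement = 0.90,
                                     max_masked_fraction = 0.20,
                                     min_other_groups = 2L) {
  groups <- group_read_pairs_by_position(pairs)
  n_groups_initial <- length(groups)
  if (split) {
    if (is.null(reference))
      stop("a reference is required for allele-based group splitting")
    groups <- split_groups_on_shared_alleles(groups, reference,
                                             min_other_groups = min_other_groups,
                                             q_mask = q_mask)
  }
  rejected <- c(single_strand = 0L, all_reads_removed = 0L)
  mols <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    m <- build_consensus_molecule(groups[[i]], q_mask = q_mask,
                                  max_divergence = max_divergence,
                                  agreement = agreement,
                                  max_masked_fraction = max_masked_fraction)
    if (inherits(m, "consensus_rejection")) {
      rejected[m$reason] <- rejected[m$reason] + 1L
    } else {
      mols[[i]] <- as.data.frame(unclass(m), stringsAsFactors = FALSE)
    }
  }
  molecules <- do.call(rbind, mols)
  if (is.null(molecules))
    molecules <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), sequence = character(0),
                            n_top = integer(0), n_bottom = integer(0),
                            n_members = integer(0))
  rownames(molecules) <- NULL
  list(molecules = molecules,
       qc = list(n_read_pairs = nrow(pairs),
                 n_groups_initial = n_groups_initial,
                 n_groups_after_split = length(groups),
                 n_splits = length(groups) - n_groups_initial,
                 n_molecules = nrow(molecules),
                 n_rejected_single_strand = unname(rejected["single_strand"]),
                 n_rejected_all_reads_removed =
                   unname(rejected["all_reads_removed"])))
}

#' Genotype one consensus molecule at a panel target
#'
#' @param molecule A `consensus_molecule` (or one-row data.frame slice of the
#'   `molecules` table).
#' @param target One-row data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return `"supports_alt"`, `"supports_ref"`, or `"no_call"` (masked base or
#'   any third allele).
#' @export
genotype_molecule_at_target <- function(molecule, target) {
  if (molecule$chrom != target$chrom ||
      target$pos <= molecule$start || target$pos > molecule$end)
    stop("target ", target$chrom, ":", target$pos, " outside molecule span")
  base <- substr(molecule$sequence, target$pos - molecule$start,
                 target$pos - molecule$start)
  if (base == target$alt) "supports_alt"
  else if (base == target$ref) "supports_ref"
  else "no_call"
}

#' Tabulate per-target molecule observations from consensus molecules
#'
#' For each active-or-not panel target, counts the unique molecules spanning
#' the locus with a determinate base call (`ref` or `alt`; masked or
#' third-allele bases are no-calls and excluded from the molecule total), and
#' the subset supporting the alt allele.
#'
#' @param molecules data.frame from [call_consensus_molecules()].
#' @param panel A `bespoke_panel` (or its `targets` data.frame).
#' @return data.frame of target observations: `target_id`, `total_molecules`,
#'   `alt_molecules`, `noise_rate`, `active`.
#' @export
count_target_molecules <- function(molecules, panel) {
  targets <- if (inherits(panel, "bespoke_panel")) panel$targets else panel
  n <- nrow(targets)
  total <- integer(n); altn <- integer(n)
  for (i in seq_len(n)) {
    span <- molecules$chrom == targets$chrom[i] &
      molecules$start < targets$pos[i] & molecules$end >= targets$pos[i]
    if (!any(span)) next
    idx <- targets$pos[i] - molecules$start[span]
    base <- substr(molecules$sequence[span], idx, idx)
    total[i] <- sum(base == targets$ref[i] | base == targets$alt[i])
    altn[i] <- sum(base == targets$alt[i])
  }
  data.frame(target_id = targets$target_id,
             total_molecules = total,
             alt_molecules = altn,
             noise_rate = targets$error_rate,
             active = targets$active,
             stringsAsFactors = FALSE)
}
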