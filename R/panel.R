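#' Filter somatic SNV candidates for panel eligibility
#'
#' Retains candidate somatic SNVs that (i) pass the caller's filters, (ii)
#' have tumor allele frequency strictly above `af_threshold`, (iii) overlap no
#' exclusion interval (germline SNPs, CHIP regions, repeats, ...), and (iv)
#' sit in a sequence window whose GC fraction is below `gc_max`. Input order
#' is preserved, and the operation is idempotent.
#'
#' @param calls data.frame of SNV calls: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `tumor_af`, optionally `tumor_depth` and `passed_caller_filters`.
#' @param exclusions A `GRanges` from [exclusion_set()], or `NULL`.
#' @param reference A [Biostrings::DNAStringSet] (or path to a FASTA file)
#'   used for the GC-content filter.
#' @param af_threshold Minimum tumor allele frequency (exclusive), default 0.10.
#' @param gc_window_bp Width of the window, centred on the variant, over which
#'   GC content is computed. Default 121 bp (probe scale).
#' @param gc_max Variants whose window GC fraction is `>= gc_max` are
#'   excluded; default 0.80.
#' @return The retained subset of `calls`, original order preserved.
#' @export
filter_candidate_variants <- function(calls, exclusions = NULL, reference,
                                      af_threshold = 0.10,
                                      gc_window_bp = 121L, gc_max = 0.80) {
  validate_snv_calls(calls)
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  stopifnot(methods::is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))

  keep <- rep(TRUE, nrow(calls))
  if ("passed_caller_filters" %in% names(calls))
    keep <- keep & calls$passed_caller_filters
  keep <- keep & calls$tumor_af > af_threshold
  keep <- keep & !loci_overlap_any(calls$chrom, calls$pos, exclusions)

  missing_contig <- setdiff(unique(calls$chrom), names(reference))
  if (length(missing_contig))
    stop("contig(s) absent from reference: ", paste(missing_contig, collapse = ", "))
  gc <- window_gc_fraction(reference, calls$chrom, calls$pos, gc_window_bp)
  keep <- keep & gc < gc_max

  calls[keep, , drop = FALSE]
}

validate_snv_calls <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("chrom", "pos", "ref", "alt", "tumor_af") %in% names(calls)))
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(nchar(calls$ref) != 1L) || any(nchar(calls$alt) != 1L))
    stop("non-SNV record(s): ref and alt must be single bases")
  substitution_class(calls$ref, calls$alt)  # validates bases and ref != alt
  if (any(calls$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(calls$tumor_af < 0 | calls$tumor_af > 1))
    stop("tumor_af must lie in [0, 1]")
  invisible(calls)
}

# GC fraction of a window of gc_window_bp centred on each locus, clipped at
# contig ends; vectorized per contig via Biostrings views.
window_gc_fraction <- function(reference, chrom, pos, gc_window_bp = 121L) {
  half <- (gc_window_bp - 1L) %/% 2L
  gc <- numeric(length(pos))
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    subject <- reference[[ctg]]
    if (any(pos[i] > length(subject)))
      stop("locus beyond end of contig ", ctg)
    s <- pmax(1L, pos[i] - half)
    e <- pmin(length(subject), pos[i] + half)
    v <- Biostrings::Views(subject, start = s, end = e)
    gc[i] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
  }
  gc
}

#' Rank eligible variants by signal-to-noise and select panel targets
#'
#' Each eligible variant is scored by `rank_score = tumor_af / error_rate`,
#' where the error rate is the background rate of the variant's substitution
#' class: high tumor signal over low background noise ranks first. At most
#' `panel_cap` targets are returned, best first. Ties are broken by (lower
#' error rate, higher allele frequency, genomic coordinate), making the
#' selection deterministic.
#'
#' @param eligible data.frame of filtered SNV calls (see
#'   [filter_candidate_variants()]).
#' @param error_model A `substitution_error_model`.
#' @param panel_cap Maximum number of MRD targets, default 1800.
#' @return data.frame of panel targets: `target_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `tumor_af`, `error_rate`, `rank_score`, `active` (all `TRUE`).
#' @export
rank_and_select_targets <- function(eligible, error_model, panel_cap = 1800L) {
  stopifnot(inherits(error_model, "substitution_error_model"))
  validate_snv_calls(eligible)
  if (nrow(eligible) == 0) stop("no designable targets")
  e <- error_rate_for(error_model, eligible$ref, eligible$alt)
  score <- eligible$tumor_af / e
  ord <- order(-score, e, -eligible$tumor_af, eligible$chrom, eligible$pos)
  ord <- utils::head(ord, panel_cap)
  targets <- data.frame(
    target_id = paste0(eligible$chrom[ord], ":", eligible$pos[ord], ":",
                       eligible$ref[ord], ">", eligible$alt[ord]),
    chrom = eligible$chrom[ord],
    pos = eligible$pos[ord],
    ref = eligible$ref[ord],
    alt = eligible$alt[ord],
    tumor_af = eligible$tumor_af[ord],
    error_rate = e[ord],
    rank_score = score[ord],
    active = TRUE,
    stringsAsFactors = FALSE)
  rownames(targets) <- NULL
  targets
}

#' Select population SNVs for panel quality assurance
#'
#' Chooses `n` common population SNVs used to detect sample--panel mismatch or
#' contamination. Eligibility requires population frequency >= 0.20, passing
#' Hardy--Weinberg equilibrium, and lying outside the HLA region. Among
#' eligible SNVs, those with the most even representation across
#' subpopulations (smallest max-minus-min spread of subpopulation
#' frequencies) are chosen greedily; exact ties are broken by a seeded,
#' reproducible shuffle.
#'
#' @param catalog data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `population_frequency`, `hwe_pass`, and zero or more subpopulation
#'   frequency columns named `freq_*`.
#' @param hla_intervals `GRanges` of the HLA region (category `hla`), or `NULL`.
#' @param n Number of QA SNVs, default 43.
#' @param seed Integer seed for deterministic tie-breaking.
#' @param min_population_frequency Eligibility threshold, default 0.20.
#' @return data.frame of `n` selected QA SNVs with a `spread` column.
#' @export
select_qa_snvs <- function(catalog, hla_intervals = NULL, n = 43L, seed = 1L,
                           min_population_frequency = 0.20) {
  stopifnot(is.data.frame(catalog),
            all(c("chrom", "pos", "ref", "alt", "population_frequency",
                  "hwe_pass") %in% names(catalog)))
  elig <- catalog$population_frequency >= min_population_frequency &
    catalog$hwe_pass &
    !loci_overlap_any(catalog$chrom, catalog$pos, hla_intervals)
  pool <- catalog[elig, , drop = FALSE]
  if (nrow(pool) < n)
    stop("only ", nrow(pool), " eligible QA SNVs; ", n, " required (shortfall ",
         n - nrow(pool), ")")
  freq_cols <- grep("^freq_", names(pool), value = TRUE)
  spread <- if (length(freq_cols) >= 2) {
    fm <- as.matrix(pool[, freq_cols, drop = FALSE])
    apply(fm, 1L, max) - apply(fm, 1L, min)
  } else {
    rep(0, nrow(pool))
  }
  tie <- local({ set.seed(seed); sample.int(nrow(pool)) })
  ord <- utils::head(order(spread, tie), n)
  out <- pool[ord, , drop = FALSE]
  out$spread <- spread[ord]
  rownames(out) <- NULL
  out
}

#' Assemble a bespoke patient-specific MRD panel
#'
#' Runs the full design path: candidate filtering, signal-to-noise ranking and
#' capped selection, QA SNV selection, and an analytic predicted 95% limit of
#' detection under an assumed per-target unique-molecule yield.
#'
#' @inheritParams filter_candidate_variants
#' @inheritParams rank_and_select_targets
#' @param catalog Population SNP catalog for QA selection (see
#'   [select_qa_snvs()]); `NULL` to omit QA SNVs.
#' @param patient_id Opaque patient identifier.
#' @param n_qa Number of QA SNVs (default 43).
#' @param seed Seed for deterministic QA tie-breaking.
#' @param assumed_yield Assumed unique molecules per target used for the
#'   predicted LOD (default 1666, i.e. ~3e6 molecules on a full panel).
#' @return An object of class `bespoke_panel`.
#' @export
design_panel <- function(calls, exclusions = NULL, reference, error_model,
                         catalog = NULL, patient_id = "patient",
                         af_threshold = 0.10, panel_cap = 1800L, n_qa = 43L,
                         seed = 1L, assumed_yield = 1666) {
  eligible <- filter_candidate_variants(calls, exclusions, reference,
                                        af_threshold = af_threshold)
  targets <- rank_and_select_targets(eligible, error_model, panel_cap)
  qa <- NULL
  if (!is.null(catalog)) {
    hla <- if (!is.null(exclusions) && length(exclusions)) {
      exclusions[S4Vectors::mcols(exclusions)$category == "hla"]
    } else NULL
    qa <- select_qa_snvs(catalog, hla, n = n_qa, seed = seed)
  }
  panel <- structure(list(patient_id = patient_id,
                          targets = targets,
                          qa_snvs = qa,
                          predicted_lod_ppm = NA_real_,
                          panel_cap = as.integer(panel_cap),
                          seed = as.integer(seed)),
                     class = "bespoke_panel")
  lambda <- sum(targets$error_rate) * assumed_yield
  lod <- predict_panel_lod(assumed_M = assumed_yield * nrow(targets),
                           assumed_lambda = lambda)
  panel$predicted_lod_ppm <- lod$lod95_ppm
  panel
}

#' Deactivate panel targets showing background signal in a healthy screen
#'
#' After panel manufacture, the panel is used to sequence plasma from an
#' unrelated healthy donor; any MRD target at which any non-reference signal
#' is observed is deactivated in the logical panel design (the target stays
#' in the panel but contributes nothing downstream).
#'
#' @param panel A `bespoke_panel`.
#' @param screen data.frame with `target_id` and `alt_molecules` covering
#'   every panel target (count may be 0).
#' @return The panel with `active = FALSE` on flagged targets.
#' @export
qualify_panel_against_background <- function(panel, screen) {
  stopifnot(inherits(panel, "bespoke_panel"), is.data.frame(screen),
            all(c("target_id", "alt_molecules") %in% names(screen)))
  missing <- setdiff(panel$targets$target_id, screen$target_id)
  if (length(missing))
    stop("screen is missing ", length(missing), " panel target(s), e.g. ",
         missing[1])
  counts <- screen$alt_molecules[match(panel$targets$target_id,
                                       screen$target_id)]
  panel$targets$active <- panel$targets$active & counts < 1
  panel
}

#' @export
print.bespoke_panel <- function(x, ...) {
  cat("Bespoke MRD panel for ", x$patient_id, "\n",
      "  targets: ", nrow(x$targets), " (", sum(x$targets$active),
      " active; cap ", x$panel_cap, ")\n",
      "  QA SNVs: ", if (is.null(x$qa_snvs)) 0L else nrow(x$qa_snvs), "\n",
      "  predicted 95% LOD: ", signif(x$predicted_lod_ppm, 3), " ppm\n",
      sep = "")
  invisible(x)
}
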