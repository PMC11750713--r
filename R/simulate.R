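#' Background substitution-rate presets
#'
#' Two per-unique-molecule noise scales bracket the assay: `raw_class_rates()`
#' is the pre-selection background substitution scale (~5e-6 mean; transitions
#' noisier than transversions), representative of what a whole cohort of
#' healthy plasma shows per substitution class before target-level
#' prioritisation. `duplex_class_rates()` is the duplex-consensus-suppressed
#' noise floor (~1.5e-7 mean) that the lowest-noise selected targets attain;
#' at ~3e6 molecules across a full panel it yields an aggregate noise mean
#' near 0.5 and ppm-scale limits of detection.
#'
#' @return Named numeric vector over the 12 substitution classes.
#' @export
raw_class_rates <- function() {
  cls <- substitution_classes()
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  r <- ifelse(cls %in% transitions, 8e-6, 3e-6)
  names(r) <- cls
  r
}

#' @rdname raw_class_rates
#' @export
duplex_class_rates <- function() {
  cls <- substitution_classes()
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  r <- ifelse(cls %in% transitions, 3e-7, 1e-7)
  names(r) <- cls
  r
}

#' Simulate a small random reference genome
#'
#' @param n_chrom Number of contigs.
#' @param chrom_length Length of each contig (bp).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @export
simulate_reference <- function(n_chrom = 1L, chrom_length = 100000L, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = ""), character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("chr", seq_len(n_chrom))
  ref
}

#' Simulate matched tumor/normal somatic SNV calls and exclusion intervals
#'
#' Generates `n_variants` somatic SNVs on the reference with allele
#' frequencies drawn from a Beta distribution, places a stated fraction of
#' them inside generated exclusion intervals, and attaches truth labels
#' (`in_exclusion`) so panel-design filtering can be checked against ground
#' truth.
#'
#' @param reference `DNAStringSet` from [simulate_reference()].
#' @param n_variants Number of SNV calls (>= 1).
#' @param af_shape1,af_shape2 Beta parameters of the tumor allele-frequency
#'   distribution (default Beta(5, 5), centred on clonal-ish 0.5 AF).
#' @param exclusion_fraction Fraction of variants covered by an exclusion
#'   interval, in [0, 1].
#' @param min_spacing Minimum distance (bp) between variant loci (default
#'   200, larger than a cfDNA fragment, so each fragment spans one target as
#'   in a genome-wide sparse panel; requires enough reference sequence).
#' @param seed Integer seed.
#' @return List with `calls` (SNV data.frame with `in_exclusion` truth
#'   label), `exclusions` (0-based half-open interval data.frame), and
#'   `exclusion_granges`.
#' @export
simulate_tumor_normal_variants <- function(reference, n_variants = 2000L,
                                           af_shape1 = 5, af_shape2 = 5,
                                           exclusion_fraction = 0.10,
                                           min_spacing = 200L,
                                           seed = 1L) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (af_shape1 <= 0 || af_shape2 <= 0) stop("Beta shape parameters must be > 0")
  if (exclusion_fraction < 0 || exclusion_fraction > 1)
    stop("exclusion_fraction must lie in [0, 1]")
  set.seed(seed)
  chroms <- names(reference)
  lens <- Biostrings::width(reference)
  loci <- sample_spaced_loci(chroms, lens, n_variants, min_spacing)
  chrom <- loci$chrom
  pos <- loci$pos
  ref_base <- substring_bases(reference, chrom, pos)
  alt_base <- vapply(ref_base, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1), USE.NAMES = FALSE)
  calls <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = ref_base, alt = alt_base,
                      tumor_af = stats::rbeta(n_variants, af_shape1, af_shape2),
                      tumor_depth = stats::rpois(n_variants, 60) + 10L,
                      passed_caller_filters = TRUE,
                      stringsAsFactors = FALSE)
  n_excl <- round(exclusion_fraction * n_variants)
  in_excl <- rep(FALSE, n_variants)
  categories <- c("germline_snp", "chip_region", "polymorphic",
                  "mapping_difficulty", "systematic_bias",
                  "short_tandem_repeat", "low_complexity")
  if (n_excl > 0) {
    idx <- sample.int(n_variants, n_excl)
    in_excl[idx] <- TRUE
    excl <- data.frame(chrom = chrom[idx],
                       start = pmax(0L, as.integer(pos[idx]) - 26L),
                       end = as.integer(pos[idx]) + 25L,
                       category = sample(categories, n_excl, replace = TRUE),
                       stringsAsFactors = FALSE)
  } else {
    excl <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), category = character(0),
                       stringsAsFactors = FALSE)
  }
  calls$in_exclusion <- in_excl
  list(calls = calls, exclusions = excl,
       exclusion_granges = exclusion_set(excl))
}

# distinct loci with pairwise spacing >= min_spacing, clear of contig ends;
# greedy thinning of uniform draws, topped up until the count is met
sample_spaced_loci <- function(chroms, lens, n, min_spacing,
                               margin = 200L, max_iter = 60L) {
  chrom <- character(0); pos <- integer(0)
  for (iter in seq_len(max_iter)) {
    need <- n - length(pos)
    if (need <= 0) break
    new_chrom <- sample(chroms, 3L * need + 10L, replace = TRUE,
                        prob = lens / sum(lens))
    new_pos <- vapply(new_chrom, function(ctg)
      sample.int(lens[match(ctg, chroms)] - 2L * margin, 1L) + margin,
      integer(1), USE.NAMES = FALSE)
    chrom <- c(chrom, new_chrom); pos <- c(pos, new_pos)
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    keep <- rep(TRUE, length(pos))
    last_pos <- -Inf; last_chrom <- ""
    for (i in seq_along(pos)) {
      if (chrom[i] == last_chrom && pos[i] - last_pos < min_spacing) {
        keep[i] <- FALSE
      } else {
        last_pos <- pos[i]; last_chrom <- chrom[i]
      }
    }
    chrom <- chrom[keep]; pos <- pos[keep]
    if (length(pos) > n) {
      sel <- sort(sample.int(length(pos), n))
      chrom <- chrom[sel]; pos <- pos[sel]
    }
  }
  if (length(pos) < n)
    stop("could not place ", n, " loci at >= ", min_spacing,
         " bp spacing on this reference; use a longer reference or a ",
         "smaller min_spacing")
  sh <- sample.int(n)  # decouple row order from genomic order
  list(chrom = chrom[sh], pos = as.integer(pos[sh]))
}

substring_bases <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    out[i] <- as.character(Biostrings::extractAt(
      reference[[ctg]], IRanges::IRanges(pos[i], width = 1L)))
  }
  out
}

#' Simulate a population SNP catalog for QA selection
#'
#' @param reference `DNAStringSet`.
#' @param n_snvs Catalog size.
#' @param subpopulations Subpopulation labels for per-subpopulation
#'   frequencies.
#' @param seed Integer seed.
#' @return data.frame catalog suitable for [select_qa_snvs()].
#' @export
simulate_snp_catalog <- function(reference, n_snvs = 300L,
                                 subpopulations = c("afr", "amr", "eas",
                                                    "eur", "sas"),
                                 seed = 1L) {
  set.seed(seed)
  chroms <- names(reference)
  lens <- Biostrings::width(reference)
  chrom <- sample(chroms, n_snvs, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(chrom, function(ctg)
    sample.int(lens[match(ctg, chroms)] - 400L, 1L) + 200L, integer(1))
  ref_base <- substring_bases(reference, chrom, pos)
  alt_base <- vapply(ref_base, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  popf <- stats::runif(n_snvs, 0.05, 0.5)
  cat <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref_base,
                    alt = alt_base, population_frequency = popf,
                    hwe_pass = stats::runif(n_snvs) > 0.05,
                    stringsAsFactors = FALSE)
  for (sp in subpopulations) {
    jitter <- stats::rnorm(n_snvs, 0, 0.04)
    cat[[paste0("freq_", sp)]] <- pmin(pmax(popf + jitter, 0.01), 0.99)
  }
  cat
}

#' Simulate a healthy-plasma background cohort
#'
#' Per sample and substitution class, draws the alt-supporting molecule count
#' as Binomial(`molecules_per_sample`, class rate); the result feeds
#' [estimate_substitution_error_model()].
#'
#' @param n_samples Cohort size (the assay's background model uses > 200
#'   healthy plasma samples; default 200).
#' @param true_class_rates Named per-class rates in (0, 1e-3].
#' @param molecules_per_sample Unique molecules observed per class per
#'   sample.
#' @param seed Integer seed.
#' @return data.frame with `sample`, `class`, `alt_molecules`,
#'   `total_molecules`.
#' @export
simulate_background_cohort <- function(n_samples = 200L,
                                       true_class_rates = raw_class_rates(),
                                       molecules_per_sample = 1e6,
                                       seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (any(true_class_rates <= 0) || any(true_class_rates > 1e-3))
    stop("true_class_rates must lie in (0, 1e-3]")
  cls <- substitution_classes()
  if (!all(cls %in% names(true_class_rates)))
    stop("true_class_rates must cover all 12 substitution classes")
  set.seed(seed)
  grid <- expand.grid(sample = paste0("bg", seq_len(n_samples)), class = cls,
                      stringsAsFactors = FALSE)
  grid$total_molecules <- molecules_per_sample
  grid$alt_molecules <- stats::rbinom(nrow(grid), size = molecules_per_sample,
                                      prob = true_class_rates[grid$class])
  grid[order(grid$sample, grid$class), c("sample", "class", "alt_molecules",
                                         "total_molecules")]
}

#' Define the data-generating truth for a simulated plasma sample
#'
#' @param tumor_fraction Tumor fraction `f` in [0, 1] (ppm / 1e6).
#' @param mean_molecules_per_target Poisson mean of the unique-molecule yield
#'   per target (default 1666, ~3e6 molecules on a 1,800-target panel).
#' @param family_mean Mean reads per strand per molecule (default 2;
#'   per-strand counts are Poisson, zero-truncated on the pair total, so
#'   single-strand families occur and exercise duplex rejection).
#' @param min_reads_per_strand Force at least this many reads on each strand
#'   (0 keeps the stochastic family model; 2 guarantees duplex families).
#' @param seq_error_rate Per-base sequencing error probability (default 1e-3).
#' @param q_high,q_low,q_low_frac Phred quality profile: each base gets
#'   `q_low` with probability `q_low_frac`, else `q_high`.
#' @param fragment_length cfDNA fragment length in bp (default 166,
#'   mononucleosomal).
#' @param distinct_fragments Draw per-target fragment offsets without
#'   replacement so no two molecules of a target share coordinates (default
#'   `FALSE`: offsets are uniform with replacement, so positional collisions
#'   occur as in real cfDNA and merge under positional consensus). Requires
#'   the per-target yield not to exceed `fragment_length`.
#' @param seed Integer seed.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(tumor_fraction = 0,
                             mean_molecules_per_target = 1666,
                             family_mean = 2,
                             min_reads_per_strand = 0L,
                             seq_error_rate = 1e-3,
                             q_high = 37L, q_low = 20L, q_low_frac = 0.05,
                             fragment_length = 166L,
                             distinct_fragments = FALSE,
                             seed = 1L) {
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  if (mean_molecules_per_target <= 0) stop("molecule yield must be > 0")
  structure(list(tumor_fraction = tumor_fraction,
                 mean_molecules_per_target = mean_molecules_per_target,
                 family_mean = family_mean,
                 min_reads_per_strand = as.integer(min_reads_per_strand),
                 seq_error_rate = seq_error_rate,
                 q_high = as.integer(q_high), q_low = as.integer(q_low),
                 q_low_frac = q_low_frac,
                 fragment_length = as.integer(fragment_length),
                 distinct_fragments = isTRUE(distinct_fragments),
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate duplex cfDNA read families over a bespoke panel
#'
#' For each panel target, the unique-molecule count is Poisson with the
#' configured yield; each molecule is tumor-derived (alt-bearing) with
#' probability `f`, or otherwise carries the target's alt allele as a
#' background error with the target's per-molecule error rate. Each molecule
#' spans the target at a uniformly drawn offset within a fixed fragment
#' length and emits a duplex read family (per-strand Poisson counts,
#' zero-truncated on the total); per-base sequencing errors and Phred
#' qualities are injected per the truth's quality profile.
#'
#' @param panel A `bespoke_panel`.
#' @param truth A `simulation_truth`.
#' @param reference `DNAStringSet` the panel was designed on.
#' @return List with `pairs` (aligned read-pair data.frame for
#'   [call_consensus_molecules()]) and `truth_table` (per-target
#'   `n_molecules`, `n_alt_molecules`, of which `n_tumor_molecules`).
#' @export
simulate_plasma_sample <- function(panel, truth, reference) {
  stopifnot(inherits(panel, "bespoke_panel"), inherits(truth, "simulation_truth"))
  targets <- panel$targets
  if (nrow(targets) == 0) stop("empty panel")
  set.seed(truth$seed)
  L <- truth$fragment_length
  f <- truth$tumor_fraction

  n_mol <- stats::rpois(nrow(targets), truth$mean_molecules_per_target)
  tgt_idx <- rep(seq_len(nrow(targets)), n_mol)
  n_total <- length(tgt_idx)
  if (n_total == 0)
    stop("no molecules simulated; increase the yield")

  is_tumor <- stats::runif(n_total) < f
  is_bg_alt <- !is_tumor &
    stats::runif(n_total) < targets$error_rate[tgt_idx]
  is_alt <- is_tumor | is_bg_alt

  chrom <- targets$chrom[tgt_idx]
  pos <- targets$pos[tgt_idx]
  clens <- Biostrings::width(reference)[match(chrom, names(reference))]
  # fragment must span the target: start0 = pos - offset, offset in 1..L
  if (isTRUE(truth$distinct_fragments)) {
    if (any(n_mol > L))
      stop("distinct_fragments requires per-target yields <= fragment_length")
    offset <- unlist(lapply(n_mol, function(n) sample.int(L, n)),
                     use.names = FALSE)
  } else {
    offset <- sample.int(L, n_total, replace = TRUE)
  }
  start0 <- pos - offset
  start0 <- pmax(0L, pmin(start0, clens - L))
  end0 <- start0 + L

  # molecule sequences from the reference, alt base substituted where alt
  mol_seq <- character(n_total)
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    mol_seq[i] <- as.character(Biostrings::extractAt(
      reference[[ctg]], IRanges::IRanges(start0[i] + 1L, width = L)))
  }
  off <- pos - start0  # 1-based offset of the target within the fragment
  for (i in which(is_alt))
    substr(mol_seq[i], off[i], off[i]) <- targets$alt[tgt_idx[i]]

  # duplex family sizes
  n_top <- stats::rpois(n_total, truth$family_mean)
  n_bot <- stats::rpois(n_total, truth$family_mean)
  if (truth$min_reads_per_strand > 0L) {
    n_top <- pmax(n_top, truth$min_reads_per_strand)
    n_bot <- pmax(n_bot, truth$min_reads_per_strand)
  } else {
    empty <- which(n_top + n_bot == 0L)
    while (length(empty)) {  # zero-truncate the pair total
      n_top[empty] <- stats::rpois(length(empty), truth$family_mean)
      n_bot[empty] <- stats::rpois(length(empty), truth$family_mean)
      empty <- empty[n_top[empty] + n_bot[empty] == 0L]
    }
  }

  n_reads <- n_top + n_bot
  read_mol <- rep(seq_len(n_total), n_reads)
  strand <- unlist(mapply(function(t, b) c(rep("top", t), rep("bottom", b)),
                          n_top, n_bot, SIMPLIFY = FALSE), use.names = FALSE)
  bases <- mol_seq[read_mol]
  total_reads <- length(bases)

  # sequencing errors: per-read error counts, positions resampled per read
  n_err <- stats::rbinom(total_reads, L, truth$seq_error_rate)
  for (i in which(n_err > 0)) {
    raw <- charToRaw(bases[i])
    at <- sample.int(L, n_err[i])
    for (p in at) {
      cur <- rawToChar(raw[p])
      raw[p] <- charToRaw(sample(setdiff(c("A", "C", "G", "T"), cur), 1L))
    }
    bases[i] <- rawToChar(raw)
  }

  # quality strings: q_high background with q_low dropped in at q_low_frac
  hi <- intToUtf8(truth$q_high + 33L)
  lo_chr <- charToRaw(intToUtf8(truth$q_low + 33L))
  quals <- rep(strrep(hi, L), total_reads)
  n_lo <- stats::rbinom(total_reads, L, truth$q_low_frac)
  for (i in which(n_lo > 0)) {
    raw <- charToRaw(quals[i])
    raw[sample.int(L, n_lo[i])] <- lo_chr
    quals[i] <- rawToChar(raw)
  }

  pairs <- data.frame(chrom = chrom[read_mol],
                      start = start0[read_mol],
                      end = end0[read_mol],
                      strand_tag = strand,
                      bases = bases,
                      quals = quals,
                      read_id = sprintf("m%06d_r%02d", read_mol,
                                        sequence_lengths(n_reads)),
                      stringsAsFactors = FALSE)

  truth_table <- data.frame(
    target_id = targets$target_id,
    n_molecules = n_mol,
    n_alt_molecules = as.integer(tapply(is_alt, factor(tgt_idx,
      levels = seq_len(nrow(targets))), sum, default = 0L)),
    n_tumor_molecules = as.integer(tapply(is_tumor, factor(tgt_idx,
      levels = seq_len(nrow(targets))), sum, default = 0L)),
    stringsAsFactors = FALSE)
  truth_table$n_alt_molecules[is.na(truth_table$n_alt_molecules)] <- 0L
  truth_table$n_tumor_molecules[is.na(truth_table$n_tumor_molecules)] <- 0L

  list(pairs = pairs, truth_table = truth_table)
}

# 1..n1, 1..n2, ... for read numbering within molecules
sequence_lengths <- function(ns) {
  unlist(lapply(ns, seq_len), use.names = FALSE)
}

#' Simulate per-target molecule observations directly (fast path)
#'
#' Skips read-level simulation: per target, the molecule total is Poisson
#' with the configured yield and the alt-supporting count is Binomial with
#' success probability `f + (1 - f) * e_t` (a tumor molecule with
#' probability `f`, else a background error with the target's rate). This is
#' the post-consensus observation model and is exact for detection-level
#' studies (specificity, LOD, spike-in recovery) at full assay scale.
#'
#' @param panel A `bespoke_panel`.
#' @param tumor_fraction `f` in [0, 1].
#' @param mean_molecules_per_target Poisson yield per target.
#' @param seed Optional integer seed (`NULL` leaves the RNG stream alone).
#' @return data.frame of target observations for [detect_ctdna()].
#' @export
simulate_target_observations <- function(panel, tumor_fraction = 0,
                                         mean_molecules_per_target = 1666,
                                         seed = NULL) {
  stopifnot(inherits(panel, "bespoke_panel"))
  targets <- panel$targets
  if (nrow(targets) == 0) stop("empty panel")
  if (!is.null(seed)) set.seed(seed)
  M_t <- stats::rpois(nrow(targets), mean_molecules_per_target)
  p_alt <- tumor_fraction + (1 - tumor_fraction) * targets$error_rate
  k_t <- stats::rbinom(nrow(targets), M_t, p_alt)
  data.frame(target_id = targets$target_id,
             total_molecules = M_t,
             alt_molecules = k_t,
             noise_rate = targets$error_rate,
             active = targets$active,
             stringsAsFactors = FALSE)
}

#' Run the simulate -> consensus -> detect pipeline end to end
#'
#' @param panel A `bespoke_panel`.
#' @param truth A `simulation_truth`.
#' @param reference `DNAStringSet`.
#' @param p_threshold Detection threshold.
#' @param plasma_volume_ml Optional plasma volume for molecules/ml.
#' @param split Apply consensus-group splitting (default `TRUE`).
#' @return List with `result` (a `sample_detection_result`), `observations`,
#'   `truth_table`, `qc`, and `true_ppm` (the spiked tumor fraction in ppm).
#' @export
run_end_to_end <- function(panel, truth, reference, p_threshold = 0.001,
                           plasma_volume_ml = NULL, split = TRUE) {
  sim <- simulate_plasma_sample(panel, truth, reference)
  cons <- call_consensus_molecules(sim$pairs, reference = reference,
                                   split = split)
  obs <- count_target_molecules(cons$molecules, panel)
  result <- detect_ctdna(obs, p_threshold = p_threshold,
                         plasma_volume_ml = plasma_volume_ml)
  list(result = result,
       observations = obs,
       truth_table = sim$truth_table,
       qc = cons$qc,
       true_ppm = truth$tumor_fraction * 1e6)
}
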