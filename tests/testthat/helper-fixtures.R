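# Shared in-code fixtures: tiny references, flat error models, hand-built
# read pairs and panels. Everything is generated, nothing is stored.

tiny_reference <- function(seed = 42L, n_chrom = 1L, chrom_length = 20000L) {
  simulate_reference(n_chrom = n_chrom, chrom_length = chrom_length,
                     seed = seed)
}

# error model with exact, fully controlled per-class rates
exact_error_model <- function(rates = NULL, rate_floor = 1e-8) {
  cls <- substitution_classes()
  if (is.null(rates)) rates <- stats::setNames(rep(1e-6, 12), cls)
  denom <- 1e9
  obs <- data.frame(class = cls,
                    alt_molecules = round(rates[cls] * denom),
                    total_molecules = denom)
  estimate_substitution_error_model(obs, rate_floor = rate_floor)
}

# one aligned read pair (fragment observation); default all-Q37 qualities
make_pair <- function(chrom, start, bases, strand = "top", quals = NULL,
                      read_id = "r1") {
  if (is.null(quals)) quals <- strrep(intToUtf8(37 + 33), nchar(bases))
  data.frame(chrom = chrom, start = start, end = start + nchar(bases),
             strand_tag = strand, bases = bases, quals = quals,
             read_id = read_id, stringsAsFactors = FALSE)
}

phred_string <- function(quals) intToUtf8(quals + 33, multiple = FALSE)

# targets data.frame at given loci with a uniform error rate
make_targets <- function(chrom, pos, ref, alt, tumor_af = 0.5,
                         error_rate = 1e-6, active = TRUE) {
  data.frame(target_id = paste0(chrom, ":", pos, ":", ref, ">", alt),
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             tumor_af = tumor_af, error_rate = error_rate,
             rank_score = tumor_af / error_rate, active = active,
             stringsAsFactors = FALSE)
}

make_panel <- function(targets, qa_snvs = NULL, patient_id = "test",
                       panel_cap = 1800L, seed = 1L) {
  structure(list(patient_id = patient_id, targets = targets,
                 qa_snvs = qa_snvs, predicted_lod_ppm = NA_real_,
                 panel_cap = as.integer(panel_cap), seed = as.integer(seed)),
            class = "bespoke_panel")
}

# base at a 1-based position of a DNAStringSet contig
ref_base_at <- function(reference, chrom, pos) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
}

# an alt base differing from the reference base at a locus
alt_base_at <- function(reference, chrom, pos) {
  setdiff(c("A", "C", "G", "T"), ref_base_at(reference, chrom, pos))[1]
}
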