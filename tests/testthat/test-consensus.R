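# Reads here are built by hand over a fixed tiny reference so every masking,
# divergence, agreement and strand rule can be asserted base by base.

cons_ref <- function() {
  out <- Biostrings::DNAStringSet(paste(rep("ACGT", 300), collapse = ""))
  names(out) <- "chr1"
  out
}

ref_frag <- function(start0, len, reference = cons_ref()) {
  as.character(Biostrings::subseq(reference[[1]], start0 + 1, start0 + len))
}

test_that("read pairs group exactly by paired fragment coordinates", {
  frag <- ref_frag(100, 20)
  pairs <- rbind(make_pair("chr1", 100L, frag, "top", read_id = "a"),
                 make_pair("chr1", 100L, frag, "bottom", read_id = "b"),
                 make_pair("chr1", 101L, ref_frag(101, 20), "top",
                           read_id = "c"))
  groups <- group_read_pairs_by_position(pairs)
  expect_length(groups, 2L)
  expect_identical(unname(vapply(groups, nrow, integer(1)) >= 1L), c(TRUE, TRUE))
  expect_identical(sum(vapply(groups, nrow, integer(1))), 3L)
  expect_length(group_read_pairs_by_position(pairs[0, ]), 0L)
  bad <- make_pair("chr1", 10L, "ACGT")
  bad$end <- 10L
  expect_error(group_read_pairs_by_position(bad), "coordinates")
})

test_that("groups split only on subset alleles seen in enough other groups", {
  reference <- cons_ref()
  frag <- ref_frag(100, 20)
  alt_frag <- frag
  substr(alt_frag, 5, 5) <- alt_base_at(reference, "chr1", 105)

  six <- do.call(rbind, lapply(1:6, function(i)
    make_pair("chr1", 100L, if (i <= 3) alt_frag else frag,
              if (i %% 2) "top" else "bottom", read_id = paste0("r", i))))
  other <- function(start0, carry) {
    f <- ref_frag(start0, 30)
    if (carry) substr(f, 105 - start0, 105 - start0) <-
        alt_base_at(reference, "chr1", 105)
    make_pair("chr1", start0, f, "top", read_id = paste0("o", start0))
  }

  # allele in 2 other groups: the group of six splits 3 + 3
  g <- group_read_pairs_by_position(rbind(six, other(90L, TRUE),
                                          other(95L, TRUE)))
  s <- split_groups_on_shared_alleles(g, reference)
  sizes <- unname(sort(vapply(s, nrow, integer(1))))
  expect_identical(sizes, c(1L, 1L, 3L, 3L))
  # read conservation
  expect_identical(sum(vapply(s, nrow, integer(1))),
                   sum(vapply(g, nrow, integer(1))))

  # allele in only 1 other group: no split
  g1 <- group_read_pairs_by_position(rbind(six, other(90L, TRUE),
                                           other(95L, FALSE)))
  s1 <- split_groups_on_shared_alleles(g1, reference)
  expect_identical(unname(sort(vapply(s1, nrow, integer(1)))), c(1L, 1L, 6L))

  # allele carried by every read (not a strict subset): no split
  all6 <- do.call(rbind, lapply(1:6, function(i)
    make_pair("chr1", 100L, alt_frag, if (i %% 2) "top" else "bottom",
              read_id = paste0("r", i))))
  g2 <- group_read_pairs_by_position(rbind(all6, other(90L, TRUE),
                                           other(95L, TRUE)))
  s2 <- split_groups_on_shared_alleles(g2, reference)
  expect_identical(unname(sort(vapply(s2, nrow, integer(1)))), c(1L, 1L, 6L))
})

test_that("duplex consensus applies mask, removal, divergence and strand rules", {
  frag <- ref_frag(200, 40)

  # clean duplex pair: a molecule with both strands and no masks
  g <- group_read_pairs_by_position(
    rbind(make_pair("chr1", 200L, frag, "top", read_id = "t"),
          make_pair("chr1", 200L, frag, "bottom", read_id = "b")))[[1]]
  m <- build_consensus_molecule(g)
  expect_s3_class(m, "consensus_molecule")
  expect_identical(m$sequence, frag)
  expect_identical(c(m$n_top, m$n_bottom), c(1L, 1L))

  # all surviving reads on one strand: duplex rejection
  g1 <- group_read_pairs_by_position(
    do.call(rbind, lapply(1:3, function(i)
      make_pair("chr1", 200L, frag, "top", read_id = paste0("t", i)))))[[1]]
  r <- build_consensus_molecule(g1)
  expect_s3_class(r, "consensus_rejection")
  expect_identical(r$reason, "single_strand")

  # a read diverging >2.5% from the provisional consensus is excluded:
  # 2 of 40 bases (5%) differ on the third read
  div <- frag
  substr(div, 10, 10) <- setdiff(c("A","C","G","T"), substr(frag,10,10))[1]
  substr(div, 20, 20) <- setdiff(c("A","C","G","T"), substr(frag,20,20))[1]
  g2 <- group_read_pairs_by_position(
    rbind(make_pair("chr1", 200L, frag, "top", read_id = "t1"),
          make_pair("chr1", 200L, frag, "top", read_id = "t2"),
          make_pair("chr1", 200L, frag, "bottom", read_id = "b1"),
          make_pair("chr1", 200L, div, "bottom", read_id = "b2")))[[1]]
  m2 <- build_consensus_molecule(g2)
  expect_identical(m2$n_members, 3L)   # divergent read dropped
  expect_identical(m2$sequence, frag)  # and leaves no trace in the consensus

  # 5 of 6 unmasked bases agreeing (83%) is below 90%: position masked.
  # One read dissents at base 30; 1/40 = 2.5% divergence is tolerated.
  one <- frag
  substr(one, 30, 30) <- setdiff(c("A","C","G","T"), substr(frag,30,30))[1]
  g3 <- group_read_pairs_by_position(do.call(rbind, lapply(1:6, function(i)
    make_pair("chr1", 200L, if (i == 1) one else frag,
              if (i <= 3) "top" else "bottom",
              read_id = paste0("r", i)))))[[1]]
  m3 <- build_consensus_molecule(g3)
  expect_identical(substr(m3$sequence, 30, 30), "N")
  expect_identical(m3$n_members, 6L)

  # a read with >20% of bases below Q29 is removed before consensus
  lowq <- phred_string(c(rep(10L, 9L), rep(37L, 31L)))  # 22.5% masked
  g4 <- group_read_pairs_by_position(
    rbind(make_pair("chr1", 200L, frag, "top", read_id = "t1"),
          make_pair("chr1", 200L, frag, "bottom", read_id = "b1"),
          make_pair("chr1", 200L, frag, "bottom", quals = lowq,
                    read_id = "b2")))[[1]]
  m4 <- build_consensus_molecule(g4)
  expect_identical(m4$n_members, 2L)

  # bases under Q29 are masked: a single masked position becomes N when no
  # other read covers it unmasked
  q1 <- phred_string(c(28L, rep(37L, 39L)))
  g5 <- group_read_pairs_by_position(
    rbind(make_pair("chr1", 200L, frag, "top", quals = q1, read_id = "t1"),
          make_pair("chr1", 200L, frag, "bottom", quals = q1,
                    read_id = "b1")))[[1]]
  m5 <- build_consensus_molecule(g5)
  expect_identical(substr(m5$sequence, 1, 1), "N")
  expect_identical(substr(m5$sequence, 2, 40), substr(frag, 2, 40))

  expect_error(build_consensus_molecule(g5[0, ]), "empty")
})

test_that("molecule genotyping distinguishes alt, ref and no-call", {
  reference <- cons_ref()
  frag <- ref_frag(100, 20)
  target <- data.frame(chrom = "chr1", pos = 105L,
                       ref = ref_base_at(reference, "chr1", 105),
                       alt = alt_base_at(reference, "chr1", 105))
  mol <- list(chrom = "chr1", start = 100L, end = 120L, sequence = frag)
  expect_identical(genotype_molecule_at_target(mol, target), "supports_ref")
  alt_seq <- frag; substr(alt_seq, 5, 5) <- target$alt
  expect_identical(genotype_molecule_at_target(
    modifyList(mol, list(sequence = alt_seq)), target), "supports_alt")
  n_seq <- frag; substr(n_seq, 5, 5) <- "N"
  expect_identical(genotype_molecule_at_target(
    modifyList(mol, list(sequence = n_seq)), target), "no_call")
  expect_error(genotype_molecule_at_target(
    mol, data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "C")),
    "outside")
})

test_that("consensus output is independent of read order and conserves counts", {
  ref <- tiny_reference(seed = 33L, chrom_length = 40000L)
  sim <- simulate_tumor_normal_variants(ref, n_variants = 60L,
                                        exclusion_fraction = 0, seed = 5L)
  model <- exact_error_model(raw_class_rates())
  eligible <- filter_candidate_variants(sim$calls, NULL, ref)
  panel <- make_panel(rank_and_select_targets(eligible, model, 40L))
  truth <- simulation_truth(tumor_fraction = 0.001,
                            mean_molecules_per_target = 12,
                            seq_error_rate = 1e-3, seed = 8L)
  s <- simulate_plasma_sample(panel, truth, ref)

  out1 <- call_consensus_molecules(s$pairs, ref)
  set.seed(99)
  shuffled <- s$pairs[sample.int(nrow(s$pairs)), ]
  out2 <- call_consensus_molecules(shuffled, ref)
  key <- function(m) do.call(order, m[c("chrom", "start", "end", "sequence")])
  m1 <- out1$molecules[key(out1$molecules), ]; rownames(m1) <- NULL
  m2 <- out2$molecules[key(out2$molecules), ]; rownames(m2) <- NULL
  expect_identical(m1, m2)

  # molecule count <= group count <= read-pair count
  expect_lte(out1$qc$n_molecules, out1$qc$n_groups_after_split)
  expect_lte(out1$qc$n_groups_initial, out1$qc$n_read_pairs)
  # every emitted molecule satisfies the duplex requirement
  expect_true(all(out1$molecules$n_top >= 1L & out1$molecules$n_bottom >= 1L))
})

test_that("consensus is idempotent on its own molecules", {
  ref <- tiny_reference(seed = 34L, chrom_length = 40000L)
  sim <- simulate_tumor_normal_variants(ref, n_variants = 40L,
                                        exclusion_fraction = 0, seed = 6L)
  model <- exact_error_model(raw_class_rates())
  panel <- make_panel(rank_and_select_targets(
    filter_candidate_variants(sim$calls, NULL, ref), model, 25L))
  truth <- simulation_truth(tumor_fraction = 0, mean_molecules_per_target = 8,
                            seq_error_rate = 1e-3, seed = 9L)
  s <- simulate_plasma_sample(panel, truth, ref)
  mols <- call_consensus_molecules(s$pairs, ref)$molecules
  mols <- mols[!grepl("N", mols$sequence, fixed = TRUE) |
                 nchar(gsub("[^N]", "", mols$sequence)) / nchar(mols$sequence)
               <= 0.2, ]
  # re-feed each molecule as one read per strand (masked bases stay masked)
  refeed <- do.call(rbind, lapply(seq_len(nrow(mols)), function(i)
    rbind(make_pair(mols$chrom[i], mols$start[i], mols$sequence[i], "top",
                    read_id = paste0("m", i, "t")),
          make_pair(mols$chrom[i], mols$start[i], mols$sequence[i], "bottom",
                    read_id = paste0("m", i, "b")))))
  again <- call_consensus_molecules(refeed, ref, split = FALSE)$molecules
  key <- function(m) do.call(order, m[c("chrom", "start", "end")])
  expect_identical(again[key(again), ]$sequence, mols[key(mols), ]$sequence)
})
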