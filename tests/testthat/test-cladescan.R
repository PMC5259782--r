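test_that("reference-unique positions are columns where the reference stands alone", {
  aln <- clade_aln(c(ref = "MKLE", o1 = "MKIE", o2 = "MKIE"))
  u <- reference_unique_positions(aln, "ref")
  expect_equal(u$column, 3L)
  expect_equal(u$reference_position, 3L)
  expect_equal(u$reference_residue, "L")

  same <- clade_aln(c(ref = "MKLE", o1 = "MKLE"))
  expect_equal(nrow(reference_unique_positions(same, "ref")), 0L)
  expect_error(reference_unique_positions(clade_aln(c(a = "MK")), "a"),
               ">= 2 sequences")
  expect_error(reference_unique_positions(aln, "nope"), "unknown sequence")
})

test_that("a sequence identical to the reference empties the unique set", {
  set.seed(11)
  aln <- random_gapped_alignment(5, 40)
  ref <- aln_ids(aln)[1]
  seqs <- c(aln$seq, twin = unname(aln$seq[ref]))
  aln2 <- clade_aln(seqs)
  expect_equal(nrow(reference_unique_positions(aln2, ref)), 0L)
})

test_that("gap policy switches the meaning of gapped rows", {
  aln <- clade_aln(c(ref = "MKLE", o1 = "MK-E", o2 = "MK-E"))
  # default: a gap differs from the reference residue -> column 3 unique
  expect_equal(reference_unique_positions(aln, "ref")$column, 3L)
  # ignoring gapped rows leaves nobody to differ from at column 3
  expect_equal(
    nrow(reference_unique_positions(aln, "ref",
                                    other_gap_policy = "ignore-gapped-rows")),
    0L)
})

test_that("clade consensus counts residues and breaks ties deterministically", {
  aln <- toy_clades(c(A_1 = "KK", A_2 = "KK", A_3 = "KE"))
  expect_equal(clade_consensus(aln, "A", 1),
               tibble::tibble(clade = "A", column = 1L, residue = "K",
                              frequency = 1, n = 3L))
  cc <- clade_consensus(aln, "A", 2)
  expect_equal(cc$residue, "K")
  expect_equal(cc$frequency, 2 / 3)
  tie <- toy_clades(c(A_1 = "K", A_2 = "E"))
  cc <- clade_consensus(tie, "A", 1)
  expect_equal(cc$residue, "E")  # E precedes K in the fixed ordering
  expect_equal(cc$frequency, 0.5)
  # gapped member: denominator depends on policy
  gap <- toy_clades(c(A_1 = "KK", A_2 = "-K"))
  expect_equal(clade_consensus(gap, "A", 1)$frequency, 0.5)
  expect_equal(clade_consensus(gap, "A", 1,
                               other_gap_policy = "ignore-gapped-rows")$frequency,
               1)
  expect_error(clade_consensus(gap, "Z", 1), "no members")
})

test_that("discriminating positions require target conservation and contrast divergence", {
  aln <- toy_clades(c(A_1 = "MKE", A_2 = "MKE",
                      B_1 = "MEE", B_2 = "MEE",
                      C_1 = "MEE", C_2 = "MEE"))
  p <- scan_params("A", c("B", "C"))
  d <- discriminating_positions(aln, p)
  expect_equal(d$column, 2L)
  expect_equal(d$target_residue, "K")
  expect_equal(d$target_frequency, 1)
  expect_equal(d$consensus_B, "E")
  expect_equal(d$frequency_B, 1)

  # below-threshold target conservation is rejected
  aln2 <- toy_clades(c(A_1 = "MKE", A_2 = "MEE",
                       B_1 = "MEE", B_2 = "MEE",
                       C_1 = "MEE", C_2 = "MEE"))
  expect_equal(nrow(discriminating_positions(aln2, p)), 0L)
  expect_error(discriminating_positions(
    toy_clades(c(A_1 = "MK", B_1 = "ME")),
    scan_params("A", c("B", "C"))), "no members")
})

test_that("strict contrast requires absence from every contrast member", {
  # B's consensus is E but one member carries the target residue K
  aln <- toy_clades(c(A_1 = "K", A_2 = "K",
                      B_1 = "E", B_2 = "E", B_3 = "K"))
  lax <- scan_params("A", "B")
  strict <- scan_params("A", "B", strict_contrast = TRUE)
  expect_equal(discriminating_positions(aln, lax)$column, 1L)
  expect_equal(nrow(discriminating_positions(aln, strict)), 0L)
})

test_that("raising the conservation threshold never adds sites", {
  set.seed(5)
  for (rep in 1:10) {
    sim <- generate_clade_msa(msa_sim_config(
      clades = c(A = 3L, B = 3L, C = 3L), length = 60L,
      within_noise = 0.1, clade_divergence = 0.2, seed = rep,
      planted_candidate = c(10L, 30L)))
    cols <- lapply(c(0.5, 0.7, 0.9, 1.0), function(th) {
      discriminating_positions(sim$alignment,
                               scan_params("B", c("A", "C"),
                                           conservation_threshold = th))$column
    })
    for (i in seq_len(length(cols) - 1)) {
      expect_true(all(cols[[i + 1]] %in% cols[[i]]))
    }
  }
})

test_that("candidate screen equals an independent naive double-loop scan", {
  set.seed(99)
  for (rep in 1:8) {
    sim <- generate_clade_msa(msa_sim_config(
      clades = c(A = 3L, B = 4L, C = 3L),
      length = sample(50:200, 1),
      within_noise = runif(1, 0, 0.15),
      clade_divergence = runif(1, 0, 0.3),
      indel_prob = runif(1, 0, 0.05),
      planted_unique = 5L, planted_candidate = c(20L, 40L),
      seed = 1000 + rep))
    aln <- sim$alignment
    got <- candidate_screen(aln, sim$ref_id,
                            scan_params("B", c("A", "C")))$column
    want <- naive_candidate_columns(aln, sim$ref_id, "B", c("A", "C"))
    expect_equal(got, want)
  }
})

test_that("zero-noise synthetic alignments are recovered exactly", {
  for (seed in 1:5) {
    sim <- generate_clade_msa(msa_sim_config(
      length = 100L, within_noise = 0, clade_divergence = 0.15,
      planted_unique = c(12L, 55L), planted_candidate = c(33L, 78L),
      seed = seed))
    got <- candidate_screen(sim$alignment, sim$ref_id,
                            scan_params("Nostocales",
                                        c("Chroococcales", "Oscillatoriales")))
    truth <- sim$truth[sim$truth$type == "candidate", ]
    expect_equal(got$column, truth$column)
    expect_equal(got$reference_position, truth$reference_position)
    uniq <- reference_unique_positions(sim$alignment, sim$ref_id)
    expect_equal(uniq$column, sort(sim$truth$column))
  }
})

test_that("known-site conservation reports per-clade frequencies and a global flag", {
  aln <- toy_clades(c(A_1 = "MKE", A_2 = "MKE",
                      B_1 = "MKE", B_2 = "MQE"))
  rep1 <- known_site_conservation(aln, "A_1", c(3, 1))
  # input order preserved
  expect_equal(unique(rep1$reference_position), c(3, 1))
  p3 <- rep1[rep1$reference_position == 3, ]
  expect_true(all(p3$conserved_in_all))
  expect_true(all(p3$frequency == 1))
  p2 <- known_site_conservation(aln, "A_1", 2)
  expect_false(any(p2$conserved_in_all))
  expect_equal(p2$frequency[p2$clade == "B"], 0.5)
  expect_error(known_site_conservation(aln, "A_1", 9), "out of range")
})

test_that("aliphatic index follows the weighted mole-fraction formula", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("AVIL"), 292.5)
  expect_equal(aliphatic_index("AVIL", method = "fraction"), 100)
  expect_equal(aliphatic_index("MKE"), 0)
  expect_equal(aliphatic_index("A-A-"), 100)  # gaps ignored
  expect_error(aliphatic_index("--"), "empty")
})
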