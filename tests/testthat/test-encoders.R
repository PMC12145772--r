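# Descriptor families: worked examples, definitional identities, and
# exact agreement with brute-force enumeration oracles.

test_that("homopolymer and small worked examples match hand calculations", {
  polyA <- strrep("A", 41)
  expect_equal(unname(encode_nac(polyA)), c(1, 0, 0, 0))
  expect_equal(unname(encode_zcurve(polyA)), c(1, 1, 1))

  k3 <- encode_kmer("AAAAA", k = 3)
  expect_equal(unname(k3["Kmer_AAA"]), 1)
  expect_equal(sum(k3), 1)

  ck <- encode_cksnap("ACAC", max_gap = 0)
  expect_equal(unname(ck["CKSNAP_0_AC"]), 2 / 3)
  expect_equal(unname(ck["CKSNAP_0_CA"]), 1 / 3)
  expect_equal(sum(ck), 1)

  polyG <- strrep("G", 20)
  ckg <- encode_cksnap(polyG, max_gap = 5)
  expect_true(all(ckg[grepl("_GG$", names(ckg))] == 1))
  expect_equal(sum(ckg), 6)   # one unit mass per gap block

  en <- encode_enac(strrep("A", 10), window = 4)
  expect_true(all(en[grepl("\\.A$", names(en))] == 1))

  expect_equal(unname(encode_ncp("ACGT")),
               c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 1))

  expect_equal(unname(encode_dbe("AC")), c(0, 0, 0, 1))
  expect_true(all(encode_dbe(strrep("T", 10)) == 1))

  ps <- encode_ps2("ACGT")
  expect_equal(sum(ps), 3)                       # one 1 per dinucleotide
  expect_equal(unname(ps["PS2_1"]), 1)           # first block, rank 1 = AC

  mm <- encode_mismatch("AAAAA", k = 3, m = 1)
  neighbors <- names(mm)[mm == 1]
  expect_length(neighbors, 10)                   # AAA + 9 single substitutions
  expect_true("Mismatch_AAA" %in% neighbors)

  expect_equal(unname(encode_mmi(strrep("A", 10))), rep(0, 30))

  as <- encode_asdc("AC")
  expect_equal(unname(as["ASDC_AC"]), 1)
  expect_equal(unname(encode_asdc(strrep("G", 8))["ASDC_GG"]), 1)
})

test_that("balanced sequences zero the Z-curve", {
  expect_equal(unname(encode_zcurve("ACGTACGTACGT")), c(0, 0, 0))
})

test_that("counting encoders match brute-force oracles on random windows", {
  set.seed(42)
  for (i in 1:200) {
    s <- rand_window(41L)
    expect_equal(unname(encode_nac(s)), unname(oracle_nac(s)), tolerance = 1e-14)
    expect_equal(unname(encode_zcurve(s)), unname(oracle_zcurve(s)),
                 tolerance = 1e-14)
  }
  set.seed(43)
  for (i in 1:50) {
    s <- rand_window(41L)
    for (k in 1:3) {
      expect_equal(unname(encode_kmer(s, k)), unname(oracle_kmer(s, k)))
    }
    expect_equal(unname(encode_cksnap(s, 5)), unname(oracle_cksnap(s, 5)))
    expect_equal(unname(encode_enac(s, 5)), unname(oracle_enac(s, 5)))
    expect_equal(unname(encode_asdc(s)), unname(oracle_asdc(s)))
  }
})

test_that("mismatch profile matches the double-loop Hamming oracle", {
  set.seed(44)
  for (i in 1:30) {
    s <- rand_window(21L)
    expect_equal(unname(encode_mismatch(s, 2, 1)), unname(oracle_mismatch(s, 2, 1)))
    expect_equal(unname(encode_mismatch(s, 3, 1)), unname(oracle_mismatch(s, 3, 1)))
  }
})

test_that("MMI matches an independent enumeration to 1e-10", {
  set.seed(45)
  for (i in 1:25) {
    s <- rand_window(21L)
    expect_equal(encode_mmi(s), oracle_mmi(s), tolerance = 1e-10)
  }
})

test_that("NCP satisfies the component-sum identity with counted bases", {
  set.seed(46)
  for (i in 1:200) {
    s <- rand_window(41L)
    counts <- oracle_nac(s) * 41
    expect_equal(sum(encode_ncp(s)),
                 counts[["A"]] * 3 + counts[["C"]] + counts[["G"]] + counts[["T"]])
  }
})

test_that("definitional identities hold between encoder families", {
  set.seed(47)
  for (i in 1:50) {
    s <- rand_window(41L)
    # k = 1 k-mers are the nucleotide composition
    expect_equal(unname(encode_kmer(s, 1)), unname(encode_nac(s)))
    # full-width ENAC window reduces to NAC
    expect_equal(unname(encode_enac(s, window = 41L)), unname(encode_nac(s)))
    # zero-mismatch profile is the plain k-mer spectrum
    expect_equal(unname(encode_mismatch(s, 3, 0)), unname(encode_kmer(s, 3)))
    # PS2 blocks marginalized over positions give the dinucleotide spectrum
    ps <- matrix(encode_ps2(s), nrow = 16L)
    expect_equal(unname(rowSums(ps) / 40), unname(encode_kmer(s, 2)),
                 tolerance = 1e-12)
    # each DBE 4-bit block decodes to the index of the 1 in the PS2 block
    dbe <- matrix(encode_dbe(s), nrow = 4L)
    decoded <- as.integer(crossprod(dbe, 2^(3:0)))
    onehot <- apply(ps, 2L, which.max) - 1L
    expect_identical(decoded, onehot)
  }
})

test_that("normalization contracts hold", {
  set.seed(48)
  for (i in 1:50) {
    s <- rand_window(41L)
    expect_equal(sum(encode_nac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_kmer(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_asdc(s)), 1, tolerance = 1e-9)
    expect_equal(unname(colSums(matrix(encode_enac(s, 5), nrow = 4L))),
                 rep(1, 37), tolerance = 1e-9)
    expect_equal(unname(colSums(matrix(encode_cksnap(s, 5), nrow = 16L))),
                 rep(1, 6), tolerance = 1e-9)
  }
})

test_that("encoders are pure: identical input gives bit-identical output", {
  s <- rand_window(41L)
  for (spec in default_encoders()) {
    expect_identical(encode_sequence(s, spec), encode_sequence(s, spec))
  }
})

test_that("parameter preconditions are enforced", {
  s <- rand_window(11L)
  expect_error(encode_kmer(s, k = 12), "k must satisfy")
  expect_error(encode_cksnap(s, max_gap = 10), "max_gap")
  expect_error(encode_enac(s, window = 12), "window")
  expect_error(encode_mismatch(s, k = 3, m = 4), "m <= k")
  expect_error(encode_nac(""), "non-empty")
  expect_error(encode_sequence(s, encoder_spec("kmer", q = 2)), "no parameter")
  expect_error(encoder_spec("pseknc"), "unknown encoder")
})

test_that("dataset encoding is deterministic, order-equivariant and composable", {
  ds <- rand_dataset(10, seed = 49)
  same <- m5c_dataset(c("x", "y", "z"), rep(ds$seq[1], 3))
  m_same <- encode_dataset(same, "nac")
  expect_true(all(m_same[1, ] == m_same[2, ]) && all(m_same[2, ] == m_same[3, ]))

  m <- encode_dataset(ds, "kmer")
  perm <- sample(length(ds))
  m_perm <- encode_dataset(ds[perm], "kmer")
  expect_equal(bare(m_perm), bare(m[perm, ]))

  m_nac <- encode_dataset(ds, "nac")
  for (i in seq_len(10)) {
    expect_equal(m_nac[i, ], encode_nac(ds$seq[i]))
  }
  expect_identical(rownames(m_nac), ds$id)
})

test_that("per-record encoder failures name the record", {
  ds <- rand_dataset(3, L = 5, seed = 50)
  expect_error(encode_dataset(ds, encoder_spec("kmer", k = 6)), "r001")
})

test_that("concatenation stacks features and checks record alignment", {
  ds <- rand_dataset(5, seed = 51)
  nac <- encode_dataset(ds, "nac")
  zc <- encode_dataset(ds, "zcurve")
  both <- concatenate_features(list(nac, zc))
  expect_identical(ncol(both), 7L)
  expect_identical(colnames(both), c(colnames(nac), colnames(zc)))

  expect_equal(bare(concatenate_features(list(nac))), bare(nac))

  misordered <- encode_dataset(ds[c(2:5, 1)], "zcurve")
  expect_error(concatenate_features(list(nac, misordered)), "record ids differ")
})
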