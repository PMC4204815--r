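test_that("count_flanked_snps: substitution + clean flanks required", {
  # fully conserved -> 0
  cp <- build_consensus_pair(backbone_alignment(100L))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 0L)

  # one substitution with >= 5 conserved columns each side -> 1
  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = 50L))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 1L)

  # two substitutions 3 apart violate each other's flanks -> 0
  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = c(50L, 53L)))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 0L)
  # ... but 6 apart both count
  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = c(50L, 56L)))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 2L)

  # gap-derived N with perfect flanks is an indel, not a SNP -> 0
  cp <- build_consensus_pair(backbone_alignment(100L, indel_at = 50L))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 0L)
  # same for an N-derived ambiguous column
  cp <- build_consensus_pair(backbone_alignment(100L, n_at = 50L))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 0L)

  # flanks may extend outside the interval but not outside the alignment
  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = 50L))
  expect_equal(count_flanked_snps(cp, interval(50, 51)), 1L)
  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = 3L))
  expect_equal(count_flanked_snps(cp, interval(0, 100)), 0L)
})

test_that("max_ambiguous_run returns the longest N run", {
  cp <- build_consensus_pair(backbone_alignment(100L))
  expect_equal(max_ambiguous_run(cp, interval(0, 100)), 0L)

  cp <- build_consensus_pair(
    backbone_alignment(100L, indel_at = c(10:12, 40:46)))
  expect_equal(max_ambiguous_run(cp, interval(0, 100)), 7L)
  expect_equal(max_ambiguous_run(cp, interval(0, 20)), 3L)

  cp <- build_consensus_pair(backbone_alignment(100L, snp_at = 50L))
  expect_equal(max_ambiguous_run(cp, interval(0, 100)), 1L)
})

test_that("scan_blocks recovers a planted hypervariable region", {
  snps <- seq(310L, 590L, by = 40L)              # 8 well-spaced SNPs
  a <- backbone_alignment(900L, snp_at = snps)
  cp <- build_consensus_pair(a)

  fam <- scan_blocks(cp, scan_params("family"))
  expect_equal(nrow(fam), 1L)
  expect_lte(fam$start, 310L)
  expect_gte(fam$end, 591L)
  expect_equal(fam$flanked_snp_count, 8L)
  expect_equal(fam$merged_from, 20L)             # starts 291..310

  # 7 SNPs: family rejects, genus accepts
  a7 <- backbone_alignment(900L, snp_at = snps[-1L])
  cp7 <- build_consensus_pair(a7)
  expect_equal(nrow(scan_blocks(cp7, scan_params("family"))), 0L)
  expect_gte(nrow(scan_blocks(cp7, scan_params("genus"))), 1L)

  # an 8-long ambiguous run kills every otherwise-qualifying window
  a8 <- backbone_alignment(900L, snp_at = snps, indel_at = 440:447)
  expect_equal(nrow(scan_blocks(build_consensus_pair(a8),
                                scan_params("family"))), 0L)
  # a 7-long run is tolerated
  a7r <- backbone_alignment(900L, snp_at = snps, indel_at = 440:446)
  expect_equal(nrow(scan_blocks(build_consensus_pair(a7r),
                                scan_params("family"))), 1L)

  expect_error(scan_blocks(build_consensus_pair(backbone_alignment(200L)),
                           scan_params("family")), "shorter")
})

test_that("scan_blocks equals the brute-force oracle on random alignments", {
  withr::local_seed(31L)
  for (i in 1:6) {
    a <- random_test_alignment(L = 1200L)
    cp <- build_consensus_pair(a)
    for (level in c("family", "genus")) {
      p <- scan_params(level)
      got <- scan_blocks(cp, p)
      want <- oracle_scan_blocks(a, p)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$merged_from, want$merged_from)
    }
  }
})

test_that("family-accepted windows are genus-accepted when caps equalize", {
  withr::local_seed(55L)
  for (i in 1:4) {
    a <- random_test_alignment(L = 1500L)
    cp <- build_consensus_pair(a)
    fam <- scan_blocks(cp, scan_params("family"))
    gen <- scan_blocks(cp, scan_params("genus", max_divergence = 0.15))
    if (nrow(fam) == 0L) next
    for (j in seq_len(nrow(fam))) {
      covered <- any(gen$start <= fam$start[j] & gen$end >= fam$end[j])
      expect_true(covered)
    }
  }
})

test_that("coarser stride detects the same isolated planted block", {
  snps <- seq(310L, 590L, by = 40L)
  cp <- build_consensus_pair(backbone_alignment(900L, snp_at = snps))
  b1 <- scan_blocks(cp, scan_params("family", step = 1L))
  b50 <- scan_blocks(cp, scan_params("family", step = 50L))
  expect_equal(nrow(b1), 1L)
  expect_equal(nrow(b50), 1L)
  expect_gte(b50$start, b1$start)    # coarser union nests in the fine one
  expect_lte(b50$end, b1$end)
})
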