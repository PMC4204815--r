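test_that("melting temperature matches frozen external oracle values", {
  # nearest-neighbor values computed independently (SantaLucia 1998
  # unified table, 50 mM Na+, 0.25 uM total strand) and frozen
  expect_equal(melting_temperature("ATGCATGCATGCATGCATGC"), 57.68)
  expect_equal(melting_temperature("CGAAGGGCTTGGTTCTGAGAG"), 56.98)
  # self-complementary oligo exercises the symmetry correction
  expect_equal(melting_temperature("ACGTACGTACGTACGT"), 49.94)

  # NN symmetry: Tm(s) == Tm(revcomp(s))
  withr::local_seed(9L)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
               collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
                collapse = "")
    expect_equal(melting_temperature(s), melting_temperature(rc))
  }

  # Wallace closed form: 2(A+T) + 4(G+C)
  expect_equal(melting_temperature("ATATATATATGCGCGCGCGC",
                                   method = "wallace"), 60)
  expect_error(melting_temperature("ACGTNACG"), "ambiguous|non-ACGT")
  expect_error(melting_temperature("ACGT"), "length >= 8")
})

# a conserved backbone with a variable target in the middle: SNPs every
# 12 columns inside [450, 550)
primer_fixture <- function() {
  snps <- seq(452L, 548L, by = 12L)
  build_consensus_pair(backbone_alignment(1000L, snp_at = snps))
}

test_that("enumerate_conserved_sites honors conservation and search flank", {
  cp <- primer_fixture()
  target <- interval(450, 550)
  cn <- primer_constraints(tm = c(0, 100), gc = c(0, 1))  # geometry only
  sites <- enumerate_conserved_sites(cp, target, cn)
  expect_gt(nrow(sites), 0L)

  amb <- strsplit(cp$ambiguous, "", fixed = TRUE)[[1L]]
  # no placement covers an ambiguous column
  for (i in seq_len(nrow(sites))) {
    expect_false(any(amb[(sites$start[i] + 1L):sites$end[i]] == "N"))
  }
  fwd <- sites[sites$orientation == "fwd", ]
  rev_ <- sites[sites$orientation == "rev", ]
  # search window: fwd starts within 300 upstream, rev ends within 300
  # downstream; boundary placements are present, beyond-boundary absent
  expect_gte(min(fwd$start), 450L - 300L)
  expect_equal(min(fwd$start), 150L)
  expect_lte(max(rev_$end), 550L + 300L)
  expect_equal(max(rev_$end), 850L)

  # oligo strings: fwd read off the template, rev its reverse complement
  i <- which(sites$orientation == "fwd")[1L]
  expect_equal(sites$seq[i],
               paste(amb[(sites$start[i] + 1L):sites$end[i]],
                     collapse = ""))
  j <- which(sites$orientation == "rev")[1L]
  tmpl <- paste(amb[(sites$start[j] + 1L):sites$end[j]], collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", tmpl), "")[[1L]]),
              collapse = "")
  expect_equal(sites$seq[j], rc)
})

test_that("design_pairs respects product size, polymorphism and footprints", {
  cp <- primer_fixture()
  target <- interval(450, 550)
  pp <- design_pairs(cp, target, k = 10L)
  expect_gt(nrow(pp), 0L)
  expect_true(all(pp$product_size >= 100L & pp$product_size <= 280L))
  expect_true(all(pp$product_size ==
                    pp$rev_end - pp$fwd_start))
  expect_true(all(abs(pp$tm_fwd - pp$tm_rev) <= 4))

  amb <- strsplit(cp$ambiguous, "", fixed = TRUE)[[1L]]
  npos <- which(amb == "N") - 1L
  for (i in seq_len(nrow(pp))) {
    # no oligo footprint touches an ambiguous column
    expect_false(any(amb[(pp$fwd_start[i] + 1L):pp$fwd_end[i]] == "N"))
    expect_false(any(amb[(pp$rev_start[i] + 1L):pp$rev_end[i]] == "N"))
    # the amplicon covers at least one polymorphic column of the target
    expect_true(any(npos >= pp$fwd_start[i] & npos < pp$rev_end[i] &
                      npos >= 450L & npos < 550L))
  }
})

test_that("a conserved-only target yields no pair, with a reason histogram", {
  cp <- build_consensus_pair(backbone_alignment(1000L))  # zero N anywhere
  pp <- design_pairs(cp, interval(450, 550))
  expect_equal(nrow(pp), 0L)
  h <- attr(pp, "rejection_histogram")
  expect_true(!is.null(h))
  expect_gt(h[["no_polymorphism"]], 0)
})

test_that("design_pairs is deterministic", {
  cp <- primer_fixture()
  a <- design_pairs(cp, interval(450, 550), k = 1L)
  b <- design_pairs(cp, interval(450, 550), k = 1L)
  expect_equal(nrow(a), 1L)
  expect_identical(a, b)
})
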