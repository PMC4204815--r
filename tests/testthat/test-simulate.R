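test_that("same seed gives byte-identical simulations", {
  s1 <- simulate_family(simulation_spec(seed = 33L))
  s2 <- simulate_family(simulation_spec(seed = 33L))
  expect_identical(alignment_strings(s1$alignment),
                   alignment_strings(s2$alignment))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_family(simulation_spec(seed = 34L))
  expect_false(identical(alignment_strings(s1$alignment),
                         alignment_strings(s3$alignment)))
})

test_that("zero mutation rate gives a clonal alignment", {
  spec <- simulation_spec(base_mutation_rate = 0, seq_len = 2000L,
                          planted_features = list(), seed = 2L)
  sim <- simulate_family(spec)
  rows <- alignment_strings(sim$alignment)
  expect_true(all(rows == rows[1L]))
  cp <- build_consensus_pair(sim$alignment)
  expect_identical(cp$ambiguous, unname(rows[1L]))
})

test_that("planted features behave as stated", {
  sim <- simulate_family(simulation_spec(seed = 11L))
  cp <- build_consensus_pair(sim$alignment)
  truth <- sim$truth

  # conserved islands carry zero ambiguous columns (rate multiplier 0)
  isl <- truth[truth$kind == "conserved_island", ]
  for (i in seq_len(nrow(isl))) {
    expect_equal(max_ambiguous_run(cp, interval(isl$start[i], isl$end[i])),
                 0L)
    expect_equal(truth$divergence[truth$kind == "conserved_island"][i], 0)
  }

  # SSR loci with unequal unit counts are flagged polymorphic
  ssr <- truth[truth$kind == "ssr_locus", ]
  expect_true(all(ssr$ssr_polymorphic))
  loci <- find_perfect_repeats(cp)
  cand <- screen_polymorphic(loci, cp)
  for (i in seq_len(nrow(ssr))) {
    hit <- cand$start < ssr$end[i] & cand$end > ssr$start[i]
    expect_true(any(hit & cand$polymorphic))
  }

  # indels appear as gap columns only in the designated taxon
  ind <- truth[truth$kind == "indel", ]
  gaps <- sim$alignment$mat[, (ind$start + 1L):ind$end] == "-"
  expect_true(all(gaps[3L, ]))
  expect_false(any(gaps[-3L, ]))

  # overlapping or out-of-range features are rejected at spec time
  expect_error(simulation_spec(planted_features = list(
    list(kind = "conserved_island", start = 100L, len = 500L),
    list(kind = "variable_block", start = 300L, len = 300L))),
    "overlap")
  expect_error(simulation_spec(seq_len = 17000L, planted_features = list(
    list(kind = "conserved_island", start = 16900L, len = 500L))),
    "past seq_len")
})

test_that("empirical transition:transversion ratio tracks kappa", {
  kappa <- 2
  d <- 0.1
  spec <- simulation_spec(tree = sprintf("(x:0,y:%f);", d),
                          seq_len = 100000L, kappa = kappa,
                          planted_features = list(), seed = 17L)
  sim <- simulate_family(spec)
  m <- sim$alignment$mat
  diff <- m[1L, ] != m[2L, ]
  pur <- m %in% c("A", "G")
  dim(pur) <- dim(m)
  ts <- sum(diff & pur[1L, ] == pur[2L, ])
  tv <- sum(diff & pur[1L, ] != pur[2L, ])

  # expected P/Q from the K80 transition probabilities at distance d
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  expect_equal(ts / tv, p_ts / p_tv, tolerance = 0.1)
})

test_that("closed loop: realized variable blocks are found by the scanner", {
  sim <- simulate_family(simulation_spec(seed = 21L))
  cp <- build_consensus_pair(sim$alignment)
  blocks <- scan_blocks(cp, scan_params("family"))
  vb <- sim$truth[sim$truth$kind == "variable_block" &
                    sim$truth$detectable_family, ]
  expect_gt(nrow(vb), 0L)
  for (i in seq_len(nrow(vb))) {
    expect_true(any(blocks$start < vb$end[i] & blocks$end > vb$start[i]))
  }
})

test_that("write_simulation emits alignment, truth and spec echo", {
  dir <- withr::local_tempdir()
  sim <- simulate_family(simulation_spec(seed = 3L))
  write_simulation(sim, file.path(dir, "sim"))
  a <- read_alignment(file.path(dir, "sim_alignment.fasta"))
  expect_identical(alignment_strings(a), alignment_strings(sim$alignment))
  truth <- read.delim(file.path(dir, "sim_truth.tsv"))
  expect_equal(nrow(truth), nrow(sim$truth))
  spec <- jsonlite::read_json(file.path(dir, "sim_spec.json"))
  expect_equal(spec$seed, 3L)
  expect_equal(spec$seq_len, 20000L)
})
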