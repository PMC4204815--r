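DEFAULT_FAMILY_TREE <-
  "(((Zof:0.001,Hco:0.001):0.001,Clo:0.001):0.001,(Aze:0.001,Aca:0.001):0.001);"

default_planted_features <- function(seq_len) {
  if (seq_len < 16000L) stop("default feature layout needs seq_len >= 16000")
  list(
    list(kind = "conserved_island", start = 1000L, len = 600L),
    list(kind = "ssr_locus", start = 3000L, motif = "AT",
         unit_counts = c(6L, 6L, 8L, 6L, 6L)),
    list(kind = "variable_block", start = 5000L, len = 300L,
         rate_mult = 10),
    list(kind = "conserved_island", start = 8000L, len = 600L),
    list(kind = "ssr_locus", start = 10000L, motif = "AAG",
         unit_counts = c(5L, 5L, 5L, 7L, 5L)),
    list(kind = "variable_block", start = 12000L, len = 300L,
         rate_mult = 10),
    list(kind = "indel", start = 15000L, len = 9L, taxa = 3L)
  )
}

#' Specify a synthetic plastome-family simulation
#'
#' The default stated world emulates a five-taxon plastome family at
#' family-level conservation: ~99% background identity (every branch
#' 0.001 substitutions/site on a topology mirroring the
#' Zingiber/Hedychium + Curcuma vs Alpinia/Amomum split), 20 kb of
#' sequence, K80 substitution with kappa = 2, two perfectly conserved
#' islands (rate 0), two 300-bp hypervariable blocks (rate x10), two
#' polymorphic SSR loci planted as explicit per-taxon unit counts, and one
#' 9-bp single-taxon indel emitted as aligned gap columns.
#'
#' @param tree Newick string with branch lengths (substitutions/site).
#' @param seq_len Alignment length in columns before feature realization.
#' @param kappa K80 transition/transversion rate ratio.
#' @param base_mutation_rate Scalar multiplier on all branch lengths.
#' @param planted_features List of feature descriptors; each a list with
#'   `kind` (`conserved_island`, `variable_block`, `ssr_locus`, `indel`),
#'   `start` (0-based column) and kind-specific fields: `len` and
#'   optionally `rate_mult` (blocks/islands), `motif` + `unit_counts`
#'   (one count per taxon, tree tip order) for SSRs, `len` + `taxa`
#'   (indices or tip ids) for indels.
#' @param seed Integer seed; the simulation is byte-reproducible.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(tree = DEFAULT_FAMILY_TREE,
                            seq_len = 20000L,
                            kappa = 2,
                            base_mutation_rate = 1,
                            planted_features = default_planted_features(seq_len),
                            seed = 1L) {
  spec <- list(tree = tree, seq_len = as.integer(seq_len), kappa = kappa,
               base_mutation_rate = base_mutation_rate,
               planted_features = planted_features, seed = as.integer(seed))
  stopifnot(spec$seq_len >= 1L, kappa > 0, base_mutation_rate >= 0)
  fiv <- feature_footprints(spec)
  if (nrow(fiv) > 1L) {
    o <- order(fiv$start)
    if (any(fiv$start[o][-1L] < fiv$end[o][-nrow(fiv)])) {
      stop("planted features overlap")
    }
  }
  if (nrow(fiv) > 0L && any(fiv$end > spec$seq_len)) {
    stop("planted feature extends past seq_len")
  }
  structure(spec, class = "simulation_spec")
}

feature_footprints <- function(spec) {
  rows <- lapply(spec$planted_features, function(f) {
    len <- switch(f$kind,
                  ssr_locus = max(f$unit_counts) * nchar(f$motif),
                  f$len)
    data.frame(kind = f$kind, start = as.integer(f$start),
               end = as.integer(f$start) + as.integer(len))
  })
  if (length(rows) == 0L) {
    return(data.frame(kind = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, rows)
}

# K80 per-site substitution draw along one branch. d is the vector of
# expected substitutions/site per column; seqs are integer codes 1..4
# (A,C,G,T). Transition partner swaps within purines/pyrimidines.
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_CHOICES <- matrix(c(2L, 4L,   # A -> C/T
                       1L, 3L,   # C -> A/G
                       2L, 4L,   # G -> C/T
                       1L, 3L),  # T -> A/G
                     nrow = 4L, byrow = TRUE)

k80_evolve_branch <- function(seq, d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e4b <- exp(-4 * bt)
  e2ab <- exp(-2 * (at + bt))
  p_same <- 0.25 + 0.25 * e4b + 0.5 * e2ab
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv1 <- 0.25 - 0.25 * e4b                 # each of the two transversions
  u <- stats::runif(length(seq))
  out <- seq
  ts <- u >= p_same & u < p_same + p_ts
  tv1 <- u >= p_same + p_ts & u < p_same + p_ts + p_tv1
  tv2 <- u >= p_same + p_ts + p_tv1
  out[ts] <- TS_PARTNER[seq[ts]]
  out[tv1] <- TV_CHOICES[cbind(seq[tv1], 1L)]
  out[tv2] <- TV_CHOICES[cbind(seq[tv2], 2L)]
  out
}

#' Simulate a plastome family with planted, ground-truthed markers
#'
#' Draws a uniform-random ancestor, evolves it along the spec's tree under
#' K80 with per-column rate multipliers (0 in conserved islands,
#' `rate_mult` in variable blocks), then realizes planted features on the
#' resulting alignment: SSR loci are overwritten with the motif repeated
#' per-taxon unit counts (shorter taxa padded with `-`, emulating aligner
#' output), and indels become gap columns in the designated taxa. The
#' truth table records each feature's interval plus its *realized*
#' statistics measured on the final alignment -- stochastic substitution
#' means requested and realized can differ, and tests must assert against
#' realized truth.
#'
#' @param spec A [simulation_spec()].
#' @return List of class `plast_simulation`: `alignment`
#'   (`plast_alignment`), `truth` (data frame: `kind`, `start`, `end`,
#'   `detail`, realized `divergence`, `flanked_snp_count`,
#'   `max_ambig_run`, `detectable_family`, `detectable_genus`,
#'   `ssr_polymorphic`), and the echoed `spec`.
#' @export
simulate_family <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  tr <- ape::read.tree(text = spec$tree)
  if (is.null(tr$edge.length)) stop("tree must carry branch lengths")
  ntip <- length(tr$tip.label)

  L <- spec$seq_len
  mult <- rep(1, L)
  for (f in spec$planted_features) {
    if (f$kind == "conserved_island") {
      mult[(f$start + 1L):(f$start + f$len)] <- 0
    } else if (f$kind == "variable_block") {
      rm <- if (is.null(f$rate_mult)) 10 else f$rate_mult
      mult[(f$start + 1L):(f$start + f$len)] <- rm
    }
  }

  mat <- with_seed(spec$seed, {
    anc <- sample.int(4L, L, replace = TRUE)
    nnode <- ntip + tr$Nnode
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- anc
    # ape edge matrix is in preorder for read.tree output; walk parents first
    ord <- order(tr$edge[, 1L])
    for (e in ord) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      d <- tr$edge.length[e] * spec$base_mutation_rate * mult
      seqs[[child]] <- k80_evolve_branch(seqs[[par]], d, spec$kappa)
    }
    m <- do.call(rbind, seqs[seq_len(ntip)])
    matrix(DNA_BASES4[m], nrow = ntip)
  })
  rownames(mat) <- tr$tip.label

  # realize SSR loci and indels on the final alignment
  for (f in spec$planted_features) {
    if (f$kind == "ssr_locus") {
      u <- nchar(f$motif)
      counts <- as.integer(f$unit_counts)
      if (length(counts) != ntip) {
        stop("ssr_locus needs one unit count per taxon")
      }
      W <- max(counts) * u
      for (i in seq_len(ntip)) {
        row <- c(strsplit(strrep(f$motif, counts[i]), "",
                          fixed = TRUE)[[1L]],
                 rep("-", W - counts[i] * u))
        mat[i, (f$start + 1L):(f$start + W)] <- row
      }
    } else if (f$kind == "indel") {
      taxa <- f$taxa
      if (is.character(taxa)) taxa <- match(taxa, tr$tip.label)
      mat[taxa, (f$start + 1L):(f$start + f$len)] <- "-"
    }
  }

  aln <- new_alignment(apply(mat, 1L, paste, collapse = ""), tr$tip.label)
  cp <- build_consensus_pair(aln)

  truth <- lapply(spec$planted_features, function(f) {
    fp <- feature_footprints(
      structure(list(planted_features = list(f)), class = "list"))
    iv <- interval(fp$start, fp$end)
    div <- divergence(cp, iv)
    snps <- count_flanked_snps(cp, iv, 5L)
    run <- max_ambiguous_run(cp, iv)
    detail <- switch(f$kind,
      ssr_locus = paste0(f$motif, ":", paste(f$unit_counts, collapse = "/")),
      variable_block = paste0("rate_mult=",
                              if (is.null(f$rate_mult)) 10 else f$rate_mult),
      indel = paste0("taxa=", paste(f$taxa, collapse = "/")),
      "")
    ssr_poly <- NA
    if (f$kind == "ssr_locus") {
      scr <- screen_polymorphic(data.frame(start = fp$start, end = fp$end),
                                cp, proximity = 4L)
      ssr_poly <- scr$polymorphic[1L]
    }
    data.frame(kind = f$kind, start = fp$start, end = fp$end,
               detail = detail, divergence = div, flanked_snp_count = snps,
               max_ambig_run = run,
               detectable_family = div >= 0.02 & div <= 0.15 & snps >= 8L &
                 run <= 7L,
               detectable_genus = div >= 0.02 & div <= 0.10 & snps >= 5L &
                 run <= 7L,
               ssr_polymorphic = ssr_poly)
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), start = integer(), end = integer(),
               detail = character(), divergence = numeric(),
               flanked_snp_count = integer(), max_ambig_run = integer(),
               detectable_family = logical(), detectable_genus = logical(),
               ssr_polymorphic = logical())

  structure(list(alignment = aln, truth = truth, spec = spec),
            class = "plast_simulation")
}

#' @export
print.plast_simulation <- function(x, ...) {
  cat("<plast_simulation> ", length(x$alignment$ids), " taxa x ",
      x$alignment$length, " columns; ", nrow(x$truth),
      " planted feature(s)\n", sep = "")
  invisible(x)
}

#' Write a simulation's alignment, truth table and spec to disk
#'
#' Emits `<stem>_alignment.fasta`, `<stem>_truth.tsv`, `<stem>_truth.bed`
#' and `<stem>_spec.json`.
#'
#' @param sim A `plast_simulation`.
#' @param stem Output path stem.
#' @return Character vector of paths written, invisibly.
#' @export
write_simulation <- function(sim, stem) {
  stopifnot(inherits(sim, "plast_simulation"))
  fa <- paste0(stem, "_alignment.fasta")
  write_alignment(sim$alignment, fa)
  truth <- cbind(id = sprintf("feature_%02d", seq_len(nrow(sim$truth))),
                 sim$truth)
  write_marker_table(truth, paste0(stem, "_truth"))
  js <- paste0(stem, "_spec.json")
  spec <- unclass(sim$spec)
  jsonlite::write_json(spec, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fa, paste0(stem, "_truth.tsv"), paste0(stem, "_truth.bed"), js))
}
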