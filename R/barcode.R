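#' Barcode block scan parameters
#'
#' Defaults encode the published screen: 300-bp blocks with divergence of
#' at least 2% (inclusive, following the headline wording) and at most 10%
#' (genus comparisons) or 15% (family comparisons), no more than 7
#' consecutive ambiguous bases, and at least 5 (genus) or 8 (family)
#' single-nucleotide polymorphisms each bordered by 5 perfectly conserved
#' bases on both sides.
#'
#' @param level `"genus"` or `"family"`; sets the divergence cap and the
#'   flanked-SNP minimum unless given explicitly.
#' @param block_len Block width in columns.
#' @param min_divergence Inclusive lower divergence bound.
#' @param max_divergence Inclusive upper divergence bound.
#' @param min_flanked_snps Inclusive minimum flanked-SNP count.
#' @param flank_width Conserved bases required each side of a SNP.
#' @param max_ambiguous_run Longest tolerated run of consecutive N columns.
#' @param step Scan stride in columns.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(level = c("family", "genus"),
                        block_len = 300L,
                        min_divergence = 0.02,
                        max_divergence = NULL,
                        min_flanked_snps = NULL,
                        flank_width = 5L,
                        max_ambiguous_run = 7L,
                        step = 1L) {
  level <- match.arg(level)
  if (is.null(max_divergence)) {
    max_divergence <- if (level == "genus") 0.10 else 0.15
  }
  if (is.null(min_flanked_snps)) {
    min_flanked_snps <- if (level == "genus") 5L else 8L
  }
  p <- list(level = level, block_len = as.integer(block_len),
            min_divergence = min_divergence, max_divergence = max_divergence,
            min_flanked_snps = as.integer(min_flanked_snps),
            flank_width = as.integer(flank_width),
            max_ambiguous_run = as.integer(max_ambiguous_run),
            step = as.integer(step))
  if (!(p$min_divergence >= 0 && p$min_divergence < p$max_divergence &&
        p$max_divergence <= 1)) {
    stop("need 0 <= min_divergence < max_divergence <= 1")
  }
  if (p$flank_width < 0L) stop("flank_width must be >= 0")
  if (p$block_len <= 2L * p$flank_width) {
    stop("block_len must exceed twice the flank width")
  }
  if (p$step < 1L) stop("step must be >= 1")
  structure(p, class = "scan_params")
}

# per-column indicator: ambiguous N caused by a substitution and bordered
# by flank_width conserved columns on each side (flanks measured on the
# whole alignment, so they may extend outside any particular block)
flanked_snp_columns <- function(cp, flank_width) {
  isN <- amb_chars(cp) == "N"
  cons <- !isN
  L <- cp$length
  left <- c(0L, run_length_ending(cons)[-L])     # conserved run ending at i-1
  right <- c(rev(run_length_ending(rev(cons)))[-1L], 0L)
  idx <- seq_len(L)
  isN & cp$is_substitution &
    (idx - 1L >= flank_width) & (L - idx >= flank_width) &
    (left >= flank_width) & (right >= flank_width)
}

#' Count conserved-flanked SNPs in a region
#'
#' A qualifying column is ambiguous in the ambiguous track, arises from a
#' substitution (every row carries an A/C/G/T base there -- indel- or
#' N-derived ambiguity does not count), and is bordered by `flank_width`
#' perfectly conserved columns on both sides. Flanks may extend outside
#' the region but not outside the alignment.
#'
#' @param cp A `consensus_pair`.
#' @param iv An [interval()].
#' @param flank_width Conserved bases required each side (default 5).
#' @return Integer count.
#' @export
count_flanked_snps <- function(cp, iv, flank_width = 5L) {
  stopifnot(inherits(cp, "consensus_pair"))
  iv <- check_bounds(iv, cp$length)
  sum(flanked_snp_columns(cp, as.integer(flank_width))[iv_idx(iv)])
}

#' Longest run of consecutive ambiguous columns in a region
#'
#' @param cp A `consensus_pair`.
#' @param iv An [interval()].
#' @return Integer run length (0 if the region has no N column).
#' @export
max_ambiguous_run <- function(cp, iv) {
  stopifnot(inherits(cp, "consensus_pair"))
  iv <- check_bounds(iv, cp$length)
  max_true_run(amb_chars(cp)[iv_idx(iv)] == "N")
}

#' Scan for hypervariable barcode blocks
#'
#' Slides a `block_len` window along the consensus by `step`; a window is
#' accepted when its divergence lies in `[min_divergence, max_divergence]`,
#' its longest ambiguous run is at most `max_ambiguous_run`, and it holds
#' at least `min_flanked_snps` conserved-flanked SNPs. Overlapping accepted
#' windows are merged into one block spanning their union; the union's
#' statistics are reported as-is (each constituent window passed the
#' filters; the union itself is not re-filtered).
#'
#' @param cp A `consensus_pair`.
#' @param params A [scan_params()] object.
#' @return Data frame, one row per merged block, sorted by start: `id`,
#'   `start`, `end`, `level`, `divergence`, `flanked_snp_count`,
#'   `max_ambig_run`, `merged_from`.
#' @export
scan_blocks <- function(cp, params = scan_params()) {
  stopifnot(inherits(cp, "consensus_pair"), inherits(params, "scan_params"))
  L <- cp$length
  B <- params$block_len
  if (L < B) stop("alignment (", L, " columns) shorter than block_len ", B)

  isN <- amb_chars(cp) == "N"
  snp <- flanked_snp_columns(cp, params$flank_width)
  csN <- c(0, cumsum(isN))
  csS <- c(0L, cumsum(snp))

  # windows with a disqualifying ambiguous run contain a start position of
  # a run of (max_ambiguous_run + 1) consecutive Ns fully inside them
  runlen <- params$max_ambiguous_run + 1L
  bad_start <- if (L >= runlen) {
    cs <- c(0, cumsum(isN))
    (cs[(runlen + 1L):(L + 1L)] - cs[1:(L - runlen + 1L)]) == runlen
  } else {
    logical(0)
  }
  csB <- c(0L, cumsum(bad_start))

  starts <- seq.int(0L, L - B, by = params$step)
  ends <- starts + B
  div <- (csN[ends + 1L] - csN[starts + 1L]) / B
  snps <- csS[ends + 1L] - csS[starts + 1L]
  nbad <- if (length(bad_start)) {
    hi <- pmin(ends - runlen + 1L, length(bad_start))
    n <- csB[hi + 1L] - csB[starts + 1L]
    n[hi < starts] <- 0L
    n
  } else {
    integer(length(starts))
  }

  ok <- div >= params$min_divergence & div <= params$max_divergence &
    nbad == 0L & snps >= params$min_flanked_snps

  empty <- data.frame(id = character(), start = integer(), end = integer(),
                      level = character(), divergence = numeric(),
                      flanked_snp_count = integer(),
                      max_ambig_run = integer(), merged_from = integer())
  if (!any(ok)) return(empty)

  ws <- starts[ok]; we <- ends[ok]
  # merge overlapping/adjacent-overlapping accepted windows (sorted)
  ms <- ws[1L]; me <- we[1L]; mn <- 1L
  blocks <- list()
  flush <- function(s, e, n) {
    iv <- interval(s, e)
    data.frame(start = s, end = e, level = params$level,
               divergence = divergence(cp, iv),
               flanked_snp_count = count_flanked_snps(cp, iv,
                                                      params$flank_width),
               max_ambig_run = max_ambiguous_run(cp, iv),
               merged_from = n)
  }
  if (length(ws) > 1L) {
    for (i in 2L:length(ws)) {
      if (ws[i] < me) {
        me <- max(me, we[i]); mn <- mn + 1L
      } else {
        blocks[[length(blocks) + 1L]] <- flush(ms, me, mn)
        ms <- ws[i]; me <- we[i]; mn <- 1L
      }
    }
  }
  blocks[[length(blocks) + 1L]] <- flush(ms, me, mn)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  cbind(id = sprintf("BC_%s_%03d", params$level, seq_len(nrow(out))), out)
}
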