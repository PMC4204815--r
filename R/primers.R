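#' Primer design constraints
#'
#' Product size range 100-280 mirrors the published Primer3 setting; the
#' 300-base search flank mirrors "300 bp upstream and 300 bp downstream"
#' of a candidate block. Length 18-24 and Tm 52-62 C are the Primer3
#' defaults, which the published pipeline did not override. Primers are
#' never drawn from ambiguous sequence; that rule is not configurable.
#'
#' @param primer_len Length-2 vector, min/max oligo length.
#' @param product_size Length-2 vector, min/max amplicon size in bases.
#' @param tm Length-2 vector, acceptable Tm window in Celsius.
#' @param max_tm_diff Maximum |Tm(fwd) - Tm(rev)| in Celsius.
#' @param gc Length-2 vector, acceptable GC fraction window.
#' @param max_search_flank Bases beyond each target edge searched.
#' @param target_tm Optimum Tm used by the penalty (midpoint by default).
#' @param max_candidates Per-orientation cap on candidates carried into
#'   pairing, best-penalty first (keeps pairing tractable; deterministic).
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len = c(18L, 24L),
                               product_size = c(100L, 280L),
                               tm = c(52, 62),
                               max_tm_diff = 4,
                               gc = c(0.30, 0.70),
                               max_search_flank = 300L,
                               target_tm = mean(tm),
                               max_candidates = 200L) {
  c <- list(primer_len = as.integer(primer_len),
            product_size = as.integer(product_size),
            tm = as.numeric(tm), max_tm_diff = max_tm_diff,
            gc = as.numeric(gc),
            max_search_flank = as.integer(max_search_flank),
            target_tm = target_tm,
            max_candidates = as.integer(max_candidates))
  stopifnot(length(c$primer_len) == 2L, c$primer_len[1L] <= c$primer_len[2L],
            length(c$product_size) == 2L, c$tm[1L] < c$tm[2L],
            c$gc[1L] < c$gc[2L], c$max_search_flank >= 0L)
  if (c$product_size[1L] < 2L * c$primer_len[1L]) {
    stop("product_size min must be >= twice the minimum primer length")
  }
  structure(c, class = "primer_constraints")
}

#' Enumerate conserved primer placements around a target
#'
#' Candidate oligos are substrings of the ambiguous consensus whose
#' columns are all explicit bases (perfectly conserved across the
#' alignment). Forward placements start no more than `max_search_flank`
#' columns upstream of the target start and no later than its last column;
#' reverse placements end no more than `max_search_flank` columns
#' downstream of the target end and no earlier than just past its first
#' column. Placements inside the target are legitimate -- the amplicon
#' must cover polymorphic columns of the target, not the whole target --
#' and are automatically confined to its conserved stretches. Length, GC
#' and Tm windows are applied here.
#'
#' @param cp A `consensus_pair`.
#' @param around Target [interval()].
#' @param constraints A [primer_constraints()] object.
#' @return Data frame: `orientation` (`fwd`/`rev`), `start`, `end`
#'   (template columns, half-open), `seq` (oligo 5'->3'; reverse primers
#'   are the reverse complement of the template segment), `tm`, `gc`.
#' @export
enumerate_conserved_sites <- function(cp, around,
                                      constraints = primer_constraints()) {
  stopifnot(inherits(cp, "consensus_pair"))
  around <- check_bounds(around, cp$length)
  cn <- constraints
  amb <- amb_chars(cp)
  conserved <- amb != "N"
  # conserved run starting at each column (1-based)
  run_from <- rev(run_length_ending(rev(conserved)))
  L <- cp$length

  grid <- function(starts0, lens) {
    g <- data.frame(start = starts0, len = lens)
    g <- g[g$start >= 0L & g$start + g$len <= L, , drop = FALSE]
    g[run_from[g$start + 1L] >= g$len, , drop = FALSE]
  }
  lens <- seq.int(cn$primer_len[1L], cn$primer_len[2L])
  fs <- seq.int(around[["start"]] - cn$max_search_flank,
                around[["end"]] - 1L)
  fg <- grid(rep(fs, each = length(lens)), rep(lens, times = length(fs)))
  re <- seq.int(around[["start"]] + 1L,
                around[["end"]] + cn$max_search_flank)
  rg <- grid(rep(re, each = length(lens)) - rep(lens, times = length(re)),
             rep(lens, times = length(re)))

  mk <- function(g, orientation) {
    if (nrow(g) == 0L) {
      return(data.frame(orientation = character(), start = integer(),
                        end = integer(), seq = character(), tm = numeric(),
                        gc = numeric()))
    }
    tmpl <- vapply(seq_len(nrow(g)), function(i) {
      paste(amb[(g$start[i] + 1L):(g$start[i] + g$len[i])], collapse = "")
    }, character(1L))
    seqs <- if (orientation == "rev") vapply(tmpl, revcomp, character(1L))
            else tmpl
    tm <- vapply(seqs, melting_temperature, numeric(1L))
    gc <- vapply(seqs, gc_fraction, numeric(1L))
    keep <- tm >= cn$tm[1L] & tm <= cn$tm[2L] &
      gc >= cn$gc[1L] & gc <= cn$gc[2L]
    data.frame(orientation = orientation, start = g$start[keep],
               end = g$start[keep] + g$len[keep],
               seq = unname(seqs[keep]), tm = unname(tm[keep]),
               gc = unname(gc[keep]))
  }
  out <- rbind(mk(fg, "fwd"), mk(rg, "rev"))
  out <- out[order(out$orientation, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# candidate-level penalty used for ranking and for the pairing cap
cand_penalty <- function(tm, gc, seq3gc, cn) {
  abs(tm - cn$target_tm) + 10 * pmax(0, abs(gc - 0.5) - 0.1) -
    0.5 * seq3gc
}

#' Design ranked primer pairs around a marker
#'
#' Pairs every forward with every reverse conserved placement (after a
#' per-orientation best-`max_candidates` cap), keeps pairs whose product
#' size is in range, whose amplicon spans at least one polymorphic (N)
#' column of the target, whose Tm difference is within `max_tm_diff`, and
#' whose oligos show no complementarity run of 8 or more bases
#' (dimer screen). Survivors are ranked by a Primer3-style penalty --
#' distance of each Tm from the optimum, GC deviation beyond 0.4-0.6, a
#' 3'-GC-clamp bonus, and excess Tm difference -- with deterministic ties
#' (leftmost forward start, then shortest product).
#'
#' @param cp A `consensus_pair`.
#' @param target Marker [interval()] whose polymorphism the amplicon must
#'   cover.
#' @param constraints A [primer_constraints()] object.
#' @param k Number of pairs to return.
#' @return Data frame of up to `k` pairs: sequences, half-open template
#'   intervals, Tm, GC, `product_size`, `penalty`. When empty, the
#'   attribute `"rejection_histogram"` records how many candidate pairs
#'   each constraint eliminated.
#' @export
design_pairs <- function(cp, target, constraints = primer_constraints(),
                         k = 5L) {
  stopifnot(inherits(cp, "consensus_pair"))
  target <- check_bounds(target, cp$length)
  cn <- constraints
  sites <- enumerate_conserved_sites(cp, target, cn)
  fwd <- sites[sites$orientation == "fwd", , drop = FALSE]
  rev_ <- sites[sites$orientation == "rev", , drop = FALSE]

  empty <- data.frame(fwd_seq = character(), rev_seq = character(),
                      fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      tm_fwd = numeric(), tm_rev = numeric(),
                      gc_fwd = numeric(), gc_rev = numeric(),
                      product_size = integer(), penalty = numeric())
  reasons <- c(no_candidates = 0, product_size = 0, no_polymorphism = 0,
               tm_diff = 0, dimer = 0)
  finish_empty <- function() {
    message("design_pairs: no valid pair; rejections: ",
            paste(names(reasons), reasons, sep = "=", collapse = ", "))
    attr(empty, "rejection_histogram") <- reasons
    empty
  }
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) {
    reasons[["no_candidates"]] <- 1
    return(finish_empty())
  }

  cap <- function(d) {
    pen <- cand_penalty(d$tm, d$gc,
                        substring(d$seq, nchar(d$seq)) %in% c("G", "C"), cn)
    d[order(pen, d$start, d$end), , drop = FALSE][
      seq_len(min(nrow(d), cn$max_candidates)), , drop = FALSE]
  }
  fwd <- cap(fwd); rev_ <- cap(rev_)

  pair <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  prod <- rev_$end[pair$r] - fwd$start[pair$f]
  ok <- prod >= cn$product_size[1L] & prod <= cn$product_size[2L] &
    fwd$end[pair$f] <= rev_$start[pair$r]
  reasons[["product_size"]] <- sum(!ok)
  pair <- pair[ok, , drop = FALSE]; prod <- prod[ok]
  if (nrow(pair) == 0L) return(finish_empty())

  npos <- which(amb_chars(cp) == "N") - 1L
  npos <- npos[npos >= target[["start"]] & npos < target[["end"]]]
  cover <- vapply(seq_len(nrow(pair)), function(i) {
    any(npos >= fwd$start[pair$f[i]] & npos < rev_$end[pair$r[i]])
  }, logical(1L))
  reasons[["no_polymorphism"]] <- sum(!cover)
  pair <- pair[cover, , drop = FALSE]; prod <- prod[cover]
  if (nrow(pair) == 0L) return(finish_empty())

  dtm <- abs(fwd$tm[pair$f] - rev_$tm[pair$r])
  ok <- dtm <= cn$max_tm_diff
  reasons[["tm_diff"]] <- sum(!ok)
  pair <- pair[ok, , drop = FALSE]; prod <- prod[ok]; dtm <- dtm[ok]
  if (nrow(pair) == 0L) return(finish_empty())

  gc3 <- function(s) substring(s, nchar(s)) %in% c("G", "C")
  penalty <- abs(fwd$tm[pair$f] - cn$target_tm) +
    abs(rev_$tm[pair$r] - cn$target_tm) +
    2 * pmax(0, dtm - cn$max_tm_diff / 2) +
    10 * pmax(0, abs(fwd$gc[pair$f] - 0.5) - 0.1) +
    10 * pmax(0, abs(rev_$gc[pair$r] - 0.5) - 0.1) -
    0.5 * gc3(fwd$seq[pair$f]) - 0.5 * gc3(rev_$seq[pair$r])

  ord <- order(penalty, fwd$start[pair$f], prod)
  out <- list()
  n_dimer <- 0
  for (i in ord) {
    f <- pair$f[i]; r <- pair$r[i]
    # dimer screen: a run of >= 8 complementary bases between the oligos
    # is a common substring of fwd and revcomp(rev) (= template segment)
    if (longest_common_substring(fwd$seq[f], revcomp(rev_$seq[r])) >= 8L) {
      n_dimer <- n_dimer + 1
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      fwd_seq = fwd$seq[f], rev_seq = rev_$seq[r],
      fwd_start = fwd$start[f], fwd_end = fwd$end[f],
      rev_start = rev_$start[r], rev_end = rev_$end[r],
      tm_fwd = fwd$tm[f], tm_rev = rev_$tm[r],
      gc_fwd = fwd$gc[f], gc_rev = rev_$gc[r],
      product_size = rev_$end[r] - fwd$start[f],
      penalty = penalty[i])
    if (length(out) == k) break
  }
  reasons[["dimer"]] <- n_dimer
  if (length(out) == 0L) return(finish_empty())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejection_histogram") <- reasons
  res
}
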