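# lexicographically smallest rotation; fixed-strand canonical form
canonical_rotation <- function(motif) {
  n <- nchar(motif)
  rots <- vapply(seq_len(n) - 1L, function(k) {
    paste0(substring(motif, k + 1L, n), substring(motif, 1L, k))
  }, character(1L))
  min(rots)
}

#' Find perfect di-/tri-nucleotide tandem repeats
#'
#' Scans a best-base consensus track for maximal perfect tandem runs with
#' at least `min_units` complete units. Runs never span a `-` column,
#' partial trailing units are excluded from the span, and homopolymers
#' disguised as di-/tri-repeats (`AA`, `AAA`, ...) are rejected --
#' homopolymer SSRs are technically unreliable markers. Motifs are
#' canonicalized to their lexicographically smallest rotation (the
#' consensus has a fixed strand, so no reverse-complement collapsing).
#'
#' @param track Best-base consensus string over `{A,C,G,T,-}`, or a
#'   `consensus_pair` (its `best_base` is used).
#' @param unit_lens Repeat unit lengths to scan, subset of `c(2, 3)` by
#'   contract (other lengths work but are outside the marker design).
#' @param min_units Minimum complete-unit count (>= 2); default 4.
#' @return Data frame (one row per locus, sorted by start then unit
#'   length): `id`, `start`, `end` (0-based half-open columns), `motif`
#'   (canonical), `unit_len`, `units`.
#' @export
#' @examples
#' find_perfect_repeats("GGATATATATGG")
find_perfect_repeats <- function(track, unit_lens = c(2L, 3L),
                                 min_units = 4L) {
  if (inherits(track, "consensus_pair")) track <- track$best_base
  stopifnot(is.character(track), length(track) == 1L)
  min_units <- as.integer(min_units)
  if (min_units < 2L) stop("min_units must be >= 2")
  ch <- strsplit(track, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c(DNA_BASES4, "-"))) {
    stop("best-base track may only contain A, C, G, T, -")
  }

  loci <- list()
  # contiguous gap-free segments
  nog <- ch != "-"
  r <- rle(nog)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  for (s in which(r$values)) {
    lo <- seg_start[s]; hi <- seg_end[s]           # 1-based inclusive
    for (u in as.integer(unit_lens)) {
      if (hi - lo + 1L < u * min_units) next
      i <- lo:(hi - u)
      eq <- ch[i] == ch[i + u]
      er <- rle(eq)
      ee <- cumsum(er$lengths)
      es <- ee - er$lengths + 1L
      for (k in which(er$values)) {
        m <- er$lengths[k]
        units <- (m + u) %/% u
        if (units < min_units) next
        start1 <- i[es[k]]                          # 1-based run start
        motif <- paste(ch[start1:(start1 + u - 1L)], collapse = "")
        if (length(unique(strsplit(motif, "", fixed = TRUE)[[1L]])) == 1L) {
          next                                      # homopolymer
        }
        loci[[length(loci) + 1L]] <- data.frame(
          start = start1 - 1L,
          end = start1 - 1L + units * u,
          motif = canonical_rotation(motif),
          unit_len = u,
          units = units)
      }
    }
  }
  if (length(loci) == 0L) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      units = integer()))
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  # identical spans across unit lengths collapse to the smaller unit
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  cbind(id = sprintf("SSR_%03d", seq_len(nrow(out))), out)
}

#' Screen repeat loci for cross-taxon polymorphism
#'
#' A repeat is called polymorphic when an ambiguous (`N`) column of the
#' ambiguous consensus lies inside the repeat span or within `proximity`
#' bases of either boundary: length variation at the repeat, or variation
#' immediately beside it, shows up as non-conserved columns there.
#' Offsets are measured from the span: an N inside is offset 0, one
#' adjacent to the boundary is offset 1.
#'
#' @param loci Data frame from [find_perfect_repeats()].
#' @param ambiguous Ambiguous consensus string, or a `consensus_pair`.
#' @param proximity Maximum qualifying offset in bases (default 4).
#' @return `loci` with `polymorphic` (logical) and
#'   `nearest_ambiguous_offset` (integer; `NA` when the track has no N at
#'   all) appended. Non-polymorphic loci are retained, flagged `FALSE`.
#' @export
screen_polymorphic <- function(loci, ambiguous, proximity = 4L) {
  if (inherits(ambiguous, "consensus_pair")) ambiguous <- ambiguous$ambiguous
  stopifnot(is.data.frame(loci))
  proximity <- as.integer(proximity)
  npos <- which(strsplit(ambiguous, "", fixed = TRUE)[[1L]] == "N") - 1L

  off <- rep(NA_integer_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    s <- loci$start[i]; e <- loci$end[i]
    if (length(npos) == 0L) next
    if (any(npos >= s & npos < e)) {
      off[i] <- 0L
    } else {
      left <- npos[npos < s]
      right <- npos[npos >= e]
      d <- c(if (length(left)) s - max(left),
             if (length(right)) min(right) - e + 1L)
      off[i] <- min(d)
    }
  }
  loci$polymorphic <- !is.na(off) & off <= proximity
  loci$nearest_ambiguous_offset <- off
  loci
}
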