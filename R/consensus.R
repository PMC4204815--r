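#' Build the best-base and ambiguous consensus tracks
#'
#' Two per-column tracks of the same length as the alignment:
#'
#' * `best_base` -- the majority base per column, gaps and N excluded from
#'   the vote; ties broken in fixed order A < C < G < T; a column with no
#'   votes at all (all gaps, or all N) yields `-`.
#' * `ambiguous` -- an explicit base only where every row carries that same
#'   base (no mismatch, no gap, no N); `N` otherwise. Explicit bases mark
#'   perfectly conserved columns and are the only sequence primers may be
#'   drawn from.
#'
#' Both tracks keep full alignment length so SSR, block and primer
#' coordinates share one frame; downstream scans skip `-` columns of
#' `best_base` rather than compressing them out.
#'
#' @param a A `plast_alignment` with >= 2 rows.
#' @return An object of class `consensus_pair`: list with `best_base` and
#'   `ambiguous` (strings of length L), `is_substitution` (logical per
#'   column: every row has an A/C/G/T base and not all agree -- i.e. the
#'   column's ambiguity stems from a point substitution, not an indel or
#'   N), `source_ids`, `maps` (per row, 0-based gapless-position to column
#'   index vector and its inverse) and `length`.
#' @export
build_consensus_pair <- function(a) {
  stopifnot(inherits(a, "plast_alignment"))
  n <- nrow(a$mat)
  if (n < 2L) stop("consensus undefined for a single-row alignment")
  L <- a$length

  counts <- vapply(DNA_BASES4, function(b) colSums(a$mat == b),
                   numeric(L))            # L x 4
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, DNA_BASES4))
  votes <- rowSums(counts)
  top <- do.call(pmax, as.data.frame(counts))

  best <- DNA_BASES4[max.col(counts, ties.method = "first")]
  best[votes == 0] <- "-"
  all_n_cols <- votes == 0 & colSums(a$mat == "N") > 0
  if (any(all_n_cols)) {
    warning(sum(all_n_cols), " all-N column(s) recorded as '-' in the ",
            "best-base track")
  }

  conserved <- top == n                    # all rows same A/C/G/T base
  amb <- ifelse(conserved, best, "N")
  is_subst <- (votes == n) & !conserved    # all bases present, disagreement

  maps <- lapply(seq_len(n), function(r) {
    cols <- which(a$mat[r, ] != "-")
    col_to_gapless <- rep(NA_integer_, L)
    col_to_gapless[cols] <- seq_along(cols) - 1L
    list(gapless_to_col = cols - 1L, col_to_gapless = col_to_gapless)
  })
  names(maps) <- a$ids

  structure(list(best_base = paste(best, collapse = ""),
                 ambiguous = paste(amb, collapse = ""),
                 is_substitution = is_subst,
                 source_ids = a$ids,
                 maps = maps,
                 length = L),
            class = "consensus_pair")
}

#' @export
print.consensus_pair <- function(x, ...) {
  nN <- sum(strsplit(x$ambiguous, "", fixed = TRUE)[[1L]] == "N")
  cat("<consensus_pair> ", x$length, " columns from ",
      length(x$source_ids), " sequences; ", nN, " ambiguous column(s) (",
      sprintf("%.2f%%", 100 * nN / x$length), ")\n", sep = "")
  invisible(x)
}

amb_chars <- function(cp) strsplit(cp$ambiguous, "", fixed = TRUE)[[1L]]
bb_chars <- function(cp) strsplit(cp$best_base, "", fixed = TRUE)[[1L]]

#' Fraction of non-conserved columns in a region
#'
#' Divergence of a region is the fraction of its columns that are ambiguous
#' (`N`) in the ambiguous track -- any mismatch, gap or N in any row makes
#' a column count. This single definition feeds both the lower (>= 2%) and
#' upper (10%/15%) block filters.
#'
#' @param cp A `consensus_pair`.
#' @param iv An [interval()].
#' @return Fraction in `[0, 1]`.
#' @export
divergence <- function(cp, iv) {
  stopifnot(inherits(cp, "consensus_pair"))
  iv <- check_bounds(iv, cp$length)
  mean(amb_chars(cp)[iv_idx(iv)] == "N")
}

#' Sliding percent-identity profile along an alignment
#'
#' Identity per window is `1 - divergence` under the ambiguous-track
#' definition. A final partial window is included and flagged.
#'
#' @param a A `plast_alignment`.
#' @param window Window width in columns (`1 <= window <= L`).
#' @param step Stride in columns (>= 1).
#' @return Data frame with `start`, `end` (0-based half-open), `identity`,
#'   `partial`.
#' @export
sliding_identity_profile <- function(a, window, step = window) {
  stopifnot(inherits(a, "plast_alignment"))
  window <- as.integer(window); step <- as.integer(step)
  L <- a$length
  if (window < 1L || window > L) {
    stop("window must be in [1, ", L, "], got ", window)
  }
  if (step < 1L) stop("step must be >= 1")

  cp <- build_consensus_pair(a)
  isN <- amb_chars(cp) == "N"
  cs <- c(0, cumsum(isN))

  starts <- seq.int(0L, L - window, by = step)
  ends <- starts + window
  partial <- rep(FALSE, length(starts))
  s <- starts[length(starts)] + step       # one trailing partial window
  if (max(ends) < L && s < L) {
    starts <- c(starts, s)
    ends <- c(ends, L)
    partial <- c(partial, TRUE)
  }
  nN <- cs[ends + 1L] - cs[starts + 1L]
  data.frame(start = starts, end = ends,
             identity = 1 - nN / (ends - starts),
             partial = partial)
}

#' Write the two consensus tracks as a 2-record FASTA
#' @param cp A `consensus_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(cp, path) {
  stopifnot(inherits(cp, "consensus_pair"))
  set <- Biostrings::BStringSet(c(best_base = cp$best_base,
                                  ambiguous = cp$ambiguous))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
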