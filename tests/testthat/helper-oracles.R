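# Shared fixtures and independent brute-force oracles. Oracles deliberately
# recompute everything per position/window from the raw characters instead of
# reusing the package's vectorized internals.

make_aln <- function(rows, ids = paste0("t", seq_along(rows))) {
  new_alignment(rows, ids)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# ---- consensus oracle: per-column loops over rows --------------------------

oracle_consensus <- function(a) {
  L <- a$length
  best <- character(L)
  amb <- character(L)
  for (i in seq_len(L)) {
    col <- a$mat[, i]
    votes <- col[col %in% c("A", "C", "G", "T")]
    if (length(votes) == 0L) {
      best[i] <- "-"
    } else {
      tab <- table(factor(votes, levels = c("A", "C", "G", "T")))
      best[i] <- names(tab)[which.max(tab)]   # which.max -> first, A<C<G<T
    }
    amb[i] <- if (length(unique(col)) == 1L &&
                  col[1L] %in% c("A", "C", "G", "T")) col[1L] else "N"
  }
  list(best_base = paste(best, collapse = ""),
       ambiguous = paste(amb, collapse = ""))
}

# ---- SSR oracle: test every (start, unit_len) anchor ------------------------

oracle_find_repeats <- function(track, unit_lens = c(2L, 3L),
                                min_units = 4L) {
  ch <- chars(track)
  L <- length(ch)
  eq <- function(j, u) {                    # 0-based j; unit bridging j..j+u
    if (j < 0L || j + u >= L) return(FALSE)
    seg <- ch[(j + 1L):(j + u + 1L)]
    all(seg != "-") && ch[j + 1L] == ch[j + u + 1L]
  }
  rot_min <- function(m) {
    n <- nchar(m)
    min(vapply(seq_len(n), function(k) {
      paste0(substring(m, k, n), substring(m, 1L, k - 1L))
    }, character(1L)))
  }
  out <- list()
  for (u in unit_lens) {
    for (s in 0:(L - 1L)) {
      if (!eq(s, u)) next
      if (eq(s - 1L, u)) next               # not left-maximal
      t <- 0L
      while (eq(s + t, u)) t <- t + 1L
      units <- (t + u) %/% u
      if (units < min_units) next
      motif <- paste(ch[(s + 1L):(s + u)], collapse = "")
      if (length(unique(chars(motif))) == 1L) next
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = s + units * u, motif = rot_min(motif),
        unit_len = u, units = units)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      units = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  res <- res[!duplicated(res[c("start", "end")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- barcode oracle: re-evaluate all criteria at every offset ---------------

oracle_scan_blocks <- function(a, p) {
  L <- a$length
  B <- p$block_len
  # column classification once (per-column loops), window stats per offset
  n <- nrow(a$mat)
  amb <- character(L)
  subst <- logical(L)
  for (i in seq_len(L)) {
    col <- a$mat[, i]
    amb[i] <- if (length(unique(col)) == 1L &&
                  col[1L] %in% c("A", "C", "G", "T")) col[1L] else "N"
    subst[i] <- all(col %in% c("A", "C", "G", "T")) &&
      length(unique(col)) > 1L
  }
  flanked <- logical(L)
  for (i in seq_len(L)) {
    if (amb[i] != "N" || !subst[i]) next
    lo <- i - p$flank_width; hi <- i + p$flank_width
    if (lo < 1L || hi > L) next
    flanked[i] <- all(amb[lo:(i - 1L)] != "N") &&
      all(amb[(i + 1L):hi] != "N")
  }
  acc <- list()
  for (s in seq.int(0L, L - B)) {
    idx <- (s + 1L):(s + B)
    isN <- amb[idx] == "N"
    div <- mean(isN)
    r <- rle(isN)
    mrun <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    snps <- sum(flanked[idx])
    if (div >= p$min_divergence && div <= p$max_divergence &&
        mrun <= p$max_ambiguous_run && snps >= p$min_flanked_snps) {
      acc[[length(acc) + 1L]] <- c(s, s + B)
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      merged_from = integer()))
  }
  m <- do.call(rbind, acc)
  out <- list()
  cs <- m[1L, 1L]; ce <- m[1L, 2L]; cn <- 1L
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      if (m[i, 1L] < ce) {
        ce <- max(ce, m[i, 2L]); cn <- cn + 1L
      } else {
        out[[length(out) + 1L]] <- c(cs, ce, cn)
        cs <- m[i, 1L]; ce <- m[i, 2L]; cn <- 1L
      }
    }
  }
  out[[length(out) + 1L]] <- c(cs, ce, cn)
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("start", "end", "merged_from")
  res
}

# ---- random fixture generators ---------------------------------------------

# random family alignment with mutations, gaps, N's and a variable patch
random_test_alignment <- function(L = 2000L, n = 5L, p_mut = 0.01,
                                  p_gap = 0.002, p_n = 0.001,
                                  patch = TRUE) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  hot <- rep(1, L)
  if (patch && L >= 500L) {
    ps <- sample.int(L - 400L, 1L)
    hot[ps:(ps + 299L)] <- 12
  }
  mat <- matrix(rep(base, each = n), nrow = n)
  for (r in 2:n) {
    mut <- runif(L) < pmin(0.5, p_mut * hot)
    mat[r, mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    gap <- runif(L) < p_gap
    mat[r, gap] <- "-"
    nn <- runif(L) < p_n
    mat[r, nn] <- "N"
  }
  new_alignment(apply(mat, 1L, paste, collapse = ""),
                paste0("t", seq_len(n)))
}

# repeat-rich random track over {A,C,G,T,-} for SSR oracle testing
random_repeat_track <- function(len = 200L) {
  out <- character(0L)
  while (sum(nchar(out)) < len) {
    piece <- switch(sample.int(4L, 1L),
      paste(sample(c("A", "C", "G", "T"), sample(3:12, 1L),
                   replace = TRUE), collapse = ""),
      strrep(paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                   collapse = ""), sample(2:7, 1L)),
      strrep(paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                   collapse = ""), sample(2:6, 1L)),
      strrep("-", sample(1:3, 1L)))
    out <- c(out, piece)
  }
  substr(paste(out, collapse = ""), 1L, len)
}

# conserved-backbone alignment builder for threshold fixtures: start from a
# fixed pseudo-random backbone, then force substitution SNPs (row 2 differs)
# or indel columns (gap in row 2) at chosen 0-based columns
backbone_alignment <- function(L, n = 3L, snp_at = integer(),
                               indel_at = integer(), n_at = integer(),
                               seed = 424242L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), nrow = n)
  swap <- c(A = "C", C = "A", G = "T", T = "G")   # transversion-ish swap
  for (i in snp_at) mat[2L, i + 1L] <- swap[[base[i + 1L]]]
  for (i in indel_at) mat[2L, i + 1L] <- "-"
  for (i in n_at) mat[2L, i + 1L] <- "N"
  new_alignment(apply(mat, 1L, paste, collapse = ""),
                paste0("t", seq_len(n)))
}
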