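PURINES <- c("A", "G")

#' Kimura two-parameter distance between two aligned rows
#'
#' Columns where either row carries a gap or N are excluded (pairwise
#' deletion). `P` is the transition fraction (A<->G, C<->T), `Q` the
#' transversion fraction, and `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`
#' substitutions per site. When a log argument is non-positive the
#' distance is saturated: `d` is `NA` and `saturated` is `TRUE`.
#'
#' @param rowA,rowB Aligned sequence strings of equal length.
#' @return List with `P`, `Q`, `d`, `saturated`, `n_sites` (usable
#'   columns).
#' @export
k80_distance <- function(rowA, rowB) {
  a <- strsplit(toupper(rowA), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(rowB), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("rows differ in length")
  use <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  n <- sum(use)
  if (n == 0L) stop("no usable (gap- and N-free) columns")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(P = P, Q = Q, d = NA_real_, saturated = TRUE, n_sites = n))
  }
  list(P = P, Q = Q, d = -0.5 * log(w1 * sqrt(w2)), saturated = FALSE,
       n_sites = n)
}

#' Pairwise K80 distance matrix for an alignment
#'
#' @param a A `plast_alignment`.
#' @return List of class `k80_dist`: `ids`, `d` (symmetric matrix, `NA`
#'   where saturated), `saturated` (logical matrix).
#' @export
k80_distance_matrix <- function(a) {
  stopifnot(inherits(a, "plast_alignment"))
  rows <- alignment_strings(a)
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(a$ids, a$ids))
  sat <- matrix(FALSE, n, n, dimnames = list(a$ids, a$ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        k <- k80_distance(rows[[i]], rows[[j]])
        d[i, j] <- d[j, i] <- k$d
        sat[i, j] <- sat[j, i] <- k$saturated
      }
    }
  }
  structure(list(ids = a$ids, d = d, saturated = sat), class = "k80_dist")
}

#' Neighbor-joining tree from a K80 distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) with taxa pre-sorted by id
#' so that ties resolve deterministically. Negative branch lengths are
#' clamped to zero with a warning. If an outgroup is given the tree is
#' rooted on its pendant edge.
#'
#' @param dm A `k80_dist` (or a plain symmetric matrix with dimnames).
#' @param outgroup Optional tip id to root on.
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  if (inherits(dm, "k80_dist")) {
    if (any(dm$saturated)) {
      bad <- which(dm$saturated, arr.ind = TRUE)[1L, ]
      stop("saturated K80 distance between '", dm$ids[bad[1L]], "' and '",
           dm$ids[bad[2L]], "'")
    }
    d <- dm$d
  } else {
    d <- as.matrix(dm)
  }
  if (nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("unknown outgroup: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE,
                    edgelabel = TRUE)
  }
  tr
}

#' Bootstrap-supported neighbor-joining tree
#'
#' Builds the full-data K80/NJ tree, then resamples alignment columns with
#' replacement `n_reps` times; the support of each internal edge is the
#' percentage of replicate trees containing the same bipartition
#' (unrooted comparison). Supports are stored as node labels.
#'
#' @param a A `plast_alignment`.
#' @param n_reps Number of bootstrap replicates (>= 1); 50 by default.
#' @param seed Integer seed; resampling is fully reproducible.
#' @param outgroup Optional tip id to root the returned tree on.
#' @return A `phylo` tree with `node.label` holding integer percent
#'   supports (root label empty).
#' @export
bootstrap_support <- function(a, n_reps = 50L, seed = 1L, outgroup = NULL) {
  stopifnot(inherits(a, "plast_alignment"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ref <- nj_tree(k80_distance_matrix(a))

  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(a$length, a$length, replace = TRUE)
      b <- structure(list(ids = a$ids,
                          mat = a$mat[, cols, drop = FALSE],
                          length = a$length),
                     class = "plast_alignment")
      tryCatch(nj_tree(k80_distance_matrix(b)), error = function(e) NULL)
    })
  })
  failed <- vapply(boots, is.null, logical(1L))
  if (any(failed)) {
    warning(sum(failed), " bootstrap replicate(s) failed (saturated ",
            "distances) and were dropped from the denominator")
    boots <- boots[!failed]
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(boots))
  lab <- as.character(support)
  lab[1L] <- ""                                    # root pseudo-node
  ref$node.label <- lab
  if (!is.null(outgroup)) {
    if (!outgroup %in% ref$tip.label) stop("unknown outgroup: ", outgroup)
    ref <- ape::root(ref, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE)
  }
  ref
}
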