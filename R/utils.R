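#' Construct a half-open column interval
#'
#' Intervals are 0-based half-open `[start, end)` on alignment columns,
#' matching the BED convention used by every exported table.
#'
#' @param start 0-based inclusive start column.
#' @param end 0-based exclusive end column; must exceed `start`.
#' @return An integer vector of length 2 with names `start`, `end` and class
#'   `"plast_interval"`.
#' @export
#' @examples
#' interval(100, 400)
interval <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L) stop("interval start must be >= 0, got ", start)
  if (end <= start) {
    stop("interval must be non-empty half-open [start, end): start=", start,
         " end=", end)
  }
  structure(c(start = start, end = end), class = "plast_interval")
}

as_interval <- function(iv) {
  if (inherits(iv, "plast_interval")) return(iv)
  if (length(iv) != 2L) stop("an interval is a (start, end) pair")
  interval(iv[[1L]], iv[[2L]])
}

check_bounds <- function(iv, len) {
  iv <- as_interval(iv)
  if (iv[["end"]] > len) {
    stop("interval [", iv[["start"]], ", ", iv[["end"]],
         ") out of bounds for length ", len)
  }
  iv
}

iv_width <- function(iv) iv[["end"]] - iv[["start"]]

# 1-based R indices for the columns of a 0-based half-open interval
iv_idx <- function(iv) seq.int(iv[["start"]] + 1L, iv[["end"]])

DNA_BASES4 <- c("A", "C", "G", "T")

revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  comp <- chartr("ACGT", "TGCA", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

gc_fraction <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  mean(ch %in% c("G", "C"))
}

# length of longest common substring of two short strings (used for the
# primer-dimer complementarity screen; O(nm) is fine at oligo scale)
longest_common_substring <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ca); m <- length(cb)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- which(cb == ca[i])
    if (length(hit)) {
      cur[hit] <- 1L
      inner <- hit[hit > 1L]
      cur[inner] <- prev[inner - 1L] + 1L
      best <- max(best, cur)
    }
    prev <- cur
  }
  best
}

# run length of TRUEs ending at each position (0 where FALSE)
run_length_ending <- function(x) {
  r <- rle(x)
  sequence(r$lengths) * rep(r$values, r$lengths)
}

# longest TRUE run in a logical vector
max_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# evaluate thunk with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
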