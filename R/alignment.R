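ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
# non-N IUPAC degeneracy codes are demoted to N: real plastome assemblies
# carry them where read support was ambiguous
IUPAC_TO_N <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a validated multiple sequence alignment
#'
#' Rows are equal-length strings over `{A,C,G,T,N,-}`. Input is normalized:
#' lowercase is uppercased, `U` becomes `T`, `.` becomes `-`, and any
#' non-`N` IUPAC ambiguity code is demoted to `N` (with a warning), because
#' assembly consensus callers emit them where coverage is thin.
#'
#' @param rows Character vector of aligned sequences.
#' @param ids Character vector of unique, non-empty identifiers.
#' @return An object of class `plast_alignment`: a list with `ids`, `mat`
#'   (character matrix, one row per sequence, one column per alignment
#'   column) and `length` (column count).
#' @export
#' @examples
#' new_alignment(c("ACGT", "ACGT"), c("s1", "s2"))
new_alignment <- function(rows, ids = NULL) {
  rows <- as.character(rows)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  ids <- as.character(ids)
  if (length(rows) == 0L) stop("alignment has no sequences")
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (any(!nzchar(ids))) stop("empty sequence id")

  rows <- toupper(rows)
  rows <- chartr("U.", "T-", rows)
  lens <- nchar(rows)
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged alignment: row '", ids[bad], "' has length ", lens[bad],
         " but '", ids[1L], "' has length ", lens[1L])
  }

  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), byrow = TRUE)
  demote <- mat %in% IUPAC_TO_N
  if (any(demote)) {
    warning(sum(demote), " non-N IUPAC ambiguity code(s) demoted to N")
    mat[demote] <- "N"
  }
  bad <- !(mat %in% ALN_ALPHABET)
  if (any(bad)) {
    stop("invalid character(s) in alignment: ",
         paste(unique(mat[bad]), collapse = " "))
  }
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, length = ncol(mat)),
            class = "plast_alignment")
}

#' @export
print.plast_alignment <- function(x, ...) {
  cat("<plast_alignment> ", length(x$ids), " sequences x ", x$length,
      " columns\n", sep = "")
  for (i in seq_along(x$ids)) {
    s <- paste(x$mat[i, seq_len(min(50L, x$length))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", x$ids[i], s,
                if (x$length > 50L) "..." else ""))
  }
  invisible(x)
}

#' Collapse alignment rows back to strings
#' @param a A `plast_alignment`.
#' @return Named character vector of aligned sequences.
#' @export
alignment_strings <- function(a) {
  stopifnot(inherits(a, "plast_alignment"))
  setNames(apply(a$mat, 1L, paste, collapse = ""), a$ids)
}

#' Read an aligned FASTA file
#'
#' Requires at least two records of identical length. See
#' [new_alignment()] for character normalization rules.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `plast_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) < 2L) stop("alignment requires >= 2 records, got ",
                             length(set))
  ids <- sub("\\s.*$", "", names(set))
  new_alignment(as.character(set), ids)
}

#' Write an alignment (or consensus pair) as FASTA
#' @param a A `plast_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "plast_alignment"))
  set <- Biostrings::BStringSet(alignment_strings(a))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a column range from an alignment
#'
#' @param a A `plast_alignment`.
#' @param iv An [interval()] (0-based half-open columns).
#' @return A `plast_alignment` over columns `[start, end)`; ids and row
#'   order preserved.
#' @export
slice_alignment <- function(a, iv) {
  stopifnot(inherits(a, "plast_alignment"))
  iv <- check_bounds(iv, a$length)
  mat <- a$mat[, iv_idx(iv), drop = FALSE]
  structure(list(ids = a$ids, mat = mat, length = ncol(mat)),
            class = "plast_alignment")
}

#' Write a marker table as TSV plus BED6
#'
#' Emits `<stem>.tsv` with every column of `markers` (plus `start_1based`)
#' and a BED6 companion `<stem>.bed`. BED score is a scaled polymorphism
#' count capped at 1000: 25 points per flanked SNP (barcode blocks) or per
#' repeat unit (SSRs).
#'
#' @param markers Data frame with at least `id`, `start`, `end` columns in
#'   one shared 0-based half-open coordinate frame.
#' @param stem Output path stem (no extension).
#' @param chrom Name used in the BED chrom field (the consensus frame).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_marker_table <- function(markers, stem, chrom = "consensus") {
  stopifnot(is.data.frame(markers))
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  tsv <- paste0(stem, ".tsv")
  bed <- paste0(stem, ".bed")

  out <- markers
  if (nrow(out) > 0L && all(c("start", "end") %in% names(out))) {
    out$start_1based <- out$start + 1L
  }
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  if (nrow(markers) == 0L) {
    file.create(bed)
  } else {
    count <- if ("flanked_snp_count" %in% names(markers)) {
      markers$flanked_snp_count
    } else if ("units" %in% names(markers)) {
      markers$units
    } else {
      0L
    }
    bed6 <- data.frame(chrom = chrom,
                       start = markers$start,
                       end = markers$end,
                       name = markers$id,
                       score = pmin(1000L, as.integer(count) * 25L),
                       strand = "+")
    write.table(bed6, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv = tsv, bed = bed))
}
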