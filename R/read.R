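#' Construct a single sequencing read
#'
#' A read is a header, an upper-case sequence over `{A,C,G,T,N}`, and one
#' integer Phred quality per base. Qualities are clamped to `[0, 60]`;
#' reads without qualities (e.g. FASTA input) get a constant default.
#'
#' @param id Header text (without the leading `@`).
#' @param seq Base sequence; coerced to upper case.
#' @param qual Integer Phred scores, one per base, or `NULL` to use
#'   `default_qual` throughout.
#' @param default_qual Constant quality assigned when `qual` is `NULL`.
#' @return An object of class `pe_read` with fields `id`, `seq`, `qual`.
#' @examples
#' r <- read_new("r1", "ACGT", c(30, 30, 20, 20))
#' reverse_complement(r)
#' @export
read_new <- function(id, seq, qual = NULL, default_qual = 30L) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) < 1L)
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", seq)) {
    bad <- regexpr("[^ACGTN]", seq)
    stop(sprintf("illegal base '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  if (is.null(qual)) qual <- rep.int(as.integer(default_qual), nchar(seq))
  qual <- as.integer(qual)
  if (length(qual) != nchar(seq))
    stop("quality length must equal sequence length")
  qual <- pmin(pmax(qual, 0L), 60L)
  structure(list(id = as.character(id), seq = seq, qual = qual),
            class = "pe_read")
}

#' @export
print.pe_read <- function(x, ...) {
  cat(sprintf("<pe_read> %s\n  %s\n  Q: %s\n", x$id,
              x$seq, paste(x$qual, collapse = " ")))
  invisible(x)
}

#' Reverse-complement a read
#'
#' Complements the sequence (`N` maps to `N`), reverses it, and reverses the
#' quality vector. Applying it twice returns the original read.
#'
#' @param r A `pe_read`.
#' @return The reverse-complemented `pe_read`.
#' @export
reverse_complement <- function(r) {
  stopifnot(inherits(r, "pe_read"))
  read_new(r$id, cpp_revcomp(r$seq), rev(r$qual))
}

# ---------------------------------------------------------------- read sets

# Column-oriented container for many reads: parallel vectors id/seq plus a
# list of integer quality vectors. Cheap to slice and to hand to the C++
# engine in one call.
new_read_set <- function(id, seq, qual) {
  structure(list(id = as.character(id), seq = as.character(seq), qual = qual),
            class = "pe_reads")
}

#' Bundle reads into a read set
#'
#' @param id Character vector of headers.
#' @param seq Character vector of sequences.
#' @param qual List of integer quality vectors (or `NULL` for constant
#'   `default_qual`).
#' @param default_qual Quality used when `qual` is `NULL`.
#' @return A `pe_reads` object.
#' @export
read_set <- function(id, seq, qual = NULL, default_qual = 30L) {
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have equal length")
  if (is.null(qual))
    qual <- lapply(nchar(seq), function(n) rep.int(as.integer(default_qual), n))
  if (length(qual) != length(seq))
    stop("qual must have one vector per read")
  qual <- lapply(qual, function(q) pmin(pmax(as.integer(q), 0L), 60L))
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad))
    stop(sprintf("quality length mismatch for read %d ('%s')",
                 bad[1], id[bad[1]]))
  new_read_set(id, seq, qual)
}

#' @export
length.pe_reads <- function(x) length(x$id)

#' @export
`[.pe_reads` <- function(x, i) new_read_set(x$id[i], x$seq[i], x$qual[i])

#' @export
print.pe_reads <- function(x, ...) {
  cat(sprintf("<pe_reads> %d reads\n", length(x)))
  n <- min(3L, length(x))
  for (i in seq_len(n))
    cat(sprintf("  [%d] %s  %s%s\n", i, x$id[i],
                substr(x$seq[i], 1, 40),
                if (nchar(x$seq[i]) > 40) "..." else ""))
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

# extract one read
read_at <- function(x, i) read_new(x$id[i], x$seq[i], x$qual[[i]])

# ------------------------------------------------------------- read pairs

# Pair-id match key: strip a trailing /1 or /2 and anything after the first
# whitespace (covers old and new Illumina header styles).
strip_mate_id <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

#' Bundle two read sets into pairs
#'
#' Read 2 is stored as sequenced (not reverse-complemented). Mate ids must
#' agree after stripping a trailing `/1`/`/2` or any space-delimited suffix.
#'
#' @param r1,r2 `pe_reads` of equal length.
#' @param check Validate mate id agreement (default `TRUE`).
#' @return A `pe_pairs` object.
#' @export
read_pairs_new <- function(r1, r2, check = TRUE) {
  stopifnot(inherits(r1, "pe_reads"), inherits(r2, "pe_reads"))
  if (length(r1) != length(r2))
    stop(sprintf("unequal read counts: %d vs %d", length(r1), length(r2)))
  if (check && length(r1)) {
    k1 <- strip_mate_id(r1$id)
    k2 <- strip_mate_id(r2$id)
    bad <- which(k1 != k2)
    if (length(bad))
      stop(sprintf("mismatched pair ids at record %d: '%s' vs '%s'",
                   bad[1], r1$id[bad[1]], r2$id[bad[1]]))
  }
  structure(list(r1 = r1, r2 = r2), class = "pe_pairs")
}

#' @export
length.pe_pairs <- function(x) length(x$r1)

#' @export
`[.pe_pairs` <- function(x, i) read_pairs_new(x$r1[i], x$r2[i], check = FALSE)

#' @export
print.pe_pairs <- function(x, ...) {
  cat(sprintf("<pe_pairs> %d read pairs, read lengths %s/%s\n", length(x),
              if (length(x)) nchar(x$r1$seq[1]) else "-",
              if (length(x)) nchar(x$r2$seq[1]) else "-"))
  invisible(x)
}
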