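#' Detect FASTQ quality encoding from sample quality lines
#'
#' Applies the classic codepoint rule: any character below codepoint 59
#' forces Phred+33 (`ascii33`); if all codepoints are at least 64 and at
#' least one exceeds 74 (impossible as Phred+33 for Illumina-range
#' qualities) the sample is Phred+64 (`ascii64`). Samples whose codepoints
#' decode legally under both conventions are undecidable: a warning is
#' issued and `ascii33` is returned as the default.
#'
#' @param sample_lines Character vector of raw quality lines.
#' @return `"ascii33"` or `"ascii64"`.
#' @examples
#' detect_quality_encoding("II!IIII")   # ascii33
#' detect_quality_encoding("hhhhfgh")   # ascii64
#' @export
detect_quality_encoding <- function(sample_lines) {
  sample_lines <- sample_lines[nzchar(sample_lines)]
  if (!length(sample_lines))
    stop("at least one non-empty quality line is required")
  cp <- utf8ToInt(paste(sample_lines, collapse = ""))
  if (any(cp < 59)) {
    "ascii33"
  } else if (all(cp >= 64) && any(cp > 74)) {
    "ascii64"
  } else {
    warning("quality encoding undecidable from sample; defaulting to ascii33")
    "ascii33"
  }
}

# gzip magic bytes 0x1f 0x8b
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_text_input <- function(path) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
}

# peek at the first non-empty line to decide fastq vs fasta
sniff_format <- function(path) {
  con <- open_text_input(path)
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) stop("empty input file: ", path)
    if (nzchar(l)) break
  }
  if (startsWith(l, "@")) "fastq"
  else if (startsWith(l, ">")) "fasta"
  else stop("unrecognized format (first line is neither '@' nor '>'): ", path)
}

# detect encoding from the first records of a fastq file
sniff_encoding <- function(path, n_records = 1000L) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) < 4L) stop("no complete FASTQ record in ", path)
  qlines <- lines[seq(4L, length(lines) - length(lines) %% 4L, by = 4L)]
  detect_quality_encoding(qlines)
}

encoding_offset <- function(encoding) {
  switch(encoding, ascii33 = 33L, ascii64 = 64L,
         stop("unknown encoding: ", encoding))
}

# Parse a block of fastq lines (must be a multiple of 4, validated upstream)
# into a pe_reads object. `first_record` is the 1-based index of the first
# record in the file, for error messages.
parse_fastq_lines <- function(lines, offset, first_record = 1L) {
  n <- length(lines)
  idx <- seq(1L, n, by = 4L)
  ids <- lines[idx]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ header at record %d",
                 first_record + bad[1] - 1L))
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals) | nchar(seqs) == 0L)
  if (length(bad))
    stop(sprintf("sequence/quality length mismatch at record %d",
                 first_record + bad[1] - 1L))
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop(sprintf("illegal base in record %d", first_record + bad[1] - 1L))
  new_read_set(sub("^@", "", ids), seqs, cpp_decode_qual(quals, offset, 60L))
}

# Read a whole fasta file (multi-line records allowed) as pe_reads with a
# constant quality.
read_fasta_set <- function(path, default_qual = 30L) {
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  hdr <- startsWith(lines, ">")
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  seqs <- toupper(unname(seqs))
  if (length(seqs) != length(ids) || any(nchar(seqs) == 0L))
    stop("FASTA record with empty sequence in ", path)
  read_set(ids, seqs, default_qual = default_qual)
}

#' Read sequences from a FASTQ or FASTA file
#'
#' Format, gzip compression, and quality encoding are autodetected (the
#' encoding can be forced). FASTA input gets a constant quality.
#'
#' @param path Input file (plain or gzip).
#' @param encoding `"auto"`, `"ascii33"`, or `"ascii64"`.
#' @param default_qual Constant quality for FASTA records.
#' @return A `pe_reads` object.
#' @export
read_seqs <- function(path, encoding = "auto", default_qual = 30L) {
  fmt <- sniff_format(path)
  if (fmt == "fasta") return(read_fasta_set(path, default_qual))
  if (encoding == "auto") encoding <- sniff_encoding(path)
  con <- open_text_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at record %d",
                 length(lines) %/% 4L + 1L))
  parse_fastq_lines(lines, encoding_offset(encoding))
}

#' Read paired sequence data
#'
#' Accepts dual files (`source1` + `source2`) or a single interleaved file
#' (`interleaved = TRUE`, pairing records `2k-1`/`2k`). FASTQ or FASTA,
#' plain or gzip (magic-byte detection), Phred+33/64 with autodetection.
#'
#' @param source1 First (or interleaved) input path.
#' @param source2 Second input path, or `NULL`.
#' @param interleaved Treat `source1` as interleaved pairs.
#' @param encoding `"auto"`, `"ascii33"`, or `"ascii64"`.
#' @param default_qual Constant quality assigned to FASTA input.
#' @return A `pe_pairs` object.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' p <- simulate_pairs(generate_genome(2000, seed = 1), n_pairs = 5, seed = 2)
#' write_pairs(p, f)
#' read_pairs(f, interleaved = TRUE)
#' @export
read_pairs <- function(source1, source2 = NULL, interleaved = FALSE,
                       encoding = "auto", default_qual = 30L) {
  if (interleaved && !is.null(source2))
    stop("interleaved input takes a single source file")
  if (!interleaved && is.null(source2))
    stop("dual-file input needs source2 (or set interleaved = TRUE)")
  if (interleaved) {
    reads <- read_seqs(source1, encoding, default_qual)
    n <- length(reads)
    if (n %% 2L != 0L)
      stop(sprintf("odd record count (%d) in interleaved input", n))
    i1 <- seq(1L, n, by = 2L)
    read_pairs_new(reads[i1], reads[i1 + 1L])
  } else {
    r1 <- read_seqs(source1, encoding, default_qual)
    r2 <- read_seqs(source2, encoding, default_qual)
    read_pairs_new(r1, r2)
  }
}

#' Write reads to FASTQ or FASTA
#'
#' FASTQ output is 4-line records; a round trip through [read_seqs()]
#' reproduces `(id, seq, qual)` exactly. Qualities are range-checked for the
#' chosen encoding before anything is written.
#'
#' @param reads A `pe_reads` object.
#' @param path Output path.
#' @param format `"fastq"` or `"fasta"`.
#' @param encoding `"ascii33"` or `"ascii64"`.
#' @param gzip `TRUE`/`FALSE`, or `NULL` to infer from a `.gz` extension.
#' @return Invisibly, the number of reads written.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta"),
                        encoding = "ascii33", gzip = NULL) {
  stopifnot(inherits(reads, "pe_reads"))
  format <- match.arg(format)
  if (is.null(gzip)) gzip <- grepl("\\.gz$", path)
  if (format == "fastq") {
    offset <- encoding_offset(encoding)
    qmax <- 126L - offset
    over <- which(vapply(reads$qual, function(q) any(q < 0L | q > qmax), TRUE))
    if (length(over))
      stop(sprintf("quality out of range for %s in read %d", encoding,
                   over[1]))
    qstr <- cpp_encode_qual(reads$qual, offset)
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qstr))
  } else {
    lines <- as.vector(rbind(paste0(">", reads$id), reads$seq))
  }
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(length(reads))
}

#' Write read pairs to one interleaved or two dual files
#'
#' @param pairs A `pe_pairs` object.
#' @param path1 Output path (interleaved when `path2` is `NULL`).
#' @param path2 Optional second output path.
#' @inheritParams write_reads
#' @return Invisibly, the number of pairs written.
#' @export
write_pairs <- function(pairs, path1, path2 = NULL,
                        format = c("fastq", "fasta"), encoding = "ascii33",
                        gzip = NULL) {
  stopifnot(inherits(pairs, "pe_pairs"))
  format <- match.arg(format)
  if (is.null(path2)) {
    n <- length(pairs)
    idx <- rep(seq_len(n), each = 2L)
    mate <- rep(c(1L, 2L), n)
    inter <- new_read_set(
      ifelse(mate == 1L, pairs$r1$id[idx], pairs$r2$id[idx]),
      ifelse(mate == 1L, pairs$r1$seq[idx], pairs$r2$seq[idx]),
      lapply(seq_len(2L * n), function(i) {
        if (mate[i] == 1L) pairs$r1$qual[[idx[i]]] else pairs$r2$qual[[idx[i]]]
      }))
    write_reads(inter, path1, format, encoding, gzip)
  } else {
    write_reads(pairs$r1, path1, format, encoding, gzip)
    write_reads(pairs$r2, path2, format, encoding, gzip)
  }
  invisible(length(pairs))
}

# ------------------------------------------------------------- streaming

# Chunked pair stream over fastq input: returns a fetch(n_pairs) closure
# yielding pe_pairs (NULL at end of input). Keeps memory proportional to the
# chunk size, not the file. FASTA input is loaded whole and then chunked.
pair_stream <- function(source1, source2 = NULL, interleaved = FALSE,
                        encoding = "auto", default_qual = 30L) {
  fmt <- sniff_format(source1)
  if (fmt == "fasta") {
    all <- read_pairs(source1, source2, interleaved, encoding, default_qual)
    pos <- 0L
    return(function(n_pairs) {
      if (pos >= length(all)) return(NULL)
      take <- seq(pos + 1L, min(pos + n_pairs, length(all)))
      pos <<- pos + length(take)
      all[take]
    })
  }
  if (encoding == "auto") encoding <- sniff_encoding(source1)
  offset <- encoding_offset(encoding)
  con1 <- open_text_input(source1)
  con2 <- if (!is.null(source2)) open_text_input(source2)
  done <- FALSE
  rec <- 0L
  grab <- function(con, n_lines) {
    lines <- readLines(con, n = n_lines)
    lines[nzchar(lines)]
  }
  function(n_pairs) {
    if (done) return(NULL)
    if (interleaved) {
      lines <- grab(con1, 8L * n_pairs)
      if (!length(lines)) {
        done <<- TRUE; close(con1); return(NULL)
      }
      if (length(lines) %% 8L != 0L) {
        if (length(lines) %% 4L != 0L)
          stop(sprintf("truncated FASTQ record at record %d",
                       rec + length(lines) %/% 4L + 1L))
        stop("odd record count in interleaved input")
      }
      reads <- parse_fastq_lines(lines, offset, first_record = rec + 1L)
      rec <<- rec + length(reads)
      i1 <- seq(1L, length(reads), by = 2L)
      read_pairs_new(reads[i1], reads[i1 + 1L])
    } else {
      l1 <- grab(con1, 4L * n_pairs)
      l2 <- grab(con2, 4L * n_pairs)
      if (!length(l1) && !length(l2)) {
        done <<- TRUE; close(con1); close(con2); return(NULL)
      }
      if (length(l1) %% 4L != 0L || length(l2) %% 4L != 0L)
        stop(sprintf("truncated FASTQ record near record %d", rec + 1L))
      if (length(l1) != length(l2))
        stop("paired input files have unequal record counts")
      r1 <- parse_fastq_lines(l1, offset, first_record = rec + 1L)
      r2 <- parse_fastq_lines(l2, offset, first_record = rec + 1L)
      rec <<- rec + length(r1)
      read_pairs_new(r1, r2)
    }
  }
}
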