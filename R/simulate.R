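#' Default sequencing-adapter pair used by the simulator
#'
#' Fragment adapters appended to reads whose insert is shorter than the
#' read length (read-through). These are the standard TruSeq-style adapter
#' strings used for synthetic benchmark data in this domain; override them
#' freely.
#'
#' @return Named character vector with elements `adapter1`, `adapter2`.
#' @export
default_adapters <- function() {
  c(adapter1 = "GACGCTGCCGACGAATAGAGAGGTGTAGATCTCGGTGGTCGCCGTATCATT",
    adapter2 = "CCGAGCCCACGAGACTAAGGCGAATCTCGTATGCCGTCTTCTGCTTG")
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with the requested GC fraction; deterministic for a fixed
#' seed.
#'
#' @param length Genome length in bases.
#' @param gc_fraction Probability that a base is G or C.
#' @param seed Optional RNG seed.
#' @return A single character string.
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  cpp_random_genome(as.integer(length), gc_fraction)
}

# truncated gaussian by redraw; sd = 0 degenerates to the mean
rtrunc_gauss <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(round(mean), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  round(x)
}

# triangular distribution on [a, b] with mode c (per-read mean quality)
rtriangular <- function(n, a, c, b) {
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Simulate paired-end shotgun reads with known insert sizes
#'
#' Fragments are cut from the genome at uniform positions and on a uniform
#' strand, with insert sizes drawn from a gaussian truncated to
#' `[min_insert, max_insert]`. Read 1 is the first `read_len` bases of the
#' fragment; read 2 the first `read_len` bases of its reverse complement.
#' When the insert is shorter than the read (read-through), each read runs
#' into its sequencing adapter. Per-base qualities come from a per-read
#' mean drawn triangularly on `[minq, maxq]` with mode `midq`, jittered by
#' gaussian noise of sd `qv` and clamped to `[2, 41]`; each base is then
#' substituted with probability `10^(-Q/10)`. Both mate headers carry the
#' true insert size as `insert=<S>`, the grading contract used by
#' [grade()].
#'
#' @param genome Genome string (e.g. from [generate_genome()]) or a path to
#'   a FASTA file whose first record is used.
#' @param n_pairs Number of pairs.
#' @param read_len Read length in bases.
#' @param min_insert,max_insert Truncation bounds of the insert
#'   distribution.
#' @param insert_mean,insert_sd Gaussian parameters; default to
#'   `(min + max) / 2` and `(max - min) / 6`.
#' @param minq,midq,maxq,qv Quality model: floor, mode, ceiling of the
#'   per-read mean, and per-base jitter sd.
#' @param adapter1,adapter2 Adapter sequences for read-through fill.
#' @param add_errors Apply quality-driven substitution errors.
#' @param prefix Header prefix for read names.
#' @param seed Optional RNG seed; a fixed seed reproduces the pairs
#'   exactly.
#' @return A `pe_pairs` object.
#' @examples
#' g <- generate_genome(5000, seed = 1)
#' p <- simulate_pairs(g, n_pairs = 10, seed = 7)
#' p$r1$id[1:2]
#' @export
simulate_pairs <- function(genome, n_pairs, read_len = 150L,
                           min_insert = 100L, max_insert = 400L,
                           insert_mean = NULL, insert_sd = NULL,
                           minq = 14, midq = 24, maxq = 34, qv = 6,
                           adapter1 = default_adapters()[["adapter1"]],
                           adapter2 = default_adapters()[["adapter2"]],
                           add_errors = TRUE, prefix = "r", seed = NULL) {
  if (nchar(genome) < 4096 && !grepl("^[ACGTN]+$", toupper(genome)) &&
      file.exists(genome))
    genome <- read_fasta_set(genome)$seq[1]
  genome <- toupper(genome)
  stopifnot(min_insert >= 1, min_insert <= max_insert, read_len >= 1,
            nchar(genome) >= max_insert)
  if (is.null(insert_mean)) insert_mean <- (min_insert + max_insert) / 2
  if (is.null(insert_sd)) insert_sd <- (max_insert - min_insert) / 6
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_pairs)
  L <- as.integer(read_len)

  S <- as.integer(rtrunc_gauss(n, insert_mean, insert_sd, min_insert,
                               max_insert))
  start <- floor(runif(n) * (nchar(genome) - S + 1)) + 1L
  frag <- substring(genome, start, start + S - 1L)
  flip <- runif(n) < 0.5
  if (any(flip)) frag[flip] <- cpp_revcomp(frag[flip])

  cut_read <- function(fragments, adapter) {
    r <- substring(fragments, 1L, L)
    short <- nchar(r) < L
    if (any(short)) {
      fill <- substring(adapter, 1L, L - nchar(r[short]))
      pad <- L - nchar(r[short]) - nchar(fill)
      r[short] <- paste0(r[short], fill, strrep("A", pmax(pad, 0L)))
    }
    r
  }
  s1 <- cut_read(frag, toupper(adapter1))
  s2 <- cut_read(cpp_revcomp(frag), toupper(adapter2))

  draw_quals <- function() {
    m <- rtriangular(n, minq, midq, maxq)
    q <- as.integer(pmin(pmax(round(rep(m, each = L) + rnorm(n * L, 0, qv)),
                              2), 41))
    split(q, rep(seq_len(n), each = L))
  }
  q1 <- unname(draw_quals())
  q2 <- unname(draw_quals())
  if (add_errors) {
    s1 <- as.character(cpp_apply_errors(s1, q1))
    s2 <- as.character(cpp_apply_errors(s2, q2))
  }

  ids <- sprintf("%s%d insert=%d", prefix, seq_len(n), S)
  read_pairs_new(new_read_set(ids, s1, q1), new_read_set(ids, s2, q2),
                 check = FALSE)
}

#' Parse the true insert size from a read header
#'
#' Reads simulated by [simulate_pairs()] (and graded output generally)
#' carry their true insert size in the header as `insert=<int>`.
#'
#' @param header Character vector of headers.
#' @return Integer vector of insert sizes; errors if a header lacks the
#'   token.
#' @examples
#' parse_true_insert("r17 insert=240")
#' @export
parse_true_insert <- function(header) {
  m <- regmatches(header, regexpr("insert=([0-9]+)", header))
  if (length(m) != length(header))
    stop("header without 'insert=' token: ",
         header[!grepl("insert=[0-9]+", header)][1])
  as.integer(sub("insert=", "", m))
}
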