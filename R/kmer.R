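#' Build a canonical k-mer count table from read pairs
#'
#' First pass of the k-mer modes: every N-free window of length `k` in
#' every read contributes one count to its canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement, so
#' counting is strand-neutral). The table is immutable once built and is
#' shared by tail extension, the REM/RSEM modes, and the k-mer filter.
#'
#' @param pairs A `pe_pairs` object (both mates are counted), or a
#'   `pe_reads` object.
#' @param k Odd word size in `[3, 31]`; default 31.
#' @return A `kmer_table` handle.
#' @examples
#' p <- simulate_pairs(generate_genome(3000, seed = 1), n_pairs = 50, seed = 2)
#' tab <- kmer_table(p, k = 21)
#' tab
#' @export
kmer_table <- function(pairs, k = 31L) {
  seqs <- if (inherits(pairs, "pe_pairs")) c(pairs$r1$seq, pairs$r2$seq)
          else if (inherits(pairs, "pe_reads")) pairs$seq
          else stop("pairs must be pe_pairs or pe_reads")
  k <- as.integer(k)
  ptr <- cpp_kmer_build(seqs, k)
  if (all(nchar(seqs) < k))
    warning("k exceeds every read length; k-mer table is empty")
  structure(list(ptr = ptr, k = k), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  st <- cpp_kmer_stats(x$ptr)
  cat(sprintf("<kmer_table> k=%d, %.0f distinct k-mers, %.0f total counts\n",
              st$k, st$n_distinct, st$total))
  invisible(x)
}

#' Look up k-mer counts
#'
#' @param table A [kmer_table()].
#' @param kmers Character vector of k-mers (length `k`); a k-mer and its
#'   reverse complement return the same count.
#' @return Integer counts (0 for unseen or N-containing k-mers).
#' @export
kmer_count <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  vapply(toupper(kmers), function(s) cpp_kmer_get(table$ptr, s), 0,
         USE.NAMES = FALSE)
}

#' Summary statistics of a k-mer table
#'
#' @param table A [kmer_table()].
#' @return List with `k`, `n_distinct`, `total`.
#' @export
kmer_table_stats <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  cpp_kmer_stats(table$ptr)
}

#' Greedily extend a read's tail through the k-mer table
#'
#' Starting from the read's terminal k-mer, repeatedly appends the unique
#' next base whose successor k-mer is present at depth `min_depth` or more.
#' Extension stops at the requested length (`max_length`), when no
#' successor is deep enough (`low_depth`), at a branch k-mer — one where a
#' second successor has count at least `max(2, best/8)` (`branch`) — or
#' immediately when the terminal k-mer is absent or N-containing
#' (`no_seed`). Appended bases carry quality `qext`.
#'
#' @param r A `pe_read`.
#' @param table A [kmer_table()].
#' @param max_ext Maximum bases to append (default 50).
#' @param min_depth Minimum successor depth (default 2).
#' @param qext Quality assigned to appended bases.
#' @return List with `extended` (`pe_read`), `added` (count), and
#'   `stop_reason` in `{"max_length","branch","low_depth","no_seed"}`.
#' @export
extend_tail <- function(r, table, max_ext = 50L, min_depth = 2L,
                        qext = 20L) {
  stopifnot(inherits(r, "pe_read"), inherits(table, "kmer_table"),
            max_ext >= 0L)
  res <- cpp_extend_tail(table$ptr, r$seq, as.integer(max_ext),
                         as.integer(min_depth))
  added <- nchar(res$added)
  ext <- if (added > 0)
    read_new(r$id, paste0(r$seq, res$added),
             c(r$qual, rep.int(as.integer(qext), added)))
  else r
  list(extended = ext, added = added,
       stop_reason = stop_reason_levels()[res$stop_reason + 1L])
}

#' K-mer support filter for a merged read
#'
#' A correct merge is made of genomic sequence, so every k-mer in it should
#' already have been observed in the input. The gate fails iff any N-free
#' window of the merged read has table count below `min_depth`. Reads
#' shorter than `k` pass vacuously.
#'
#' @param merged A `pe_read` (or `pe_reads`; then a logical vector is
#'   returned).
#' @param table A [kmer_table()].
#' @param min_depth Required depth (default 1).
#' @return Logical: `TRUE` = pass.
#' @export
kfilter_gate <- function(merged, table, min_depth = 1L) {
  stopifnot(inherits(table, "kmer_table"))
  seqs <- if (inherits(merged, "pe_read")) merged$seq
          else if (inherits(merged, "pe_reads")) merged$seq
          else stop("merged must be pe_read or pe_reads")
  as.logical(cpp_kfilter(table$ptr, seqs, as.integer(min_depth)))
}

#' Merge one pair with k-mer extension (REM/RSEM logic)
#'
#' Computes the overlap-only insert `S0`, extends both read tails through
#' the table, and recomputes the insert `S1` on the extended pair (tail
#' extension keeps read starts fixed, so `S0` and `S1` are directly
#' comparable). If neither read gained a base, the `S0` decision stands
#' regardless of mode. REM accepts when `S0 == S1`, uses `S1` when overlap
#' alone found nothing, and rejects disagreements; RSEM accepts only when
#' `S0` exists and equals `S1`. Accepted merges are built from the original
#' (unextended) reads; only interior gap positions of a rescued
#' non-overlapping pair are taken from the extension.
#'
#' @param pair List with `r1`, `r2` (`pe_read`s) or a length-1 `pe_pairs`.
#' @param table A [kmer_table()] built from the same dataset.
#' @param mode `"rem"` or `"rsem"`.
#' @param profile A [sensitivity_profile()].
#' @param adapter1,adapter2 Optional adapters.
#' @param max_ext,min_depth,qext Extension parameters (see [extend_tail()]).
#' @return List with `status`, `S`, and (when merged) `merged` (`pe_read`).
#' @export
merge_with_extension <- function(pair, table, mode = c("rem", "rsem"),
                                 profile = sensitivity_profile(),
                                 adapter1 = NULL, adapter2 = NULL,
                                 max_ext = 50L, min_depth = 2L, qext = 20L) {
  mode <- match.arg(mode)
  if (inherits(pair, "pe_pairs")) pair <- pair_at(pair, 1L)
  pp <- read_pairs_new(
    read_set(pair$r1$id, pair$r1$seq, list(pair$r1$qual)),
    read_set(pair$r2$id, pair$r2$seq, list(pair$r2$qual)), check = FALSE)
  res <- merge_pairs(pp, profile = profile, mode = mode, table = table,
                     adapter1 = adapter1, adapter2 = adapter2,
                     extend_len = max_ext, min_depth = min_depth,
                     qext = qext)
  out <- list(status = as.character(res$status[1]), S = res$insert[1])
  if (out$status == "merged") out$merged <- read_at(res$merged, 1L)
  out
}
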