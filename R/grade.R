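#' Grade merged reads against their known insert sizes
#'
#' A merged read is correct iff its length exactly equals the insert size
#' recorded in its header (`insert=<S>`). With `P` input pairs, `C` correct
#' and `I` incorrect merges, the report derives
#' `C% = 100 * C / P`, `I% = 100 * I / P`, and the signal-to-noise ratio
#' `SNR = 10 * log10(C / I)` in decibels (`Inf` when `I = 0` and `C > 0`).
#' Unmerged pairs are `U = P - C - I`.
#'
#' @param merged Merged reads: a `pe_reads`, a `merge_result`, or a path to
#'   a FASTQ/FASTA file of merged reads.
#' @param P Number of input read pairs.
#' @return A `grade_report` with fields `P`, `C`, `I`, `U`, `C_pct`,
#'   `I_pct`, `SNR`.
#' @examples
#' g <- generate_genome(20000, seed = 1)
#' p <- simulate_pairs(g, n_pairs = 200, max_insert = 280, seed = 2)
#' grade(merge_pairs(p), length(p))
#' @export
grade <- function(merged, P) {
  if (inherits(merged, "merge_result")) merged <- merged$merged
  if (is.character(merged)) merged <- read_seqs(merged)
  stopifnot(inherits(merged, "pe_reads"))
  s_true <- parse_true_insert(merged$id)
  C <- sum(nchar(merged$seq) == s_true)
  I <- length(merged) - C
  if (P < C + I)
    stop(sprintf("input pair count P=%d smaller than merged count %d", P,
                 C + I))
  snr <- if (I == 0 && C > 0) Inf
         else if (C == 0 && I == 0) NA_real_
         else 10 * log10(C / I)
  structure(list(P = as.integer(P), C = C, I = I, U = as.integer(P) - C - I,
                 C_pct = 100 * C / P, I_pct = 100 * I / P, SNR = snr),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cat(sprintf("<grade_report> P=%d pairs\n", x$P))
  cat(sprintf("  correct:   C=%d (%.4g%%)\n", x$C, x$C_pct))
  cat(sprintf("  incorrect: I=%d (%.4g%%)\n", x$I, x$I_pct))
  cat(sprintf("  unmerged:  U=%d\n", x$U))
  cat(sprintf("  SNR: %s dB\n",
              if (is.na(x$SNR)) "NA"
              else if (is.infinite(x$SNR)) "Inf"
              else sprintf("%.4g", x$SNR)))
  invisible(x)
}

#' @export
as.data.frame.grade_report <- function(x, ...) {
  data.frame(P = x$P, C = x$C, I = x$I, U = x$U, C_pct = x$C_pct,
             I_pct = x$I_pct, SNR = x$SNR)
}
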