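#' Consensus of two aligned bases
#'
#' Rules for one overlap position: matching non-N bases keep the base with
#' quality `min(q1 + q2, qcap)` (agreement increases confidence); on a
#' mismatch the higher-quality base wins with quality `|q1 - q2|`; a
#' mismatch at equal quality is uninformative and yields `N` at quality 0;
#' if exactly one base is `N` the other base and its quality carry through;
#' two `N`s stay `N` at 0.
#'
#' @param b1,b2 Single bases in `{A,C,G,T,N}`.
#' @param q1,q2 Phred qualities.
#' @param qcap Quality ceiling for boosted matches.
#' @return List with `base` and `qual`.
#' @examples
#' consensus_base("A", 30, "C", 20)  # A at Q10
#' consensus_base("A", 20, "C", 20)  # N at Q0
#' @export
consensus_base <- function(b1, q1, b2, q2, qcap = 41L) {
  stopifnot(b1 %in% c("A", "C", "G", "T", "N"),
            b2 %in% c("A", "C", "G", "T", "N"))
  if (b1 == "N" && b2 == "N") return(list(base = "N", qual = 0L))
  if (b1 == "N") return(list(base = b2, qual = as.integer(q2)))
  if (b2 == "N") return(list(base = b1, qual = as.integer(q1)))
  if (b1 == b2) return(list(base = b1, qual = as.integer(min(q1 + q2, qcap))))
  if (q1 == q2) return(list(base = "N", qual = 0L))
  if (q1 > q2) list(base = b1, qual = as.integer(q1 - q2))
  else list(base = b2, qual = as.integer(q2 - q1))
}

#' Build the merged read for an accepted insert size
#'
#' The merged read has length exactly `S`. For tail-overlapping pairs
#' (`S >= max(L1, L2)`) it is the non-overlapping head of read 1, the
#' consensus over the `W` overlapping positions, then the non-overlapping
#' tail of reverse-complemented read 2. For read-through pairs (`S` shorter
#' than the reads) the adapter portions are trimmed and every position is a
#' consensus of two bases.
#'
#' @param r1 `pe_read`, read 1 as sequenced.
#' @param r2rc `pe_read`, read 2 reverse-complemented.
#' @param S Accepted insert size; must lie in `[1, L1 + L2 - 1]`.
#' @param qcap Quality ceiling for boosted matches.
#' @param id Header for the merged read (default: read 1's header).
#' @return A `pe_read` of length `S`.
#' @export
build_merged_read <- function(r1, r2rc, S, qcap = 41L, id = r1$id) {
  stopifnot(inherits(r1, "pe_read"), inherits(r2rc, "pe_read"))
  res <- cpp_consensus_merge(r1$seq, r1$qual, r2rc$seq, r2rc$qual,
                             as.integer(S), as.integer(qcap))
  read_new(id, res$seq, res$qual)
}
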