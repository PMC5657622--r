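#' Enumerate candidate insert sizes for a read pair
#'
#' Aligns read 1 against the reverse-complemented read 2 at every candidate
#' insert size `S` from `profile$c6_insert` to `L1 + L2 - 1` (gap-free; no
#' indels). For each `S` the overlap spans `W = min(L1,S) + min(L2,S) - S`
#' positions; matches increment `G`, mismatches `B`, and positions involving
#' `N` increment neither. The ratio score is `R = (B + c0) / (B + G)`.
#' Candidates with `G + B = 0` are omitted. With `profile$ouq`, `G` and `B`
#' accumulate quality-derived weights instead of unit counts.
#'
#' @param r1 `pe_read`, read 1 as sequenced.
#' @param r2rc `pe_read`, read 2 already reverse-complemented.
#' @param profile A [sensitivity_profile()].
#' @return A data.frame with columns `S`, `W`, `G`, `B`, `R`, one row per
#'   candidate (possibly zero rows).
#' @export
enumerate_candidates <- function(r1, r2rc,
                                 profile = sensitivity_profile()) {
  stopifnot(inherits(r1, "pe_read"), inherits(r2rc, "pe_read"))
  cpp_enumerate_candidates(r1$seq, r1$qual, r2rc$seq, r2rc$qual,
                           profile$c0, profile$c6_insert, profile$ouq)
}

#' Best and second-best ratio among candidates
#'
#' Selects the candidate with the lowest ratio `R` (ties broken towards the
#' smaller insert size, i.e. the longer overlap) and reports the lowest `R`
#' among the remaining candidates (`Inf` if there is only one).
#'
#' @param candidates Data.frame from [enumerate_candidates()].
#' @return List with `best` (one-row data.frame) and `R2` (numeric).
#' @export
best_two_ratios <- function(candidates) {
  if (!nrow(candidates))
    stop("no overlap candidates (empty candidate list)")
  ord <- order(candidates$R, candidates$S)
  best <- candidates[ord[1], , drop = FALSE]
  R2 <- if (nrow(candidates) > 1) candidates$R[ord[2]] else Inf
  list(best = best, R2 = R2)
}

#' Minimum-overlap requirement from pair complexity
#'
#' Low-complexity pairs need longer overlaps before a merge is believable.
#' `V` is derived from the Shannon entropy `H` (bits) of the pair's
#' dinucleotide composition: `V = floor(v_max * max(0, 1 - H / h_thresh))`.
#' Homopolymers (`H = 0`) get the maximum; random sequence (`H` near 4 bits)
#' gets 0, leaving the `c4` floor in charge.
#'
#' @param r1,r2 `pe_read` objects (orientation does not matter; the measure
#'   is reverse-complement invariant).
#' @param profile A [sensitivity_profile()] supplying `v_max`, `h_thresh`.
#' @return Non-negative integer `V`.
#' @export
complexity_min_overlap <- function(r1, r2, profile = sensitivity_profile()) {
  stopifnot(inherits(r1, "pe_read"), inherits(r2, "pe_read"))
  cpp_complexity_v(r1$seq, r2$seq, profile$v_max, profile$h_thresh)
}

#' Ratio-mode acceptance gates
#'
#' Applies the ordered rejection rules to the best candidate: reject when
#' `R1 > c1` (no believable overlap), when `R1 * c2 > R2` or `R2 < c3`
#' (ambiguous — a rival offset is nearly as good), when `G < max(c4, V)`
#' (overlap too short), or when `S < c6_insert` (insert too short).
#'
#' @param best One-row candidate data.frame (from [best_two_ratios()]).
#' @param R2 Second-best ratio.
#' @param V Complexity floor from [complexity_min_overlap()].
#' @param profile A [sensitivity_profile()].
#' @return A status string: `"merged"` if all gates pass, otherwise the
#'   first failing gate's rejection status.
#' @export
apply_gates <- function(best, R2, V = 0L, profile = sensitivity_profile()) {
  if (best$R > profile$c1) return("no_overlap")
  if (best$R * profile$c2 > R2) return("ambiguous")
  if (R2 < profile$c3) return("ambiguous")
  if (best$G < max(profile$c4, V)) return("too_short_overlap")
  if (best$S < profile$c6_insert) return("too_short_insert")
  "merged"
}

#' Flat-mode candidate (minimum mismatches)
#'
#' Returns the candidate minimizing the raw mismatch count `B`, subject to
#' `G >= max(c4, V)` and `S >= c6_insert`; ties go to the smaller insert.
#' Used at extreme sensitivity settings: `xstrict`/`ustrict` accept ratio
#' mode's choice only if flat mode picks the same insert size; `xloose`
#' falls back to the flat-mode candidate when ratio mode produced none.
#'
#' @inheritParams enumerate_candidates
#' @return One-row candidate data.frame, or `NULL` if no candidate
#'   satisfies the constraints.
#' @export
flat_mode_best <- function(r1, r2rc, profile = sensitivity_profile()) {
  cand <- enumerate_candidates(r1, r2rc, profile)
  if (!nrow(cand)) return(NULL)
  V <- complexity_min_overlap(r1, r2rc, profile)
  ok <- cand$G >= max(profile$c4, V) & cand$S >= profile$c6_insert
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  cand[order(cand$B, cand$S)[1], , drop = FALSE]
}

#' Adapter check for read-through overlaps
#'
#' For inserts shorter than the read length, the bases beyond the insert are
#' sequencing adapter. Read 1 beyond position `S` is compared to the prefix
#' of `adapter1`, and read 2 (as sequenced) beyond `S` to the prefix of
#' `adapter2`. Each side passes iff its mismatch fraction over
#' `min(overhang, adapter length)` positions is at most
#' `profile$adapter_mismatch_frac`; `N` positions are tolerated. With no
#' adapters, or no overhang, the check passes.
#'
#' @param r1 `pe_read`, read 1 as sequenced.
#' @param r2 `pe_read`, read 2 as sequenced.
#' @param S Candidate insert size.
#' @param adapter1,adapter2 Adapter sequences (may be `NULL`/empty).
#' @param profile A [sensitivity_profile()].
#' @return `TRUE` (pass) or `FALSE` (reject).
#' @export
adapter_check <- function(r1, r2, S, adapter1 = NULL, adapter2 = NULL,
                          profile = sensitivity_profile()) {
  check_side <- function(seq, adapter) {
    if (is.null(adapter) || !nzchar(adapter)) return(TRUE)
    over <- nchar(seq) - S
    n <- min(over, nchar(adapter))
    if (n <= 0) return(TRUE)
    rb <- strsplit(substr(seq, S + 1L, S + n), "")[[1]]
    ab <- strsplit(toupper(substr(adapter, 1L, n)), "")[[1]]
    mm <- sum(rb != ab & rb != "N" & ab != "N")
    mm / n <= profile$adapter_mismatch_frac
  }
  check_side(r1$seq, adapter1) && check_side(r2$seq, adapter2)
}

# compared (non-N) overlap positions for insert size S, as index pairs
overlap_positions <- function(r1, r2rc, S) {
  L1 <- nchar(r1$seq); L2 <- nchar(r2rc$seq)
  off <- S - L2
  j <- seq.int(max(0L, off), min(L1, S) - 1L)
  u <- j - off
  b1 <- substring(r1$seq, j + 1L, j + 1L)
  b2 <- substring(r2rc$seq, u + 1L, u + 1L)
  keep <- b1 != "N" & b2 != "N"
  list(j = j[keep], u = u[keep], b1 = b1[keep], b2 = b2[keep])
}

#' Expected-mismatch gate
#'
#' The number of mismatches expected from the quality scores alone is
#' `E = sum(p1 + p2 - (4/3) p1 p2)` over the compared overlap positions,
#' where `p = 10^(-Q/10)`. An overlap with observed mismatches `B` greater
#' than `E * c5` has more errors than its qualities can explain and is
#' rejected.
#'
#' @inheritParams enumerate_candidates
#' @param cand One-row candidate data.frame (needs columns `S`, `B`).
#' @return List with `E` (numeric) and `pass` (logical).
#' @export
expected_mismatch_gate <- function(r1, r2rc, cand,
                                   profile = sensitivity_profile()) {
  pos <- overlap_positions(r1, r2rc, cand$S)
  p1 <- 10^(-r1$qual[pos$j + 1L] / 10)
  p2 <- 10^(-r2rc$qual[pos$u + 1L] / 10)
  E <- sum(p1 + p2 - (4 / 3) * p1 * p2)
  list(E = E, pass = cand$B <= E * profile$c5)
}

#' Pattern-probability gate
#'
#' Models the number of mismatches in the overlap as binomial with `W`
#' trials at the quality-implied per-position rate `r = E / W`, and computes
#' the upper-tail probability `P` of observing at least `B` mismatches.
#' Overlaps whose mismatch pattern is this improbable (`P < c6_prob`) are
#' rejected.
#'
#' @inheritParams expected_mismatch_gate
#' @return List with `P` (numeric) and `pass` (logical).
#' @export
pattern_probability_gate <- function(r1, r2rc, cand,
                                     profile = sensitivity_profile()) {
  E <- expected_mismatch_gate(r1, r2rc, cand, profile)$E
  W <- cand$W
  B <- ceiling(cand$B - 1e-9)
  r <- min(max(E / max(W, 1L), 1e-12), 1 - 1e-12)
  P <- if (B <= 0) 1 else stats::pbinom(B - 1, W, r, lower.tail = FALSE)
  list(P = P, pass = P >= profile$c6_prob)
}

#' Full overlap decision for one read pair
#'
#' Composes the whole detection cascade: reverse-complement read 2,
#' enumerate candidate insert sizes, pick the two best ratios, apply the
#' ratio gates, flat-mode confirmation/rescue per the profile, then the
#' adapter, expected-mismatch, and pattern-probability gates. The first
#' failing gate determines the status.
#'
#' @param pair A list with `r1` and `r2` (`pe_read`s, as sequenced), or a
#'   `pe_pairs` of length 1.
#' @param profile A [sensitivity_profile()].
#' @param adapter1,adapter2 Optional adapter sequences.
#' @return A `merge_decision`: list with `status` (string), `S`, `W`, `G`,
#'   `B`, `R1`, `R2`, `E`, `P`, `V`, `from_flat`.
#' @examples
#' g <- generate_genome(400, seed = 1)
#' p <- simulate_pairs(g, n_pairs = 1, read_len = 150, insert_mean = 260,
#'                     insert_sd = 0, min_insert = 260, max_insert = 260,
#'                     error = FALSE, seed = 2)
#' find_overlap(pair_at(p, 1))
#' @export
find_overlap <- function(pair, profile = sensitivity_profile(),
                         adapter1 = NULL, adapter2 = NULL) {
  if (inherits(pair, "pe_pairs")) pair <- pair_at(pair, 1L)
  r1 <- pair$r1; r2 <- pair$r2
  stopifnot(inherits(r1, "pe_read"), inherits(r2, "pe_read"))
  a1 <- if (is.null(adapter1)) "" else toupper(adapter1)
  a2 <- if (is.null(adapter2)) "" else toupper(adapter2)
  res <- cpp_find_overlap(r1$seq, r1$qual, r2$seq, r2$qual, profile,
                          a1, a2, nzchar(a1) || nzchar(a2))
  res$status <- as.character(status_factor(res$status))
  class(res) <- "merge_decision"
  res
}

#' @export
print.merge_decision <- function(x, ...) {
  cat(sprintf("<merge_decision> %s", x$status))
  if (!is.na(x$S))
    cat(sprintf("  S=%d W=%d G=%.4g B=%.4g R1=%.4g R2=%.4g",
                x$S, x$W, x$G, x$B, x$R1, x$R2))
  cat("\n")
  invisible(x)
}

#' Extract a single pair from a pair set
#'
#' @param x A `pe_pairs` object.
#' @param i Pair index.
#' @return List with `r1` and `r2` as `pe_read` objects.
#' @export
pair_at <- function(x, i) {
  stopifnot(inherits(x, "pe_pairs"))
  list(r1 = read_at(x$r1, i), r2 = read_at(x$r2, i))
}
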