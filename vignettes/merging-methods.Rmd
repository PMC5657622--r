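---
title: "How pemerge merges paired-end reads: model, gates, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How pemerge merges paired-end reads: model, gates, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemerge)
```

## The problem

Illumina-style paired-end sequencing reads the two ends of a DNA fragment.
When the fragment (the *insert*) is shorter than the sum of the two read
lengths, the reads overlap, and the pair can be collapsed into a single
longer read spanning the whole insert. Merged reads improve assembly,
binning, and clustering — but an *incorrectly* merged read (wrong insert
size) injects sequence that never existed, which is worse than leaving the
pair unmerged. pemerge is therefore built around one priority: keep the
false-merge rate as close to zero as possible, and make it measurable.

## Overlap detection in ratio mode

Read 2 is reverse-complemented (the mates come from opposite strands), and
the pair is evaluated at **every** candidate insert size `S` from the
configured minimum up to `L1 + L2 - 1`. The alignment at each `S` is
gap-free — only matches and mismatches are counted, no indels — over the
`W = min(L1,S) + min(L2,S) - S` overlapping positions. Positions where
either base is `N` count as neither. Each candidate gets a ratio score

\[ R = \frac{B + C_0}{B + G} \]

with `G` matches, `B` mismatches, and pseudocount `C_0`. Low `R` is good:
it favors long overlaps with few mismatches, while the pseudocount
penalizes short overlaps that are perfect only by chance. The two lowest
ratios `R1` (best) and `R2` (runner-up) drive the acceptance gates, applied
in order:

1. `R1 > C1` — no believable overlap at all (*no_overlap*);
2. `R1 · C2 > R2` — a rival offset is nearly as good (*ambiguous*);
3. `R2 < C3` — the runner-up is itself suspiciously good (*ambiguous*);
4. `G < max(C4, V)` — overlap too short (*too_short_overlap*), where `V`
   rises for low-complexity pairs (below);
5. `S < C6` — insert too short (*too_short_insert*).

A surviving candidate then faces three evidence checks:

* **Adapter check.** If `S` is shorter than the read, the bases beyond the
  insert must look like the configured sequencing adapters (mismatch
  fraction ≤ 25% over the compared prefix, `N`-tolerant). The 25% ceiling
  keeps single sequencing errors in short overhangs from rejecting true
  read-through pairs.
* **Expected mismatches.** From the Phred qualities, the expected number of
  mismatches in the overlap is
  `E = Σ p1 + p2 − (4/3) p1 p2` with `p = 10^(−Q/10)` (the 4/3 term
  removes double-counting when both bases err, with a 1-in-3 chance of
  erring to the same base). If `B > E · C5`, the overlap has more errors
  than its qualities can explain.
* **Pattern probability.** The observed mismatch count is referred to a
  binomial with `W` trials at rate `E/W`; if the upper-tail probability of
  seeing ≥ `B` mismatches falls below `C6_prob`, the pattern is too
  improbable. The binomial tail is the minimal model consistent with a
  "probability of the observed match/mismatch pattern"; position-specific
  models would need calibration data this package does not assume.

### Constants and the preset ladder

The gate constants are configuration, not measurements. The defaults —
`C0 = 0.4`, `C1 = 0.12`, `C2 = 6`, `C3 = 0.05`, `C4 = 12` bases,
`C5 = 8`, `C6_insert = 35` bases, `C6_prob = 1e-5` — were fixed once when
the package was designed and are validated by the property tests (zero
incorrect merges on simulated data at these settings), not tuned against
any external tool. Eight presets from `ustrict` to `xloose` scale only
`C1` (×2 per step looser) and `C2` (÷1.4 per step looser), so the merged
set at any preset is by construction a subset of the merged set at every
looser preset — the property the sensitivity-ladder test asserts. The two
extreme ends additionally engage **flat mode** (offset chosen by minimum
raw mismatch count): `xstrict`/`ustrict` accept ratio mode's offset only
when flat mode independently picks the same insert size, and `xloose`
falls back to a flat-mode offset when ratio mode produced none.

### Low-complexity floor `V`

A 20-base perfect overlap is strong evidence in random sequence and no
evidence inside a poly-A run. `V` is derived from the Shannon entropy `H`
(bits) of the pair's dinucleotide composition — a measure invariant under
reverse complement — as `V = floor(v_max · max(0, 1 − H/h_thresh))` with
`v_max = 30` bases and `h_thresh = 3.2` bits. Homopolymers (`H = 0`) must
therefore overlap by 30+ bases; random 150-mers (`H ≈ 3.9`) get `V = 0`
and are governed by `C4` alone. The functional form is a package choice;
only its endpoints and monotonicity are contractual.

### Tie-breaking and determinism

Candidates are scanned in increasing `S`; a tie in `R` keeps the smaller
insert (the longer overlap carries more evidence). Equal-ratio ties also
set `R2 = R1`, so exact repeats trip the ambiguity gate rather than being
resolved arbitrarily. All paths are deterministic: results are identical
for any worker count or buffer size, and the simulator is reproducible
from its seed through R's RNG.

## Consensus construction

An accepted merge yields a read of length exactly `S`: read 1's
non-overlapping head, the consensus of the overlap, and read 2's
non-overlapping tail. Read-through pairs (`S` below the read length) are
trimmed to `S` and are 100% consensus. Per position: matching bases keep
the base with quality `min(q1 + q2, 41)`; on mismatch the higher-quality
base wins with quality `|q1 − q2|`; equal-quality mismatches become `N` at
quality 0; a lone `N` defers to the other base. The additive boost with a
cap at the conventional Illumina ceiling of Q41 was chosen over a full
posterior update for monotonicity and simplicity; both the boost rule and
the cap are exposed as configuration (`qcap`).

## K-mer modes: REM, RSEM, kfilter

With sufficient depth and a randomly sheared library, k-mer frequencies
carry information the single pair does not. The input is processed twice:
a counting pass builds an immutable table of canonical 31-mers (the
lexicographic minimum of each k-mer and its reverse complement — counting
is strand-neutral because fragments are sequenced from both strands), then
a merging pass extends each read's 3′ tail through the table: append the
unique successor base whose k-mer has count ≥ 2, stopping at the requested
length (50 bp by default), at a depth dropout, or at a *branch k-mer* —
one where a second successor reaches `max(2, best/8)` counts. The branch
rule's 8:1 dominance requirement errs on the side of stopping: extension
into the wrong haplotype or repeat copy is the failure mode that matters.

Tail-only extension leaves both read start positions fixed, so the insert
size `S1` implied by overlapping the *extended* pair is directly
comparable with the original `S0`. **REM** ("require extension match")
accepts `S0` when `S1` confirms it, accepts `S1` alone when plain overlap
found nothing — this is how initially non-overlapping pairs (insert larger
than `L1 + L2`) become mergeable — and rejects disagreements, which is
what defuses short-repeat-induced false overlaps. **RSEM** (strict)
accepts only a confirmed `S0`, so its merges are a subset of default
mode's and always shorter than `L1 + L2`. If extension fails to add a
single base to either read, the `S0` decision stands unchanged in both
modes.

Merged output is always built from the original, unextended reads; the
one exception is an REM-rescued insert larger than `L1 + L2`, whose
interior gap is exactly the sequence the extension assembled, emitted at
the synthetic-base quality `Q = 20`. Filling the gap (rather than emitting
`N`s) reflects what the k-mer rescue is for — assembling the unsequenced
middle of the fragment — while keeping every base that *was* sequenced at
its measured quality.

The optional **kfilter** rejects any merge containing an N-free k-mer
absent from the table at the required depth (default 1): a correct merge
is genomic sequence, so every window of it should have been seen in the
input. It shares the same table, so enabling it with REM/RSEM costs no
additional memory.

## The simulator

`simulate_pairs()` emulates a shotgun library from a reference (or a
random genome of chosen GC): insert sizes are gaussian, truncated to
`[100, 400]` by default with mean `(min+max)/2 = 250` and
`sd = (max−min)/6 = 50` — chosen so the untruncated distribution places
±3σ at the stated bounds; fragment positions and strands are uniform.
Inserts shorter than the read produce genuine read-through into the
configured adapter sequences. Per-base qualities use a per-read mean drawn
triangularly on `[minq = 14, maxq = 34]` with mode `midq = 24`, jittered
per-base by gaussian noise of sd `qv = 6` and clamped to `[2, 41]`; each
base is then substituted with probability `10^(−Q/10)`, so the written
qualities are *calibrated* by construction. Both mate headers carry the
true insert (`insert=<S>`), which is the grading contract.

What the simulator does **not** emulate: indels, quality decay along the
read cycle, miscalibrated quality scores, GC-dependent coverage bias,
chimeric fragments, and real repeat structure (a 1 Mbp i.i.d. genome is
nearly repeat-free, unlike real eukaryotic sequence). Passing grades on
simulated data therefore demonstrate the engine's correctness and its
behavior under calibrated noise — not its false-merge rate on repeat-rich
real libraries, which is bounded instead by the ambiguity gates and the
k-mer confirmation modes.

## Grading

`grade()` scores merged output against the header contract: a merge is
correct iff its length **exactly** equals the recorded insert. With `P`
input pairs, `C` correct and `I` incorrect merges: `C% = 100·C/P`,
`I% = 100·I/P`, and `SNR = 10·log10(C/I)` dB, reported as `+Inf` when
`I = 0` with `C > 0`. Conservation `C + I + U = P` is asserted on every
report.

## Problem sizes used in validation

The shipped tests exercise the full pipeline at 50,000 pairs from a 1 Mbp
random genome for the error-free and realistic-error runs (the latter
across all eight presets), 4,000 pairs at depth 20 for the REM rescue run,
and 1,000 random pairs for the brute-force oracle comparison — sizes at
which the measured rates are stable to well under a percentage point while
the whole suite stays fast on a single core. `scripts/acceptance.R`
re-runs the same measurements from scratch under a caller-supplied seed.

## Known limitations

* No indel-tolerant overlap: a single-base indel inside the overlap
  shifts the registers and the pair is (correctly) rejected rather than
  repaired.
* No k-mer error correction of reads that fail to merge; the table is
  used for extension and filtering only.
* Adapter *detection* is out of scope — adapters must be supplied; without
  them, read-through merges rely on the ratio and probability gates alone.
* FASTQ records must be 4-line; multi-line FASTQ is not supported
  (multi-line FASTA is).
* `extend_tail()` and the k-mer modes assume `k ≤ 31` (two-bit packing in
  a 64-bit word).
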