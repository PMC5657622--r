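# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no fixture files.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_chr <- function(s) {
  # plain-R reverse complement, independent of the package's C++ one
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Literal brute-force candidate scan: for every insert size S, walk the
# overlap position by position and apply the ratio formula directly.
# Implemented with string splitting and explicit loops so it shares nothing
# with the engine's rolling scan.
oracle_scan <- function(seq1, seq2rc, c0, min_insert) {
  b1 <- strsplit(seq1, "")[[1]]
  b2 <- strsplit(seq2rc, "")[[1]]
  L1 <- length(b1); L2 <- length(b2)
  out <- list()
  for (S in seq(min_insert, L1 + L2 - 1)) {
    G <- 0L; B <- 0L
    for (j in 0:(L1 - 1)) {
      u <- j - (S - L2)
      if (u >= 0 && u < L2) {
        x <- b1[j + 1]; y <- b2[u + 1]
        if (x != "N" && y != "N") {
          if (x == y) G <- G + 1L else B <- B + 1L
        }
      }
    }
    if (G + B > 0)
      out[[length(out) + 1]] <- data.frame(
        S = S, W = min(L1, S) + min(L2, S) - S, G = G, B = B,
        R = (B + c0) / (B + G))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(S = integer(), W = integer(), G = numeric(),
                  B = numeric(), R = numeric())
}

# Build one error-free pair from a genome string: fragment at `start` of
# length S, reads of length L from each end.
pair_from_genome <- function(genome, start, S, L, qual = 30L,
                             id = sprintf("t insert=%d", S)) {
  frag <- substr(genome, start, start + S - 1)
  r1 <- read_new(id, substr(frag, 1, min(L, S)), default_qual = qual)
  r2 <- read_new(id, substr(rc_chr(frag), 1, min(L, S)), default_qual = qual)
  list(r1 = r1, r2 = r2, frag = frag)
}

# Shared large simulations for the acceptance tests: built once per test
# run, reused across blocks.
.acc_cache <- new.env(parent = emptyenv())

acc_genome <- function() {
  if (is.null(.acc_cache$genome))
    .acc_cache$genome <- generate_genome(1e6, seed = 424243)
  .acc_cache$genome
}

# realistic-error run: full insert range incl. read-through, printed adapters
acc_run3 <- function() {
  if (is.null(.acc_cache$run3)) {
    ad <- default_adapters()
    pairs <- simulate_pairs(acc_genome(), n_pairs = 50000, seed = 424244)
    res <- merge_pairs(pairs, adapter1 = ad[["adapter1"]],
                       adapter2 = ad[["adapter2"]])
    .acc_cache$run3 <- list(pairs = pairs, res = res)
  }
  .acc_cache$run3
}
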