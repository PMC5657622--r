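test_that("k-mer counting is canonical and window-exact", {
  reads <- read_set("a", "ACGTACG", default_qual = 30L)
  tab <- kmer_table(reads, k = 3)
  st <- kmer_table_stats(tab)
  expect_equal(st$total, 5)  # L - k + 1 windows
  # a k-mer and its reverse complement share one key
  two <- read_set(c("a", "b"), c("ACGTAGA", "TCTACGT"), default_qual = 30L)
  t2 <- kmer_table(two, k = 7)
  expect_equal(kmer_count(t2, "ACGTAGA"), 2)
  expect_equal(kmer_count(t2, "TCTACGT"), 2)
  # interior N voids the windows that span it
  withN <- read_set("n", "ACGNACG", default_qual = 30L)
  tn <- kmer_table(withN, k = 3)
  expect_equal(kmer_table_stats(tn)$total, 2)  # only ACG and ACG survive
  expect_equal(kmer_count(tn, "ACG"), 2)
  expect_equal(kmer_count(tn, "GNA"), 0)
})

test_that("k is validated and oversized k warns with an empty table", {
  reads <- read_set("a", "ACGTACGT", default_qual = 30L)
  expect_error(kmer_table(reads, k = 4), "odd")
  expect_error(kmer_table(reads, k = 33), "odd|31")
  expect_warning(tab <- kmer_table(reads, k = 31), "empty")
  expect_equal(kmer_table_stats(tab)$total, 0)
})

test_that("tail extension recovers the genomic continuation", {
  g <- generate_genome(500, seed = 301)
  # tile depth-3 error-free coverage
  starts <- seq(1, 500 - 100 + 1, by = 33)
  cov <- read_set(paste0("c", seq_along(starts)),
                  substring(g, starts, starts + 99), default_qual = 30L)
  tab <- kmer_table(cov, k = 21)
  # a read truncated 30 bases before position 200
  r <- read_new("t", substr(g, 71, 170), default_qual = 30L)
  ext <- extend_tail(r, tab, max_ext = 50, min_depth = 1)
  expect_gte(ext$added, 30)
  expect_equal(ext$extended$seq,
               substr(g, 71, 170 + ext$added))
  expect_equal(ext$extended$qual[101:110], rep(20L, 10))
})

test_that("extension stops with the right reason", {
  empty <- suppressWarnings(
    kmer_table(read_set("a", "ACG", default_qual = 30L), k = 21))
  r <- read_new("t", rand_seq(50), default_qual = 30L)
  e <- extend_tail(r, empty, max_ext = 10)
  expect_equal(e$added, 0)
  expect_equal(e$stop_reason, "no_seed")
  # two haplotypes diverging at one site, both deep: branch stop
  set.seed(302)
  core <- rand_seq(60)
  hapA <- paste0(core, "A", rand_seq(40))
  hapB <- paste0(core, "C", rand_seq(40))
  haps <- read_set(paste0("h", 1:6),
                   rep(c(hapA, hapB), each = 3), default_qual = 30L)
  tab <- kmer_table(haps, k = 21)
  seed_read <- read_new("s", substr(core, 1, 40), default_qual = 30L)
  e2 <- extend_tail(seed_read, tab, max_ext = 60, min_depth = 2)
  expect_equal(e2$stop_reason, "branch")
  # extension proceeds up to the divergence point, then halts
  expect_equal(e2$added, 20)  # bases 41..60 of core
  expect_equal(e2$extended$seq, substr(core, 1, 60))
  # max_length when the table goes far enough
  g <- generate_genome(400, seed = 303)
  tabg <- kmer_table(read_set("g", g, default_qual = 30L), k = 21)
  e3 <- extend_tail(read_new("r", substr(g, 1, 100), default_qual = 30L),
                    tabg, max_ext = 25, min_depth = 1)
  expect_equal(e3$stop_reason, "max_length")
  expect_equal(e3$added, 25)
})

test_that("REM rescues non-overlapping pairs; RSEM refuses them", {
  g <- generate_genome(60000, seed = 304)
  p <- simulate_pairs(g, n_pairs = 1500, min_insert = 330, max_insert = 345,
                      insert_mean = 338, insert_sd = 5, add_errors = FALSE,
                      seed = 305)
  tab <- kmer_table(p, 31)
  i <- which(parse_true_insert(p$r1$id) == 340)[1]
  expect_false(is.na(i))
  pr <- pair_at(p, i)
  expect_false(find_overlap(pr)$status == "merged")
  rem <- merge_with_extension(pr, tab, mode = "rem")
  expect_equal(rem$status, "merged")
  expect_equal(rem$S, 340)
  expect_equal(nchar(rem$merged$seq), 340)
  rsem <- merge_with_extension(pr, tab, mode = "rsem")
  expect_false(rsem$status == "merged")
})

test_that("extension disagreement rejects a repeat-induced false overlap", {
  # each read ends in a copy of a 20-base repeat, faking a clean 20-base
  # overlap at S = 320 while the true insert is 380; k = 31 > repeat length,
  # so extension walks through the repeat and exposes the true geometry
  set.seed(306)
  left <- rand_seq(150)
  rep20 <- rand_seq(20)
  mid <- rand_seq(40)
  right <- rand_seq(150)
  frag <- paste0(left, rep20, mid, rep20, right)  # true insert 380
  cov_starts <- seq(1, nchar(frag) - 99)
  cov <- read_set(paste0("c", cov_starts),
                  substring(frag, cov_starts, cov_starts + 99),
                  default_qual = 30L)
  tab <- kmer_table(cov, k = 31)
  r1 <- read_new("f insert=380", substr(frag, 1, 170), default_qual = 30L)
  r2 <- read_new("f insert=380", substr(rc_chr(frag), 1, 170),
                 default_qual = 30L)
  d0 <- find_overlap(list(r1 = r1, r2 = r2))
  expect_equal(d0$status, "merged")   # the false overlap fools pure overlap
  expect_equal(d0$S, 320)
  rem <- merge_with_extension(list(r1 = r1, r2 = r2), tab, mode = "rem",
                              max_ext = 30)
  expect_false(rem$status == "merged")
})

test_that("zero-length extension reduces k-mer modes to the overlap decision", {
  g <- generate_genome(50000, seed = 307)
  p <- simulate_pairs(g, n_pairs = 200, seed = 308)
  tab <- kmer_table(p, 31)
  def <- merge_pairs(p)
  rem0 <- merge_pairs(p, mode = "rem", table = tab, extend_len = 0)
  expect_identical(as.character(rem0$status), as.character(def$status))
  expect_identical(rem0$insert, def$insert)
})

test_that("k-mer filter passes genomic merges and rejects chimeric ones", {
  g <- generate_genome(60000, seed = 309)
  p <- simulate_pairs(g, n_pairs = 2000, max_insert = 280, add_errors = FALSE,
                      seed = 310)
  tab <- kmer_table(p, 31)
  res <- merge_pairs(p, table = tab)
  ok <- kfilter_gate(res$merged, tab, min_depth = 1)
  expect_true(all(ok))
  # a chimera of two distant loci has unseen junction k-mers
  chimera <- read_new("x", paste0(substr(g, 1, 100), substr(g, 30001, 30100)),
                      default_qual = 30L)
  expect_false(kfilter_gate(chimera, tab, min_depth = 1))
  # shorter than k: vacuous pass
  expect_true(kfilter_gate(read_new("s", "ACGTT", default_qual = 30L), tab))
})

test_that("RSEM merges are a subset of default merges, shorter than L1+L2", {
  g <- generate_genome(1e5, seed = 311)
  p <- simulate_pairs(g, n_pairs = 2000, seed = 312)
  def <- merge_pairs(p)
  rsem <- merge_pairs(p, mode = "rsem")
  expect_true(all(rsem$merged_idx %in% def$merged_idx))
  expect_true(all(nchar(rsem$merged$seq) < 300))
  # agreement on accepted insert sizes for the common set
  common <- rsem$merged_idx
  expect_identical(rsem$insert[common], def$insert[common])
})
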