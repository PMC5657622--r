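test_that("reverse complement reverses, complements, and is an involution", {
  r <- read_new("x", "AACC", c(10L, 20L, 30L, 40L))
  rc <- reverse_complement(r)
  expect_equal(rc$seq, "GGTT")
  expect_equal(rc$qual, c(40L, 30L, 20L, 10L))
  pal <- read_new("p", "ACGT", c(1L, 2L, 3L, 4L))
  expect_equal(reverse_complement(pal)$seq, "ACGT")
  expect_equal(reverse_complement(pal)$qual, c(4L, 3L, 2L, 1L))
  expect_identical(reverse_complement(rc)[c("seq", "qual")],
                   r[c("seq", "qual")])
  expect_error(read_new("bad", "ACXT"), "illegal base")
})

test_that("candidate enumeration finds a constructed junction overlap", {
  set.seed(7)
  junction <- "ACGTACGTAC"
  X <- rand_seq(20)
  Y <- rand_seq(20)
  r1 <- read_new("a", paste0(X, junction), default_qual = 30L)
  r2rc <- read_new("a", paste0(junction, Y), default_qual = 30L)
  prof <- sensitivity_profile("default", c6_insert = 10L)
  cand <- enumerate_candidates(r1, r2rc, prof)
  hit <- cand[cand$S == 50, ]   # L1=30, L2=30, S=50 -> W = 10
  expect_equal(nrow(hit), 1)
  expect_equal(hit$W, 10)
  expect_equal(hit$B, 0)
  expect_equal(hit$G, 10)
})

test_that("full self-overlap and the ratio formula behave as specified", {
  s <- rand_seq(20)
  prof <- sensitivity_profile("default", c6_insert = 5L)
  r <- read_new("a", s, default_qual = 30L)
  cand <- enumerate_candidates(r, r, prof)
  self <- cand[cand$S == 20, ]
  expect_equal(self$W, 20)
  expect_equal(self$G, 20)
  expect_equal(self$B, 0)
  expect_equal(self$R, prof$c0 / 20)
  # 8 matches + 2 mismatches at full overlap: R = (2 + 0.4) / (2 + 8)
  a <- read_new("a", "AAAAACCCCC", default_qual = 30L)
  b <- read_new("a", "AAAAACCCGG", default_qual = 30L)
  cand2 <- enumerate_candidates(a, b, sensitivity_profile(c6_insert = 10L))
  expect_equal(cand2[cand2$S == 10, "R"], 2.4 / 10)
})

test_that("best_two_ratios tracks the two lowest ratios with S tie-break", {
  df <- data.frame(S = c(100, 120, 140), W = 1, G = 1, B = 0,
                   R = c(0.5, 0.02, 0.3))
  bt <- best_two_ratios(df)
  expect_equal(bt$best$R, 0.02)
  expect_equal(bt$best$S, 120)
  expect_equal(bt$R2, 0.3)
  expect_equal(best_two_ratios(df[1, ])$R2, Inf)
  tie <- data.frame(S = c(90, 80), W = 1, G = 1, B = 0, R = c(0.1, 0.1))
  expect_equal(best_two_ratios(tie)$best$S, 80)
  expect_error(best_two_ratios(df[0, ]), "no overlap candidates")
})

test_that("engine candidates match a literal brute-force scan", {
  set.seed(99)
  prof <- sensitivity_profile("default", c6_insert = 10L)
  for (i in 1:50) {
    L1 <- sample(20:60, 1); L2 <- sample(20:60, 1)
    s1 <- rand_seq(L1); s2rc <- rand_seq(L2)
    r1 <- read_new("a", s1, default_qual = 30L)
    r2rc <- read_new("a", s2rc, default_qual = 30L)
    eng <- enumerate_candidates(r1, r2rc, prof)
    ora <- oracle_scan(s1, s2rc, prof$c0, prof$c6_insert)
    expect_equal(eng$S, ora$S)
    expect_equal(eng$G, ora$G)
    expect_equal(eng$B, ora$B)
    expect_equal(eng$R, ora$R, tolerance = 1e-12)
    if (nrow(eng)) {
      bt <- best_two_ratios(eng)
      obt <- ora[order(ora$R, ora$S), ]
      expect_equal(bt$best$S, obt$S[1])
      if (nrow(obt) > 1) expect_equal(bt$R2, obt$R[2], tolerance = 1e-12)
    }
  }
})

test_that("acceptance gates fire in the specified order", {
  prof <- sensitivity_profile("default", c1 = 0.1, c2 = 5)
  cand <- function(S, G, B, R) data.frame(S = S, W = G + B, G = G, B = B,
                                          R = R)
  expect_equal(apply_gates(cand(200, 30, 10, 0.5), Inf, 0, prof),
               "no_overlap")
  expect_equal(apply_gates(cand(200, 30, 0, 0.02), 0.03, 0, prof),
               "ambiguous")    # 0.02 * 5 = 0.1 > 0.03
  expect_equal(apply_gates(cand(200, 30, 0, 0.005), 0.04, 0, prof),
               "ambiguous")    # R2 < c3
  expect_equal(apply_gates(cand(200, 9, 0, 0.04), 0.9, 8, prof),
               "too_short_overlap")  # G = 9 < max(c4 = 12, 8)
  expect_equal(apply_gates(cand(20, 30, 0, 0.013), 0.9, 0, prof),
               "too_short_insert")
  expect_equal(apply_gates(cand(200, 30, 0, 0.013), 0.9, 0, prof), "merged")
})

test_that("complexity floor is maximal for homopolymers, zero for random", {
  prof <- sensitivity_profile()
  homo <- read_new("h", strrep("A", 150), default_qual = 30L)
  expect_equal(complexity_min_overlap(homo, homo, prof), prof$v_max)
  set.seed(13)
  v <- replicate(1000, {
    r <- read_new("r", rand_seq(150), default_qual = 30L)
    complexity_min_overlap(r, r, prof)
  })
  expect_gte(mean(v == 0), 0.99)
  expect_true(all(complexity_min_overlap(homo, homo, prof) >= v))
})

test_that("flat mode agrees with ratio mode on clean overlaps and xstrict
           rejects disagreements", {
  g <- generate_genome(400, seed = 21)
  pr <- pair_from_genome(g, 30, 260, 150)
  prof <- sensitivity_profile()
  flat <- flat_mode_best(pr$r1, reverse_complement(pr$r2), prof)
  ratio <- best_two_ratios(
    enumerate_candidates(pr$r1, reverse_complement(pr$r2), prof))
  expect_equal(flat$S, 260)
  expect_equal(ratio$best$S, 260)
  # no candidate satisfies G >= c4 -> NULL
  short1 <- read_new("s", rand_seq(20), default_qual = 30L)
  short2 <- read_new("s", rand_seq(20), default_qual = 30L)
  expect_null(flat_mode_best(short1, short2,
                             sensitivity_profile(c4 = 25L)))
  # xstrict merges a clean pair (modes agree)
  dec <- find_overlap(pr, sensitivity_profile("xstrict"))
  expect_equal(dec$status, "merged")
  expect_equal(dec$S, 260)
})

test_that("adapter check passes true read-through and rejects random overhang", {
  ad <- default_adapters()
  g <- generate_genome(5000, seed = 31)
  p <- simulate_pairs(g, n_pairs = 30, min_insert = 100, max_insert = 120,
                      read_len = 150, add_errors = FALSE, seed = 32)
  prof <- sensitivity_profile()
  for (i in 1:10) {
    pr <- pair_at(p, i)
    S <- parse_true_insert(pr$r1$id)
    expect_true(adapter_check(pr$r1, pr$r2, S, ad[["adapter1"]],
                              ad[["adapter2"]], prof))
    # replace the overhang by random bases: must fail
    fake <- read_new(pr$r1$id,
                     paste0(substr(pr$r1$seq, 1, S), rand_seq(150 - S)),
                     pr$r1$qual)
    expect_false(adapter_check(fake, fake, S, ad[["adapter1"]],
                               ad[["adapter2"]], prof))
  }
  # no overhang -> vacuous pass
  long <- read_new("l", rand_seq(150), default_qual = 30L)
  expect_true(adapter_check(long, long, 200, ad[["adapter1"]],
                            ad[["adapter2"]], prof))
})

test_that("expected-mismatch gate matches direct summation", {
  prof <- sensitivity_profile(c5 = 10)
  r1 <- read_new("a", rand_seq(30), default_qual = 40L)
  r2rc <- read_new("a", r1$seq, default_qual = 40L)
  cand <- data.frame(S = 30, W = 30, G = 30, B = 0)
  gate <- expected_mismatch_gate(r1, r2rc, cand, prof)
  p <- 1e-4
  expect_equal(gate$E, 30 * (2 * p - (4 / 3) * p^2), tolerance = 1e-12)
  expect_true(gate$pass)
  cand$B <- 3   # 3 > E * 10 ~ 0.06
  expect_false(expected_mismatch_gate(r1, r2rc, cand, prof)$pass)
  cand$B <- 0   # B = 0 always passes
  expect_true(expected_mismatch_gate(r1, r2rc, cand, prof)$pass)
})

test_that("pattern-probability gate is an exact binomial tail", {
  prof <- sensitivity_profile()
  r1 <- read_new("a", rand_seq(40), default_qual = 40L)
  r2rc <- read_new("a", r1$seq, default_qual = 40L)
  expect_equal(pattern_probability_gate(
    r1, r2rc, data.frame(S = 40, W = 40, G = 40, B = 0), prof)$P, 1)
  # all-mismatch overlap at Q40 is essentially impossible
  allmm <- pattern_probability_gate(
    r1, r2rc, data.frame(S = 40, W = 8, G = 0, B = 8), prof)
  expect_lt(allmm$P, 1e-10)
  expect_false(allmm$pass)
  # random (B, W, Q) triples against an independent long-sum computation
  set.seed(17)
  for (i in 1:100) {
    W <- sample(10:60, 1)
    B <- sample(0:W, 1)
    Q <- sample(10:40, 1)
    rr1 <- read_new("a", rand_seq(W), default_qual = Q)
    rr2 <- read_new("a", rr1$seq, default_qual = Q)
    got <- pattern_probability_gate(
      rr1, rr2, data.frame(S = W, W = W, G = W - B, B = B), prof)$P
    p <- 10^(-Q / 10)
    r <- (2 * p - (4 / 3) * p^2)  # per-position rate E/W
    want <- if (B == 0) 1 else sum(vapply(B:W, function(k)
      choose(W, k) * r^k * (1 - r)^(W - k), 0))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("find_overlap recovers constructed inserts and rejects noise", {
  g <- generate_genome(300, seed = 51)
  pr <- pair_from_genome(g, 1, 260, 150)
  dec <- find_overlap(pr)
  expect_equal(dec$status, "merged")
  expect_equal(dec$S, 260)
  expect_equal(dec$W, 40)
  # disjoint random reads: never merged
  set.seed(52)
  statuses <- replicate(200, {
    find_overlap(list(r1 = read_new("a", rand_seq(150), default_qual = 30L),
                      r2 = read_new("a", rand_seq(150), default_qual = 30L)
                 ))$status
  })
  expect_false(any(statuses == "merged"))
  # fragment inside an exact tandem repeat: ambiguous placement
  unit <- rand_seq(60)
  rep_g <- strrep(unit, 6)
  prr <- pair_from_genome(rep_g, 1, 260, 150)
  expect_equal(find_overlap(prr)$status, "ambiguous")
})

test_that("overlap decisions are symmetric in mate order", {
  g <- generate_genome(1e5, seed = 61)
  ad <- default_adapters()
  p <- simulate_pairs(g, n_pairs = 200, seed = 62)
  for (i in seq(1, 200, by = 7)) {
    pr <- pair_at(p, i)
    d12 <- find_overlap(pr, adapter1 = ad[["adapter1"]],
                        adapter2 = ad[["adapter2"]])
    d21 <- find_overlap(list(r1 = pr$r2, r2 = pr$r1),
                        adapter1 = ad[["adapter2"]],
                        adapter2 = ad[["adapter1"]])
    expect_equal(d21$status, d12$status)
    expect_equal(d21$S, d12$S)
  }
})

test_that("loosening a single gate constant never un-merges a pair", {
  g <- generate_genome(1e5, seed = 71)
  p <- simulate_pairs(g, n_pairs = 500, seed = 72)
  base <- sensitivity_profile()
  merged_base <- which(merge_pairs(p, base)$status == "merged")
  for (prof in list(sensitivity_profile(c1 = base$c1 * 2),
                    sensitivity_profile(c2 = base$c2 / 2),
                    sensitivity_profile(c4 = 8L))) {
    merged_loose <- which(merge_pairs(p, prof)$status == "merged")
    expect_true(all(merged_base %in% merged_loose))
  }
})

test_that("no merged pair reports an insert below the configured minimum", {
  g <- generate_genome(5e4, seed = 81)
  p <- simulate_pairs(g, n_pairs = 500, min_insert = 100, max_insert = 200,
                      seed = 82)
  prof <- sensitivity_profile(c6_insert = 150L)
  res <- merge_pairs(p, prof)
  expect_true(all(res$insert[!is.na(res$insert)] >= 150))
})

test_that("quality-weighted counting (ouq) stays consistent with the gates", {
  g <- generate_genome(5e4, seed = 91)
  p <- simulate_pairs(g, n_pairs = 300, seed = 92)
  res <- merge_pairs(p, sensitivity_profile(ouq = TRUE))
  resn <- merge_pairs(p)
  # weighted counts change scores, not the vocabulary or the conservation
  expect_true(all(res$status %in% levels(resn$status)))
  expect_equal(length(res$status), 300)
  pr <- pair_at(p, 1)
  cw <- enumerate_candidates(pr$r1, reverse_complement(pr$r2),
                             sensitivity_profile(ouq = TRUE))
  cn <- enumerate_candidates(pr$r1, reverse_complement(pr$r2),
                             sensitivity_profile())
  expect_equal(cw$S, cn$S)
  expect_true(all(cw$G <= cn$G + 1e-9))  # weights never exceed unit counts
})
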