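test_that("effective positions: sense identity, antisense +2", {
  expect_equal(effective_position(42L, "sense"), 42L)
  expect_equal(effective_position(40L, "antisense"), 42L)
  expect_equal(effective_position(c(0L, 10L), c("sense", "antisense")),
               c(0L, 12L))
})

test_that("perfect duplex partners share a register after the +2 offset", {
  for (p in c(21L, 24L)) {
    for (s in c(2L, 7L, 100L, 1000L)) {
      d <- duplex_placements(s, p)
      eff <- effective_position(d$start, d$strand)
      expect_equal(eff[1] %% p, eff[2] %% p)
      expect_equal(eff[2], s)
    }
  }
})

test_that("phasing p-value matches the tail-enumeration oracle", {
  for (p in c(21L, 24L)) {
    for (n in c(1L, 3L, 12L, 40L)) {
      for (k in 0:min(n, 10L)) {
        expect_equal(phasing_p_value(k, n, 10L, p),
                     hyper_tail_enum(k, n, 10L, p), tolerance = 1e-12,
                     label = sprintf("k=%d n=%d p=%d", k, n, p))
      }
    }
  }
  # the two spec'd anchor cases
  expect_equal(phasing_p_value(3, 3, 10, 21), hyper_tail_enum(3, 3, 10, 21),
               tolerance = 1e-12)
  expect_equal(phasing_p_value(5, 12, 10, 24),
               hyper_tail_enum(5, 12, 10, 24), tolerance = 1e-12)
})

test_that("phasing p-value: k=0 is exactly 1 and tails are monotone in k", {
  expect_identical(phasing_p_value(0, 17, 10, 21), 1)
  expect_identical(phasing_p_value(0, 0, 10, 24), 1)
  for (n in c(5L, 20L, 40L)) {
    pv <- phasing_p_value(0:min(n, 10L), n, 10L, 21L)
    expect_true(all(diff(pv) < 0))
  }
})

test_that("phasing p-value rejects out-of-domain input", {
  expect_error(phasing_p_value(-1, 5, 10, 21), "domain")
  expect_error(phasing_p_value(6, 5, 10, 21), "domain")   # k > n
  expect_error(phasing_p_value(11, 30, 10, 21), "domain") # k > m
  expect_error(phasing_p_value(3, 211, 10, 21), "domain") # n > pm
})

test_that("phase score closed forms and the k>=3 gate", {
  expect_equal(phase_score(3, 10, 0), log(101))
  expect_equal(phase_score(4, 20, 19), 2 * log(11))
  expect_identical(phase_score(2, 1000, 0), 0)
  expect_identical(phase_score(0, 0, 0), 0)
})

test_that("phase score is monotone in k and sum_P, anti-monotone in sum_U", {
  set.seed(77)
  for (i in 1:200) {
    k <- sample(3:12, 1); P <- runif(1, 0, 200); U <- runif(1, 0, 200)
    dP <- runif(1, 0.1, 50); dU <- runif(1, 0.1, 50)
    expect_gte(phase_score(k + 1, P, U), phase_score(k, P, U))
    expect_gte(phase_score(k, P + dP, U), phase_score(k, P, U))
    expect_lte(phase_score(k, P, U + dU), phase_score(k, P, U))
  }
})

test_that("scan counts a pure phased stack as k = n with no off-phase mass", {
  a <- 30L
  stack <- phased_stack(a, 5)
  w <- scan_transcript(stack, 400L, phase_config())
  w0 <- w[w$window_start == a, ]
  expect_equal(w0$k, 5L)
  expect_equal(w0$n, 5L)
  expect_equal(w0$sum_P, 50)
  expect_equal(w0$sum_U, 0)
})

test_that("scan ignores reads of other lengths and books off-register abundance", {
  a <- 30L
  stack <- phased_stack(a, 5)
  plus22 <- mapped_row(random_dna(22), 100, "t1", a + 3L, "sense")
  off21 <- mapped_row(random_dna(21), 7, "t1", a + 1L, "sense")
  w <- scan_transcript(rbind(stack, plus22, off21), 400L, phase_config())
  w0 <- w[w$window_start == a, ]
  expect_equal(w0$k, 5L)      # 22-mer invisible
  expect_equal(w0$n, 6L)      # off-register 21-mer counted in n
  expect_equal(w0$sum_U, 7)
  expect_equal(w0$sum_P, 50)
})

test_that("windows are anchored only at effective positions that fit", {
  stack <- phased_stack(100L, 3)
  w <- scan_transcript(stack, 320L, phase_config())
  expect_equal(nrow(w), 1L)                    # only anchor 100 fits 210 nt
  expect_equal(w$window_start, 100L)
  expect_equal(w$k, 3L)                        # all three reads in register
})

test_that("strand flip with consistent effective positions leaves stats unchanged", {
  set.seed(13)
  tx_len <- 600L
  reads <- rbind(phased_stack(40L, 4, seed = 1),
                 mapped_row(random_dna(21), 5, "t1", 66L, "sense"),
                 mapped_row(random_dna(21), 3, "t1", 100L, "antisense"))
  flipped <- reads
  flipped$seq <- revcomp(reads$seq)
  flipped$strand <- ifelse(reads$strand == "sense", "antisense", "sense")
  # keep effective positions identical: sense->antisense moves start by -2
  flipped$start <- reads$start + ifelse(reads$strand == "sense", -2L, 2L)
  w1 <- scan_transcript(reads, tx_len, phase_config())
  w2 <- scan_transcript(flipped, tx_len, phase_config())
  cols <- c("window_start", "k", "n", "sum_P", "sum_U", "p_value",
            "phase_score")
  expect_equal(w1[, cols], w2[, cols], ignore_attr = TRUE)
})

test_that("extension and merging follow the 100 bp / overlap contract", {
  cfg <- phase_config()
  w <- rbind(
    data.frame(transcript_id = "t1", window_start = 0L, p = 21L, m = 10L,
               k = 5L, n = 5L, sum_P = 50, sum_U = 0,
               p_value = 1e-6, phase_score = 12),
    data.frame(transcript_id = "t1", window_start = 50L, p = 21L, m = 10L,
               k = 4L, n = 5L, sum_P = 30, sum_U = 2,
               p_value = 1e-4, phase_score = 8),
    data.frame(transcript_id = "t1", window_start = 340L, p = 21L, m = 10L,
               k = 3L, n = 9L, sum_P = 9, sum_U = 9, p_value = 0.2,
               phase_score = 2))
  r <- extend_and_merge(w, 360L, cfg)
  expect_equal(nrow(r), 1L)              # p=0.2 window dropped, rest merge
  expect_equal(r$start, 0L)              # clipped at 5' end
  expect_equal(r$end, 360L)              # clipped at transcript end
  expect_equal(r$best_window_start, 0L)  # max-score member
  expect_equal(r$best_register, 0L)
  expect_equal(r$min_p_value, 1e-6)
  expect_equal(r$max_phase_score, 12)
})

test_that("extend_and_merge drops non-significant windows and handles none", {
  cfg <- phase_config()
  w <- data.frame(transcript_id = "t1", window_start = 10L, p = 21L,
                  m = 10L, k = 1L, n = 1L, sum_P = 1, sum_U = 0,
                  p_value = 0.2, phase_score = 0)
  expect_equal(nrow(extend_and_merge(w, 1000L, cfg)), 0L)
  expect_equal(nrow(extend_and_merge(w[0, ], 1000L, cfg)), 0L)
})

test_that("merging already-merged regions is idempotent", {
  cfg <- phase_config()
  set.seed(3)
  w <- data.frame(transcript_id = "t1",
                  window_start = sort(sample(0:1500, 12)), p = 21L, m = 10L,
                  k = 4L, n = 5L, sum_P = 20, sum_U = 1,
                  p_value = runif(12, 0, 0.04), phase_score = 6)
  r1 <- extend_and_merge(w, 2000L, cfg)
  # merged regions are pairwise disjoint (merging them again changes nothing)
  expect_true(all(r1$start[-1] > utils::head(r1$end, -1)))
  expect_true(all(r1$end <= 2000L) && all(r1$start >= 0L))
})

test_that("BH correction matches hand-computed values", {
  r <- data.frame(min_p_value = c(0.01, 0.02, 0.03))
  expect_equal(fdr_correct(r)$fdr, c(0.03, 0.03, 0.03))
  r1 <- data.frame(min_p_value = 0.01)
  expect_equal(fdr_correct(r1)$fdr, 0.01)
  rall <- data.frame(min_p_value = rep(1, 5))
  expect_equal(fdr_correct(rall)$fdr, rep(1, 5))
  # cross-check against the generic implementation on a random draw
  set.seed(8)
  pr <- data.frame(min_p_value = runif(50))
  expect_equal(fdr_correct(pr)$fdr, p.adjust(pr$min_p_value, "BH"))
})

test_that("locus calling applies both thresholds and the naming contract", {
  cfg <- phase_config()
  reg <- data.frame(
    transcript_id = c("TR101427|c8_g4_i1", "t2", "t2", "t3"),
    start = c(0L, 500L, 10L, 0L), end = c(360L, 900L, 400L, 300L),
    p = 21L, best_window_start = c(0L, 600L, 100L, 10L),
    best_register = c(0L, 12L, 16L, 10L), k = 6L, n = 7L,
    max_phase_score = c(6.0, 7.5, 5.2, 4.9),
    min_p_value = c(1e-5, 1e-6, 1e-4, 1e-9))
  loci <- call_loci(fdr_correct(reg), cfg)
  # the score-4.9 region fails despite its tiny P
  expect_false("t3" %in% loci$transcript_id)
  expect_equal(loci$name[loci$transcript_id == "TR101427|c8_g4_i1"],
               "P21_TR101427_c8_g4_i1_1")
  t2 <- loci[loci$transcript_id == "t2", ]
  expect_equal(t2$name[order(t2$start)], c("P21_t2_1", "P21_t2_2"))
})

test_that("loci failing the corrected-P threshold are rejected", {
  cfg <- phase_config()
  reg <- data.frame(transcript_id = "t1", start = 0L, end = 360L, p = 21L,
                    best_window_start = 0L, best_register = 0L, k = 6L,
                    n = 7L, max_phase_score = 10, min_p_value = 0.04)
  reg$fdr <- 0.08    # fails alpha after correction
  expect_equal(nrow(call_loci(reg, cfg)), 0L)
})

test_that("phasiRNA extraction keeps register, orders serials, includes antisense", {
  stack <- phased_stack(105L, 5)
  anti <- mapped_row(revcomp(random_dna(21)), 4, "t1", 103L, "antisense")
  off <- mapped_row(random_dna(21), 9, "t1", 108L, "sense")
  locus <- data.frame(name = "P21_t1_1", transcript_id = "t1", start = 5L,
                      end = 400L, p = 21L, best_window_start = 105L,
                      best_register = 105L %% 21L)
  ph <- extract_phasirnas(locus, rbind(stack, anti, off))
  expect_equal(nrow(ph), 6L)
  expect_equal(ph$name, sprintf("P21_t1_1_siR%d", 1:6))
  # sense before antisense at the shared effective position 105
  expect_equal(ph$strand[1:2], c("sense", "antisense"))
  expect_false(off$seq %in% ph$seq)
  expect_true(all((ph$position - locus$best_register) %% 21L == 0L))
})

test_that("find_phas_loci is clean on empty input and reads off one transcript", {
  tx <- as_dss(t1 = random_dna(800, seed = 2))
  res <- find_phas_loci(align_exact(data.frame(seq = character(),
                                               count = numeric()), tx), tx)
  expect_equal(nrow(res$loci), 0L)
  expect_equal(nrow(res$windows), 0L)
  expect_equal(nrow(res$phasirnas), 0L)
})
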